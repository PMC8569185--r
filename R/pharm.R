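# Assay quantification: three-parameter logistic fits, Cheng-Prusoff
# conversion, cAMP reference normalization and monophasic inhibition fits,
# and BRET ligand-induced-signal quantification.
#
# All concentration-response fits fix the Hill slope at 1 (three-parameter
# logistic). Nonlinear least squares runs through minpack.lm with
# multi-start initialization (data-driven start plus +/- 1 log-unit shifts
# of the midpoint); the best converged start by SSE is reported and
# non-convergence is flagged, never silently returned.

.fit_starts <- function(concentration, response) {
  agg <- tapply(response, concentration, mean)
  conc <- as.numeric(names(agg))
  top0 <- max(agg)
  bottom0 <- min(agg)
  mid <- (top0 + bottom0) / 2
  lc50_0 <- log10(conc[which.min(abs(agg - mid))])
  list(top = top0, bottom = bottom0, lc50 = lc50_0)
}

.run_nls <- function(formula, data, starts_list) {
  best <- NULL
  for (st in starts_list) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$convInfo$isConv)) next
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  best
}

.fit_se <- function(fit) {
  tryCatch(summary(fit)$coefficients[, "Std. Error"],
           error = function(e) NULL)
}

#' Three-parameter logistic fit of a concentration-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + 10^(s (log10 c - log10 c50)))` with
#' the Hill slope fixed at 1; `s = +1` for `direction = "decreasing"`
#' (displacement curves on the cpm scale) and `s = -1` for curves rising to
#' a plateau.
#'
#' @param concentration Concentrations, nM (> 0); at least 4 distinct
#'   values.
#' @param response Measured responses, same length.
#' @param direction `"decreasing"` or `"increasing"`.
#' @return List of class `"kor_fit"`: `top`, `bottom`, `log_c50`, `c50`
#'   (nM), `sse`, `converged`, `degenerate`, `se` (named vector or NULL),
#'   `direction`, `n_points`.
#' @export
fit_logistic3 <- function(concentration, response,
                          direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  stopifnot(length(concentration) == length(response))
  if (!all(is.finite(response)) || !all(concentration > 0))
    stop("responses must be finite and concentrations > 0", call. = FALSE)
  if (length(unique(concentration)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  out <- list(top = NA_real_, bottom = NA_real_, log_c50 = NA_real_,
              c50 = NA_real_, sse = NA_real_, converged = FALSE,
              degenerate = FALSE, se = NULL, direction = direction,
              n_points = length(response))
  class(out) <- "kor_fit"
  if (diff(range(response)) == 0) {
    out$degenerate <- TRUE
    out$top <- out$bottom <- response[1]
    return(out)
  }
  df <- data.frame(lc = log10(concentration), y = response)
  st <- .fit_starts(concentration, response)
  starts <- lapply(c(0, -1, 1), function(shift) {
    list(top = st$top, bottom = st$bottom, lc50 = st$lc50 + shift)
  })
  form <- if (direction == "decreasing") {
    y ~ bottom + (top - bottom) / (1 + 10^(lc - lc50))
  } else {
    y ~ bottom + (top - bottom) / (1 + 10^(lc50 - lc))
  }
  fit <- .run_nls(form, df, starts)
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  out$top <- unname(cf["top"]); out$bottom <- unname(cf["bottom"])
  out$log_c50 <- unname(cf["lc50"]); out$c50 <- 10^out$log_c50
  out$sse <- deviance(fit); out$converged <- TRUE
  out$se <- .fit_se(fit)
  out
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + L / Kd)` for a competition binding experiment with
#' free radioligand concentration L and radioligand dissociation constant
#' Kd.
#'
#' @param ic50 Half-maximal displacement concentration, nM.
#' @param L Radioligand concentration, nM.
#' @param Kd Radioligand dissociation constant, nM.
#' @return Ki in nM.
#' @export
#' @examples
#' cheng_prusoff(7.0926, L = 1, Kd = 0.87)
cheng_prusoff <- function(ic50, L, Kd) {
  if (any(c(ic50, L, Kd) <= 0))
    stop("ic50, L and Kd must all be > 0", call. = FALSE)
  ic50 / (1 + L / Kd)
}

#' Fit a displacement dataset and convert to Ki
#'
#' Fits the raw cpm curve with [fit_logistic3()] (decreasing, bottom free)
#' and converts the fitted IC50 to Ki by [cheng_prusoff()]. The fitted
#' bottom plateau is reported alongside the experimentally defined
#' nonspecific level for comparison.
#'
#' @param dataset A `"binding_dataset"` from [simulate_displacement()], or
#'   a data.frame with columns `concentration_nM` and `cpm` (then
#'   `radioligand_conc` and `radioligand_Kd` must be given).
#' @param radioligand_conc,radioligand_Kd Radioligand parameters, nM;
#'   defaults taken from the dataset if present.
#' @return List: `fit` (the `"kor_fit"`), `ic50`, `ki`,
#'   `nonspecific_fitted` (fitted bottom), `nonspecific_experimental`.
#' @export
fit_binding <- function(dataset, radioligand_conc = NULL,
                        radioligand_Kd = NULL) {
  if (inherits(dataset, "binding_dataset")) {
    radioligand_conc <- radioligand_conc %||% dataset$radioligand_conc
    radioligand_Kd <- radioligand_Kd %||% dataset$radioligand_Kd
    ns_exp <- dataset$nonspecific_cpm
    df <- dataset$data
  } else {
    df <- dataset
    ns_exp <- NA_real_
  }
  if (is.null(radioligand_conc) || is.null(radioligand_Kd))
    stop("radioligand_conc and radioligand_Kd are required", call. = FALSE)
  fit <- fit_logistic3(df$concentration_nM, df$cpm, direction = "decreasing")
  ki <- if (fit$converged) cheng_prusoff(fit$c50, radioligand_conc,
                                         radioligand_Kd) else NA_real_
  list(fit = fit, ic50 = fit$c50, ki = ki,
       nonspecific_fitted = fit$bottom, nonspecific_experimental = ns_exp)
}

#' Normalize raw cAMP responses to the reference effect
#'
#' Expresses each raw response as percent of the reference-ligand
#' inhibition at 10 uM, which defines 100% on the normalized scale.
#'
#' @param raw_responses Numeric vector of raw-scale responses.
#' @param reference_raw_at_10uM Raw response of the reference ligand at
#'   10 uM (must be nonzero).
#' @return Numeric vector of percent-scale responses.
#' @export
normalize_camp <- function(raw_responses, reference_raw_at_10uM) {
  if (!is.finite(reference_raw_at_10uM) || reference_raw_at_10uM == 0)
    stop("zero reference effect: cannot normalize", call. = FALSE)
  100 * raw_responses / reference_raw_at_10uM
}

#' Monophasic inhibition fit on the normalized percent scale
#'
#' Least-squares fit of `y = Emax / (1 + EC50 / c)`: the three-parameter
#' logistic with bottom fixed at 0 (the normalization defines 0 as no
#' inhibition) and slope 1. A fitted plateau above 120% draws a warning
#' but is still reported.
#'
#' @param concentration Concentrations, nM; at least 4 distinct values.
#' @param response_pct Responses in percent of the reference effect.
#' @return List of class `"kor_fit"` with additionally `ec50` (nM) and
#'   `emax` (percent).
#' @export
fit_inhibition <- function(concentration, response_pct) {
  stopifnot(length(concentration) == length(response_pct))
  if (!all(is.finite(response_pct)) || !all(concentration > 0))
    stop("responses must be finite and concentrations > 0", call. = FALSE)
  if (length(unique(concentration)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  out <- list(top = NA_real_, bottom = 0, log_c50 = NA_real_,
              c50 = NA_real_, ec50 = NA_real_, emax = NA_real_,
              sse = NA_real_, converged = FALSE, degenerate = FALSE,
              se = NULL, direction = "increasing",
              n_points = length(response_pct))
  class(out) <- "kor_fit"
  if (diff(range(response_pct)) == 0) {
    out$degenerate <- TRUE
    return(out)
  }
  df <- data.frame(lc = log10(concentration), y = response_pct)
  st <- .fit_starts(concentration, response_pct)
  starts <- lapply(c(0, -1, 1), function(shift) {
    list(emax = max(st$top, 1e-6), lc50 = st$lc50 + shift)
  })
  fit <- .run_nls(y ~ emax / (1 + 10^(lc50 - lc)), df, starts)
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  out$emax <- out$top <- unname(cf["emax"])
  out$log_c50 <- unname(cf["lc50"])
  out$ec50 <- out$c50 <- 10^out$log_c50
  out$sse <- deviance(fit); out$converged <- TRUE
  out$se <- .fit_se(fit)
  if (out$emax > 120)
    warning("fitted Emax exceeds 120% of the reference effect")
  out
}

#' Fit a simulated cAMP dataset end to end
#'
#' Normalizes the raw responses to the dataset's reference at 10 uM and
#' fits the monophasic inhibition equation.
#'
#' @param dataset A `"camp_dataset"` from [simulate_camp()].
#' @return The `"kor_fit"` from [fit_inhibition()].
#' @export
fit_camp <- function(dataset) {
  stopifnot(inherits(dataset, "camp_dataset"))
  pct <- normalize_camp(dataset$data$response,
                        dataset$reference_response_at_10uM)
  fit_inhibition(dataset$data$concentration_nM, pct)
}

.bret_ratio <- function(trace) trace$em510 / trace$em460

#' Ligand-induced BRET time series
#'
#' Pointwise difference of acceptor/donor emission ratios,
#' `delta(t) = (em510/em460)_ligand - (em510/em460)_vehicle`. Unequal time
#' grids are resolved by linear interpolation of the vehicle ratio onto the
#' ligand grid; ligand times outside the vehicle grid are an error.
#'
#' @param ligand,vehicle Trace data.frames with columns `time_s`, `em460`,
#'   `em510`.
#' @return data.frame with columns `time_s`, `delta`.
#' @export
bret_ligand_induced <- function(ligand, vehicle) {
  rl <- .bret_ratio(ligand)
  if (length(ligand$time_s) == length(vehicle$time_s) &&
      all(ligand$time_s == vehicle$time_s)) {
    rv <- .bret_ratio(vehicle)
  } else {
    rv <- approx(vehicle$time_s, .bret_ratio(vehicle),
                 xout = ligand$time_s)$y
    if (anyNA(rv))
      stop("time grids misaligned: vehicle trace does not cover the ligand grid",
           call. = FALSE)
  }
  data.frame(time_s = ligand$time_s, delta = rl - rv)
}

#' Windowed-mean relative BRET quantification
#'
#' Mean ligand-induced BRET over the analysis window (inclusive endpoints,
#' default 311-2411 s) divided by the reference windowed mean, as percent.
#'
#' @param ligand_delta,reference_delta data.frames with columns `time_s`,
#'   `delta` (from [bret_ligand_induced()]).
#' @param window Length-2 numeric window in seconds.
#' @return Percent of the reference effect.
#' @export
bret_relative <- function(ligand_delta, reference_delta,
                          window = c(311, 2411)) {
  wmean <- function(d) {
    keep <- d$time_s >= window[1] & d$time_s <= window[2]
    if (!any(keep)) stop("no samples in the analysis window", call. = FALSE)
    mean(d$delta[keep])
  }
  100 * wmean(ligand_delta) / wmean(reference_delta)
}

#' Summarize per-ligand fit results across independent experiments
#'
#' Mean and sample SD (n - 1 denominator) per ligand for every metric
#' present among `ki`, `ec50`, `emax`, `bret_relative`; SD is NA for a
#' single experiment.
#'
#' @param results data.frame with columns `ligand`, `experiment` and one or
#'   more of `ki`, `ec50`, `emax`, `bret_relative`.
#' @return data.frame with one row per ligand: `n_experiments` and
#'   `<metric>_mean` / `<metric>_sd` columns.
#' @export
assemble_summary <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("ligand", "experiment") %in% names(results)))
  metrics <- intersect(c("ki", "ec50", "emax", "bret_relative"),
                       names(results))
  if (nrow(results) == 0L || length(metrics) == 0L)
    stop("no converged fit results to summarize", call. = FALSE)
  ligands <- unique(results$ligand)
  rows <- lapply(ligands, function(lg) {
    sub <- results[results$ligand == lg, , drop = FALSE]
    row <- data.frame(ligand = lg,
                      n_experiments = length(unique(sub$experiment)),
                      stringsAsFactors = FALSE)
    for (mt in metrics) {
      v <- sub[[mt]][is.finite(sub[[mt]])]
      row[[paste0(mt, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(mt, "_sd")]] <- if (length(v) > 1L) sd(v) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
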