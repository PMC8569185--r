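test_that("noise-free logistic data are recovered to high precision", {
  conc <- binding_grid()
  y <- 400 + (4000 - 400) / (1 + conc / 7.09)
  fit <- fit_logistic3(conc, y, direction = "decreasing")
  expect_true(fit$converged)
  expect_equal(fit$top, 4000, tolerance = 1e-6)
  expect_equal(fit$bottom, 400, tolerance = 1e-6)
  expect_equal(fit$c50, 7.09, tolerance = 1e-6)
  # fitted curve passes through (top + bottom) / 2 at c50
  mid <- fit$bottom + (fit$top - fit$bottom) /
    (1 + 10^(log10(fit$c50) - fit$log_c50))
  expect_equal(mid, (fit$top + fit$bottom) / 2)
})

test_that("logistic fits are scale-equivariant and flag degenerate data", {
  set.seed(8)
  conc <- binding_grid()
  y <- 400 + 3600 / (1 + conc / 20) + rnorm(length(conc), 0, 30)
  f1 <- fit_logistic3(conc, y, "decreasing")
  f2 <- fit_logistic3(conc, 3.5 * y, "decreasing")
  expect_equal(f2$top, 3.5 * f1$top, tolerance = 1e-6)
  expect_equal(f2$bottom, 3.5 * f1$bottom, tolerance = 1e-6)
  expect_equal(f2$c50, f1$c50, tolerance = 1e-6)

  flat <- fit_logistic3(conc, rep(1000, length(conc)), "decreasing")
  expect_true(flat$degenerate)
  expect_false(flat$converged)
  expect_true(is.na(flat$c50))
  expect_error(fit_logistic3(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
})

test_that("Cheng-Prusoff conversion matches the closed form and its limits", {
  expect_equal(cheng_prusoff(10, L = 1, Kd = 1), 5)
  expect_equal(cheng_prusoff(10, L = 1e-9, Kd = 1), 10, tolerance = 1e-8)
  expect_equal(cheng_prusoff(7.0926, L = 1, Kd = 0.87),
               7.0926 / (1 + 1 / 0.87))
  expect_equal(round(cheng_prusoff(7.0926, L = 1, Kd = 0.87), 2), 3.30)
  # Ki never exceeds IC50
  set.seed(2)
  for (rep in 1:25) {
    ic50 <- 10^runif(1, -2, 4); L <- 10^runif(1, -2, 2)
    Kd <- 10^runif(1, -2, 2)
    expect_lt(cheng_prusoff(ic50, L, Kd), ic50)
  }
  expect_error(cheng_prusoff(-1, 1, 1), "> 0")
})

test_that("cAMP normalization maps the reference effect to 100%", {
  expect_equal(normalize_camp(0.5, 0.5), 100)
  expect_equal(normalize_camp(0, 0.5), 0)
  expect_equal(normalize_camp(0.25, 0.5), 50)
  expect_error(normalize_camp(1, 0), "reference")
})

test_that("monophasic inhibition fit recovers noise-free parameters", {
  conc <- camp_grid()
  y <- 82.4 / (1 + 3.60 / conc)
  fit <- fit_inhibition(conc, y)
  expect_true(fit$converged)
  expect_equal(fit$ec50, 3.60, tolerance = 1e-6)
  expect_equal(fit$emax, 82.4, tolerance = 1e-6)
  # y at c = EC50 is Emax / 2 on the fitted curve
  expect_equal(fit$emax / (1 + fit$ec50 / fit$ec50), fit$emax / 2)
  expect_warning(fit_inhibition(conc, 140 / (1 + 3.6 / conc)), "120")
})

test_that("ligand-induced BRET subtracts the vehicle ratio pointwise", {
  t <- seq(-300, 2460, 60)
  vehicle <- data.frame(time_s = t, em460 = 1e5, em510 = 1e5 * 0.6)
  ligand <- vehicle
  ligand$em510 <- 1e5 * (0.6 + ifelse(t > 0, 0.05, 0))
  dl <- bret_ligand_induced(ligand, vehicle)
  expect_equal(dl$delta, ifelse(t > 0, 0.05, 0))
  # identical traces give identically zero
  expect_equal(bret_ligand_induced(vehicle, vehicle)$delta, rep(0, length(t)))
  # interpolation onto the ligand grid
  vehicle2 <- data.frame(time_s = seq(-300, 2460, 30), em460 = 1e5,
                         em510 = 1e5 * 0.6)
  expect_equal(bret_ligand_induced(ligand, vehicle2)$delta,
               ifelse(t > 0, 0.05, 0))
  short <- vehicle[vehicle$time_s < 2000, ]
  expect_error(bret_ligand_induced(ligand, short), "misaligned")
})

test_that("windowed relative BRET is exact for matched kinetics and scale-free", {
  cfg <- assay_sim_config(bret_efficacy_ratio = 0.7, noise_frac = 0,
                          seed = 1)
  br <- simulate_bret(cfg)
  dl <- bret_ligand_induced(br$ligand, br$vehicle)
  dr <- bret_ligand_induced(br$reference, br$vehicle)
  expect_equal(bret_relative(dl, dr), 70)
  expect_equal(bret_relative(dr, dr), 100)
  # pointwise scaling scales the relative value
  dl2 <- dr; dl2$delta <- 0.31 * dr$delta
  expect_equal(bret_relative(dl2, dr), 31)
  # invariant under common rescaling of both emission channels
  lig2 <- br$ligand; lig2$em460 <- lig2$em460 * 3; lig2$em510 <- lig2$em510 * 3
  veh2 <- br$vehicle; veh2$em460 <- veh2$em460 * 3; veh2$em510 <- veh2$em510 * 3
  dl3 <- bret_ligand_induced(lig2, veh2)
  expect_equal(bret_relative(dl3, dr), 70)
  expect_error(bret_relative(dl, dr, window = c(5000, 6000)), "window")
})

test_that("parameter recovery: median relative error under 10% across seeds", {
  presets <- ligand_presets()
  p8 <- presets[presets$ligand == "blenniorphin 1-8", ]
  err_ki <- err_ec50 <- err_emax <- numeric(100)
  for (s in 1:100) {
    cfg <- assay_sim_config(true_Ki = p8$ki_nM, true_EC50 = p8$ec50_nM,
                            true_Emax = p8$emax_pct, seed = 1000 + s)
    fb <- fit_binding(simulate_displacement(cfg))
    err_ki[s] <- abs(fb$ki - p8$ki_nM) / p8$ki_nM
    fc <- fit_camp(simulate_camp(cfg))
    err_ec50[s] <- abs(fc$ec50 - p8$ec50_nM) / p8$ec50_nM
    err_emax[s] <- abs(fc$emax - p8$emax_pct) / p8$emax_pct
  }
  expect_lt(median(err_ki), 0.10)
  expect_lt(median(err_ec50), 0.10)
  expect_lt(median(err_emax), 0.10)
})

test_that("summary tables report mean, sample SD and n per ligand", {
  res <- data.frame(
    ligand = rep(c("blenniorphin 1-8", "blenniorphin 1-13"), c(3, 1)),
    experiment = c(1, 2, 3, 1),
    ki = c(3.1, 3.4, 3.3, 110),
    ec50 = c(3.5, 3.8, 3.6, 5.1))
  sm <- assemble_summary(res)
  expect_equal(sm$ki_mean[sm$ligand == "blenniorphin 1-8"], mean(c(3.1, 3.4, 3.3)))
  expect_equal(sm$ki_sd[sm$ligand == "blenniorphin 1-8"], sd(c(3.1, 3.4, 3.3)))
  # single experiment: SD unavailable
  expect_true(is.na(sm$ki_sd[sm$ligand == "blenniorphin 1-13"]))
  expect_equal(sm$n_experiments, c(3L, 1L))
  expect_error(assemble_summary(res[0, ]), "no converged")
})
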