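# Synthetic-data generators: transcriptome fixtures with ground-truth
# manifests, plus simulated binding, cAMP and BRET datasets.
#
# Every generator takes an explicit integer seed and is byte-reproducible
# given that seed. The fixtures emulate the study conditions: precursors
# carrying a 17-residue dynorphin-like core starting with YGGF, embedded at
# random strand/frame/offset in random-nucleotide contigs among motif-free
# decoys; binding counts with Poisson counting noise; HTRF/cAMP and BRET
# readouts with additive Gaussian noise of 3% of the dynamic range.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
           "T","V","W","Y")
.DYNA_CORE <- "YGGFLRRIRPKLKWDNQ"
.FISH_TAXA <- c("Cypriniformes", "Salmoniformes", "Cyprinodontiformes",
                "Perciformes", "Blenniiformes", "Gadiformes",
                "Siluriformes", "Characiformes")

`%||%` <- function(a, b) if (is.null(a)) b else a

.random_aa <- function(n) paste(sample(.AA20, n, replace = TRUE),
                                collapse = "")
.random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Generate dynorphin-like precursor templates
#'
#' Each template carries the human dyn A 1-17 core with positions 5-17
#' independently substituted (by one of the 19 other residues) with
#' probability `mutation_rate`; the N-terminal YGGF motif is never mutated.
#' Flanking precursor sequence is random (N-flank 40-80 residues, C-flank
#' 10-30), emulating unrelated precursor context around the mature peptide.
#'
#' @param seed Integer seed.
#' @param n_species Number of templates (one species each).
#' @param mutation_rate Per-position substitution probability in `[0, 1)`.
#' @return data.frame with columns `species`, `taxon`, `protein`,
#'   `core_start`, `core_end` (1-based inclusive), `core`.
#' @export
make_precursor_set <- function(seed, n_species, mutation_rate = 0) {
  if (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must be in [0, 1)", call. = FALSE)
  if (n_species < 1) stop("n_species must be >= 1", call. = FALSE)
  set.seed(seed)
  out <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    core <- strsplit(.DYNA_CORE, "")[[1]]
    for (p in 5:17) {
      if (stats::runif(1) < mutation_rate) {
        core[p] <- sample(setdiff(.AA20, core[p]), 1)
      }
    }
    core <- paste(core, collapse = "")
    nf <- sample(40:80, 1)
    cf <- sample(10:30, 1)
    out[[i]] <- data.frame(
      species = sprintf("species_%04d", i),
      taxon = sample(.FISH_TAXA, 1),
      protein = paste0(.random_aa(nf), core, .random_aa(cf)),
      core_start = nf + 1L, core_end = nf + 17L, core = core,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Synthetic preprodynorphin-like query precursor
#'
#' A deterministic synthetic stand-in for a preprodynorphin query: an
#' 80-residue precursor with random flanks around the human dyn A 1-17 core
#' at residues 41-57. For real analyses supply the actual precursor of
#' interest (e.g. human preprodynorphin, UniProt P01213, dyn A at residues
#' 207-223) via [query_precursor()].
#'
#' @param seed Integer seed (fixed default so the query is stable).
#' @return A [query_precursor()].
#' @export
make_query_precursor <- function(seed = 773029L) {
  set.seed(seed)
  seq <- paste0(.random_aa(40), .DYNA_CORE, .random_aa(23))
  query_precursor("synthetic_preprodynorphin_like_query", seq, c(41L, 57L))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

# back-translate a protein with uniformly random synonymous codons
# (standard genetic code); uses the current RNG stream
back_translate <- function(protein) {
  inv <- .codon_table()
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) {
    codons <- inv[[a]]
    if (is.null(codons)) stop("cannot back-translate residue: ", a,
                              call. = FALSE)
    codons[sample.int(length(codons), 1)]
  }, character(1)), collapse = "")
}

#' Embed precursor templates in synthetic transcriptome contigs
#'
#' Each template is back-translated with uniformly random synonymous
#' codons and planted at a uniformly random offset, strand and frame in a
#' random-nucleotide contig; decoy contigs are rejection-sampled until none
#' of their six frame translations contains the YGGF motif. The ground
#' truth of every planting is recorded in a manifest.
#'
#' @param templates data.frame from [make_precursor_set()].
#' @param seed Integer seed.
#' @param n_decoys Number of motif-free decoy contigs.
#' @param contig_length Length-2 integer range of contig lengths (nt).
#' @return List with `contigs` (data.frame: id, sequence, species, taxon),
#'   `metadata` (contig_id, species, taxon) and `manifest` (contig_id,
#'   species, taxon, strand, frame, nt_start, nt_end, planted_core).
#' @export
embed_in_contigs <- function(templates, seed, n_decoys = 0L,
                             contig_length = c(900L, 1500L)) {
  set.seed(seed)
  lens <- nchar(templates$protein)
  if (contig_length[1] < max(3L * lens + 6L))
    stop("contig_length too short for the longest precursor", call. = FALSE)
  n <- nrow(templates)
  contigs <- vector("list", n + n_decoys)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    nt <- back_translate(templates$protein[i])
    w <- nchar(nt)
    L <- sample(contig_length[1]:contig_length[2], 1)
    strand <- sample(c("+", "-"), 1)
    p <- sample.int(L - w + 1L, 1)
    insert <- if (strand == "+") nt else .revcomp(nt)
    seqchars <- strsplit(.random_nt(L), "")[[1]]
    seqchars[p:(p + w - 1L)] <- strsplit(insert, "")[[1]]
    frame <- if (strand == "+") (p - 1L) %% 3L else (L - p - w + 1L) %% 3L
    id <- sprintf("contig_%05d", i)
    contigs[[i]] <- data.frame(
      id = id, sequence = paste(seqchars, collapse = ""),
      species = templates$species[i], taxon = templates$taxon[i],
      stringsAsFactors = FALSE)
    manifest[[i]] <- data.frame(
      contig_id = id, species = templates$species[i],
      taxon = templates$taxon[i], strand = strand, frame = frame,
      nt_start = p, nt_end = p + w - 1L,
      planted_core = templates$core[i], stringsAsFactors = FALSE)
  }
  if (n_decoys > 0L) {
    Ls <- sample(contig_length[1]:contig_length[2], n_decoys, replace = TRUE)
    seqs <- vapply(Ls, .random_nt, character(1))
    # rejection-sample until no decoy frame contains the motif
    repeat {
      bad <- colSums(matrix(grepl("YGGF", .six_frame_proteins(seqs),
                                  fixed = TRUE), nrow = 6L)) > 0L
      if (!any(bad)) break
      seqs[bad] <- vapply(Ls[bad], .random_nt, character(1))
    }
    sp <- if (n > 0L) sample(templates$species, n_decoys, replace = TRUE)
      else rep("species_0000", n_decoys)
    tx <- if (n > 0L) templates$taxon[match(sp, templates$species)] else
      rep(.FISH_TAXA[1], n_decoys)
    for (i in seq_len(n_decoys)) {
      contigs[[n + i]] <- data.frame(
        id = sprintf("decoy_%05d", i), sequence = seqs[i], species = sp[i],
        taxon = tx[i], stringsAsFactors = FALSE)
    }
  }
  contigs <- do.call(rbind, contigs)
  rownames(contigs) <- NULL
  manifest <- do.call(rbind, manifest)
  list(contigs = contigs,
       metadata = contigs[, c("id", "species", "taxon")] |>
         stats::setNames(c("contig_id", "species", "taxon")),
       manifest = manifest)
}

#' Assay simulation configuration
#'
#' Collects the generating parameters of the three assay simulators. The
#' defaults are the blenniorphin 1-8 preset (see [ligand_presets()]) with
#' the radioligand conditions of the binding assay: 1 nM tracer with
#' Kd = 0.87 nM, total-binding scale 4000 cpm, nonspecific level 10% of
#' the total. `cpm_per_fmol` stores the detector calibration constant
#' (1 cpm = 38.4 fmol); it is informational and not used by the defaults.
#'
#' @param true_Ki Generating inhibition constant, nM.
#' @param radioligand_conc Free radioligand concentration L, nM.
#' @param radioligand_Kd Radioligand dissociation constant, nM.
#' @param B0 Total-binding cpm scale (zero-displacement plateau).
#' @param NS Nonspecific cpm level (default 10% of `B0`), the plateau at
#'   full displacement as defined operationally by 10 uM naloxone.
#' @param true_EC50 Generating cAMP potency, nM.
#' @param true_Emax Generating cAMP efficacy, percent of the reference
#'   effect at 10 uM.
#' @param bret_efficacy_ratio Ligand BRET amplitude relative to the
#'   reference ligand, in `[0, 1.5]`.
#' @param bret_A_ref Reference-ligand BRET amplitude, acceptor/donor ratio
#'   units.
#' @param bret_baseline_ratio Baseline acceptor/donor emission ratio.
#' @param bret_tau Mono-exponential recruitment time constant, seconds.
#' @param noise_frac Gaussian noise SD as a fraction of the dynamic range
#'   (cAMP and BRET; binding uses Poisson counting noise).
#' @param camp_scale Raw-scale magnitude of the reference cAMP effect.
#' @param n_replicates Replicates per concentration (NULL = per-assay
#'   default: duplicates for binding, triplicates for cAMP).
#' @param seed Default integer seed for the simulators.
#' @param ligand_id Label carried through to datasets.
#' @param cpm_per_fmol Stored calibration constant, cpm per fmol.
#' @return List of class `"assay_sim_config"`.
#' @export
assay_sim_config <- function(true_Ki = 3.30, radioligand_conc = 1,
                             radioligand_Kd = 0.87, B0 = 4000, NS = NULL,
                             true_EC50 = 3.60, true_Emax = 82.4,
                             bret_efficacy_ratio = 0.7, bret_A_ref = 0.10,
                             bret_baseline_ratio = 0.6, bret_tau = 300,
                             noise_frac = 0.03, camp_scale = 1,
                             n_replicates = NULL, seed = 1L,
                             ligand_id = "ligand", cpm_per_fmol = 38.4) {
  NS <- NS %||% (0.1 * B0)
  conc <- c(true_Ki = true_Ki, radioligand_conc = radioligand_conc,
            radioligand_Kd = radioligand_Kd, true_EC50 = true_EC50)
  if (any(conc <= 0))
    stop("all concentrations must be > 0: ",
         paste(names(conc)[conc <= 0], collapse = ", "), call. = FALSE)
  if (bret_efficacy_ratio < 0 || bret_efficacy_ratio > 1.5)
    stop("bret_efficacy_ratio must be in [0, 1.5]", call. = FALSE)
  if (!is.null(n_replicates) && n_replicates < 1)
    stop("n_replicates must be >= 1", call. = FALSE)
  if (noise_frac < 0) stop("noise_frac must be >= 0", call. = FALSE)
  structure(list(
    true_Ki = true_Ki, radioligand_conc = radioligand_conc,
    radioligand_Kd = radioligand_Kd, B0 = B0, NS = NS,
    true_EC50 = true_EC50, true_Emax = true_Emax,
    bret_efficacy_ratio = bret_efficacy_ratio, bret_A_ref = bret_A_ref,
    bret_baseline_ratio = bret_baseline_ratio, bret_tau = bret_tau,
    noise_frac = noise_frac, camp_scale = camp_scale,
    n_replicates = n_replicates, seed = as.integer(seed),
    ligand_id = ligand_id, cpm_per_fmol = cpm_per_fmol),
    class = "assay_sim_config")
}

#' Default logarithmic concentration grids
#'
#' Binding: 12 points over 0.1 nM - 30 uM; cAMP: 13 points over
#' 0.03 nM - 30 uM.
#'
#' @param n Number of points.
#' @return Numeric vector of concentrations in nM.
#' @export
binding_grid <- function(n = 12L) 10^seq(log10(0.1), log10(3e4),
                                         length.out = n)

#' @rdname binding_grid
#' @export
camp_grid <- function(n = 13L) 10^seq(log10(0.03), log10(3e4),
                                      length.out = n)

#' Simulate a competition radioligand displacement experiment
#'
#' Expected bound counts follow the monophasic displacement curve
#' cpm(c) = NS + (B0 - NS) / (1 + c / IC50) with
#' IC50 = Ki (1 + L / Kd); observed counts carry Poisson counting noise.
#'
#' @param cfg An [assay_sim_config()].
#' @param concentrations Inhibitor concentrations, nM (default
#'   [binding_grid()]).
#' @param n_replicates Replicates per concentration (default: duplicates).
#' @param seed Integer seed (default `cfg$seed`).
#' @return List of class `"binding_dataset"`: `data` (data.frame:
#'   concentration_nM, replicate, cpm), `expected` (noise-free curve),
#'   `radioligand_conc`, `radioligand_Kd`, `nonspecific_cpm`, `ic50_true`,
#'   `ligand_id`.
#' @export
simulate_displacement <- function(cfg, concentrations = binding_grid(),
                                  n_replicates = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "assay_sim_config"))
  if (any(concentrations <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  n_replicates <- n_replicates %||% cfg$n_replicates %||% 2L
  set.seed(seed %||% cfg$seed)
  ic50 <- cfg$true_Ki * (1 + cfg$radioligand_conc / cfg$radioligand_Kd)
  mu <- cfg$NS + (cfg$B0 - cfg$NS) / (1 + concentrations / ic50)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      concentration_nM = concentrations)
  obs <- rpois(nrow(grid), mu[match(grid$concentration_nM, concentrations)])
  structure(list(
    data = data.frame(concentration_nM = grid$concentration_nM,
                      replicate = grid$replicate, cpm = obs),
    expected = data.frame(concentration_nM = concentrations, cpm = mu),
    radioligand_conc = cfg$radioligand_conc,
    radioligand_Kd = cfg$radioligand_Kd,
    nonspecific_cpm = cfg$NS, ic50_true = ic50,
    ligand_id = cfg$ligand_id), class = "binding_dataset")
}

#' Simulate a cAMP inhibition concentration-response experiment
#'
#' The generating response, as percent of the reference effect, is the
#' monophasic inhibition curve pct(c) = Emax / (1 + EC50 / c). Raw-scale
#' responses are pct/100 times the reference effect magnitude plus Gaussian
#' noise (`noise_frac` of the reference effect). The reference response at
#' 10 uM is measured in triplicate alongside; by the normalization rule it
#' operationally defines the 100% scale, so `true_Emax` is the exact
#' generating plateau on the normalized scale.
#'
#' @param cfg An [assay_sim_config()].
#' @param concentrations Agonist concentrations, nM (default [camp_grid()]).
#' @param n_replicates Replicates per concentration (default: triplicates).
#' @param seed Integer seed (default `cfg$seed`).
#' @return List of class `"camp_dataset"`: `data` (concentration_nM,
#'   replicate, response on raw scale), `reference_response_at_10uM`,
#'   `ligand_id`.
#' @export
simulate_camp <- function(cfg, concentrations = camp_grid(),
                          n_replicates = 3L, seed = NULL) {
  stopifnot(inherits(cfg, "assay_sim_config"))
  if (any(concentrations <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  set.seed(seed %||% cfg$seed)
  pct <- cfg$true_Emax / (1 + cfg$true_EC50 / concentrations)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      concentration_nM = concentrations)
  mu <- cfg$camp_scale * pct[match(grid$concentration_nM, concentrations)] / 100
  obs <- mu + rnorm(nrow(grid), 0, cfg$noise_frac * cfg$camp_scale)
  ref <- mean(cfg$camp_scale +
                rnorm(3L, 0, cfg$noise_frac * cfg$camp_scale))
  structure(list(
    data = data.frame(concentration_nM = grid$concentration_nM,
                      replicate = grid$replicate, response = obs),
    reference_response_at_10uM = ref,
    ligand_id = cfg$ligand_id), class = "camp_dataset")
}

#' Simulate a BRET beta-arrestin-2 recruitment experiment
#'
#' Three kinetic traces (ligand, vehicle, reference) on a shared time grid
#' with ligand addition at t = 0 after a 300 s baseline. The ligand-induced
#' acceptor/donor ratio rises mono-exponentially,
#' delta(t) = A (1 - exp(-t / tau)) for t > 0 and 0 before addition, with
#' A = `bret_efficacy_ratio` x `bret_A_ref` for the ligand, 0 for vehicle
#' and `bret_A_ref` for the reference. Donor emission (460 nm) is constant;
#' acceptor emission (510 nm) encodes the ratio plus Gaussian noise.
#'
#' @param cfg An [assay_sim_config()].
#' @param timepoints Sampling times in seconds; must include at least two
#'   baseline points before t = 0 and span the 311-2411 s analysis window.
#' @param seed Integer seed (default `cfg$seed`).
#' @return List of class `"bret_experiment"` with elements `ligand`,
#'   `vehicle`, `reference` (each a data.frame: time_s, em460, em510),
#'   `addition_time`, `tau`, `A_ligand`, `A_reference`.
#' @export
simulate_bret <- function(cfg, timepoints = seq(-300, 2460, by = 60),
                          seed = NULL) {
  stopifnot(inherits(cfg, "assay_sim_config"))
  if (sum(timepoints < 0) < 2L)
    stop("missing baseline points: need >= 2 timepoints before addition",
         call. = FALSE)
  if (max(timepoints) < 2411 || min(timepoints[timepoints >= 0]) > 0)
    stop("timepoints must span 0-2411 s", call. = FALSE)
  set.seed(seed %||% cfg$seed)
  donor <- 1e5
  one_trace <- function(A) {
    delta <- ifelse(timepoints > 0, A * (1 - exp(-timepoints / cfg$bret_tau)),
                    0)
    ratio <- cfg$bret_baseline_ratio + delta +
      rnorm(length(timepoints), 0, cfg$noise_frac * cfg$bret_A_ref)
    data.frame(time_s = timepoints, em460 = rep(donor, length(timepoints)),
               em510 = donor * ratio)
  }
  A_lig <- cfg$bret_efficacy_ratio * cfg$bret_A_ref
  structure(list(
    ligand = one_trace(A_lig), vehicle = one_trace(0),
    reference = one_trace(cfg$bret_A_ref), addition_time = 0,
    tau = cfg$bret_tau, A_ligand = A_lig, A_reference = cfg$bret_A_ref),
    class = "bret_experiment")
}
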