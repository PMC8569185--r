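test_that("precursor templates protect the motif and hit the target mutation load", {
  tpl0 <- make_precursor_set(seed = 1, n_species = 5, mutation_rate = 0)
  expect_equal(nrow(tpl0), 5L)
  expect_true(all(tpl0$core == "YGGFLRRIRPKLKWDNQ"))
  expect_identical(substr(tpl0$protein, tpl0$core_start, tpl0$core_end),
                   tpl0$core)

  tpl <- make_precursor_set(seed = 1, n_species = 200, mutation_rate = 0.2)
  expect_true(all(startsWith(tpl$core, "YGGF")))

  # binomial expectation oracle: E[substitutions] = 13 * rate
  big <- make_precursor_set(seed = 1, n_species = 1000, mutation_rate = 0.2)
  nsub <- vapply(big$core, function(co) {
    sum(strsplit(co, "")[[1]] != strsplit("YGGFLRRIRPKLKWDNQ", "")[[1]])
  }, numeric(1), USE.NAMES = FALSE)
  se3 <- 3 * sqrt(13 * 0.2 * 0.8 / 1000)
  expect_lt(abs(mean(nsub) - 2.6), se3)
  expect_error(make_precursor_set(1, 5, mutation_rate = 1.2), "mutation_rate")
})

test_that("planted contigs carry the precursor in the recorded strand and frame", {
  tpl <- make_precursor_set(seed = 2, n_species = 1, mutation_rate = 0)
  fx <- embed_in_contigs(tpl, seed = 3, n_decoys = 0,
                         contig_length = c(700, 900))
  fr <- translate_six_frames(fx$contigs$sequence[1])
  found <- grepl(tpl$protein[1], fr$protein, fixed = TRUE)
  expect_equal(sum(found), 1L)
  mf <- fx$manifest[1, ]
  expect_identical(fr$strand[found], mf$strand)
  expect_equal(fr$frame_offset[found], mf$frame)
  expect_true(mf$nt_start >= 1 &&
                mf$nt_end <= nchar(fx$contigs$sequence[1]))

  # reverse-strand plantings appear in a reverse-complement frame
  rev_seen <- FALSE
  for (s in 4:12) {
    fx2 <- embed_in_contigs(tpl, seed = s, n_decoys = 0,
                            contig_length = c(700, 900))
    if (fx2$manifest$strand[1] == "-") {
      fr2 <- translate_six_frames(fx2$contigs$sequence[1])
      hit <- fr2[grepl(tpl$protein[1], fr2$protein, fixed = TRUE), ]
      expect_identical(hit$strand, "-")
      rev_seen <- TRUE
      break
    }
  }
  expect_true(rev_seen)
  expect_error(embed_in_contigs(tpl, seed = 3, contig_length = c(100, 120)),
               "too short")
})

test_that("simulators are byte-reproducible under a fixed seed", {
  cfg <- assay_sim_config(seed = 99)
  expect_identical(simulate_displacement(cfg), simulate_displacement(cfg))
  expect_identical(simulate_camp(cfg), simulate_camp(cfg))
  expect_identical(simulate_bret(cfg), simulate_bret(cfg))
  tpl <- make_precursor_set(seed = 5, n_species = 3)
  expect_identical(embed_in_contigs(tpl, seed = 6, n_decoys = 2),
                   embed_in_contigs(tpl, seed = 6, n_decoys = 2))
})

test_that("expected displacement follows the closed-form binding curve", {
  cfg <- assay_sim_config(true_Ki = 1, radioligand_conc = 1,
                          radioligand_Kd = 1, B0 = 4000, seed = 1)
  d <- simulate_displacement(cfg, concentrations = c(1e-4, 2, 1e7))
  # IC50 = Ki (1 + L/Kd) = 2 nM; midpoint at c = 2
  expect_equal(d$ic50_true, 2)
  expect_equal(d$expected$cpm[1], 4000, tolerance = 1e-3)
  expect_equal(d$expected$cpm[2], (4000 + 400) / 2)
  expect_equal(d$expected$cpm[3], 400, tolerance = 1e-3)
  # monotone non-increasing expectation
  grid <- simulate_displacement(cfg)
  expect_true(all(diff(grid$expected$cpm) <= 0))
})

test_that("cAMP responses sit at half-max at EC50 and saturate at Emax", {
  cfg <- assay_sim_config(true_EC50 = 5, true_Emax = 100, noise_frac = 0,
                          seed = 1)
  cm <- simulate_camp(cfg, concentrations = c(5, 1e8))
  pct <- normalize_camp(cm$data$response, cm$reference_response_at_10uM)
  expect_equal(pct[cm$data$concentration_nM == 5], rep(50, 3))
  expect_equal(pct[cm$data$concentration_nM == 1e8], rep(100, 3),
               tolerance = 1e-6)
})

test_that("BRET traces encode the mono-exponential ligand-induced signal", {
  cfg <- assay_sim_config(bret_efficacy_ratio = 0.7, noise_frac = 0,
                          seed = 1)
  br <- simulate_bret(cfg)
  dl <- bret_ligand_induced(br$ligand, br$vehicle)
  expect_true(all(dl$delta[dl$time_s <= 0] == 0))
  t_pos <- dl$time_s[dl$time_s > 0]
  expect_equal(dl$delta[dl$time_s > 0],
               br$A_ligand * (1 - exp(-t_pos / br$tau)))
  # zero efficacy: ligand indistinguishable from vehicle
  cfg0 <- assay_sim_config(bret_efficacy_ratio = 0, noise_frac = 0, seed = 1)
  br0 <- simulate_bret(cfg0)
  expect_equal(bret_ligand_induced(br0$ligand, br0$vehicle)$delta,
               rep(0, length(br0$ligand$time_s)))
  expect_error(simulate_bret(cfg, timepoints = seq(0, 2460, 60)), "baseline")
  expect_error(simulate_bret(cfg, timepoints = seq(-300, 1200, 60)), "span")
})

test_that("config invariants are enforced", {
  expect_error(assay_sim_config(true_Ki = -1), "concentrations")
  expect_error(assay_sim_config(bret_efficacy_ratio = 2), "1.5")
  expect_error(assay_sim_config(n_replicates = 0), "n_replicates")
})
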