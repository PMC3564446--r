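test_that("label mass shift is n_cys times the per-label delta", {
  expect_identical(label_mass_shift(2, label_config(nominal = TRUE)), 18)
  expect_identical(label_mass_shift(0, label_config()), 0)
  expect_equal(label_mass_shift(3, label_config()), 27.0906)
  expect_error(label_mass_shift(-1), "non-negative")
})

test_that("locate_envelope sums matched isotopologues and flags absence", {
  cfg <- label_config()
  s <- spectrum(1000, 42)
  expect_equal(as.numeric(locate_envelope(s, 1000, cfg)), 42)
  expect_false(attr(locate_envelope(s, 1000, cfg), "missing"))

  empty <- spectrum()
  r <- locate_envelope(empty, 1000, cfg)
  expect_identical(as.numeric(r), 0)
  expect_true(attr(r, "missing"))

  # noise-free generated envelope: located sum equals generator truth
  pep <- peptide_spec("p", cys_pos = 5, reduced_mz = 1500, n_cys = 1)
  s1 <- gen_spectrum(pep, 0.4, cfg, noise = 0)
  totals <- attr(s1, "envelope_totals")
  i0 <- locate_envelope(s1, pep$reduced_mz, cfg)
  i1 <- locate_envelope(s1, pep$reduced_mz + cfg$per_label_delta, cfg)
  expect_equal(as.numeric(i0), unname(totals["I0"]), tolerance = 1e-9)
  expect_equal(as.numeric(i1), unname(totals["I1"]), tolerance = 1e-9)
})

test_that("percent oxidation follows the label-weighted intensity formula", {
  cfg <- label_config(nominal = TRUE)
  pep <- peptide_spec("gapdh", cys_pos = c(150, 154), reduced_mz = 2161.13)
  s <- spectrum(c(2161.13, 2179.13), c(30, 70))
  expect_equal(quantify_oxidation(s, pep, cfg)$percent_oxidized, 70)

  all_light <- spectrum(2161.13, 100)
  expect_equal(quantify_oxidation(all_light, pep, cfg)$percent_oxidized, 0)

  # full-state mode: I0 = 50, I1 = 50, I2 = 0 over 2 cysteines -> 25%
  s_mid <- spectrum(c(2161.13, 2170.13), c(50, 50))
  q <- quantify_oxidation(s_mid, pep, cfg, mode = "full")
  expect_equal(q$percent_oxidized, 25)

  # no envelope at all -> flagged, no number
  far <- spectrum(500, 10)
  qf <- quantify_oxidation(far, pep, cfg)
  expect_false(qf$quantifiable)
  expect_true(is.na(qf$percent_oxidized))
})

test_that("quantification is scale invariant, bounded, and mode-consistent", {
  cfg <- label_config()
  pep <- peptide_spec("p", cys_pos = c(3, 9), reduced_mz = 1800)
  for (f in c(0, 0.2, 0.55, 1)) {
    s <- gen_spectrum(pep, f, cfg, noise = 0.1, seed = round(100 * f) + 1)
    q1 <- quantify_oxidation(s, pep, cfg)
    s2 <- spectrum(s$mz, s$intensity * 37.5)
    q2 <- quantify_oxidation(s2, pep, cfg)
    expect_equal(q1$percent_oxidized, q2$percent_oxidized)
    expect_gte(q1$percent_oxidized, 0)
    expect_lte(q1$percent_oxidized, 100)
    # two-state spectra have no middle envelope: both modes agree
    qf <- quantify_oxidation(s, pep, cfg, mode = "full")
    expect_equal(q1$percent_oxidized, qf$percent_oxidized,
                 tolerance = 1e-12)
  }
})

test_that("replicate aggregation applies mean, sample SD and the n cutoff", {
  res <- data.frame(peptide = "p1", day = 0,
                    percent_oxidized = c(70, 70, 70))
  agg <- aggregate_replicates(res)
  expect_equal(agg$mean, 70)
  expect_equal(agg$sd, 0)
  expect_equal(agg$n, 3L)

  two <- aggregate_replicates(data.frame(peptide = "p1", day = 0,
                                         percent_oxidized = c(60, 80)))
  expect_true(two$missing)
  expect_true(is.na(two$mean))

  four <- aggregate_replicates(data.frame(peptide = "p1", day = 1,
                                          percent_oxidized = c(26, 22, 28,
                                                               24)))
  expect_equal(four$mean, 25)
  expect_equal(four$sd, sqrt(20 / 3))  # hand-computed sample SD ~ 2.58
  expect_identical(nrow(aggregate_replicates(
    data.frame(peptide = character(), day = numeric(),
               percent_oxidized = numeric()))), 0L)
})

test_that("matrix assembly enforces uniqueness and the strict filter", {
  sched <- timepoint_schedule("standard")
  agg <- data.frame(peptide = rep(c("a", "b"), each = 5),
                    day = rep(0:4, 2),
                    mean = 50, sd = 1, n = 4L, missing = FALSE)
  agg$missing[10] <- TRUE  # peptide b lacks day 4
  agg$mean[10] <- NA
  full <- build_matrix(agg, sched)
  expect_identical(rownames(full$mean), c("a", "b"))
  strict <- build_matrix(agg, sched, strict = TRUE)
  expect_identical(rownames(strict$mean), "a")
  expect_error(build_matrix(rbind(agg, agg[1, ]), sched), "duplicate")

  # strict-set size equals an independent scan of fully observed rows
  sim <- gen_trajectories(sim_config(n_peptides = 120, noise_sd = 5,
                                     missing_rate = 0.1, seed = 3))
  mat <- sim_oxidation_matrix(sim, min_replicates = 4)
  strict2 <- sim_oxidation_matrix(sim, min_replicates = 4, strict = TRUE)
  observed_all <- Reduce(`+`, lapply(sim$replicates,
                                     function(m) !is.na(m))) == 4
  expect_identical(nrow(strict2$mean), sum(rowSums(observed_all) ==
                                             ncol(observed_all)))
  expect_identical(sum(is.na(strict2$mean)), 0L)
  expect_gte(nrow(mat$mean), nrow(strict2$mean))
})
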