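test_that("zero-noise trajectories equal their archetypes and are recovered", {
  for (cond in c("standard", "caloric_restriction")) {
    cfg <- sim_config(n_peptides = 70, label_proportions = equal_props,
                      noise_sd = 0, missing_rate = 0, n_replicates = 2,
                      seed = 42, condition = cond)
    sim <- gen_trajectories(cfg)
    arch <- oxidation_archetypes(cond)
    for (m in sim$replicates)
      expect_equal(unname(m), unname(arch[sim$truth$labels, ]))
    lab <- classify_trajectories(sim$replicates[[1]],
                                 timepoint_schedule(cond))
    expect_identical(unname(lab$labels), unname(sim$truth$labels))
  }
})

test_that("trajectory generation is deterministic in the seed and bounded", {
  cfg <- sim_config(n_peptides = 50, noise_sd = 8, missing_rate = 0.2,
                    seed = 7)
  a <- gen_trajectories(cfg)
  b <- gen_trajectories(cfg)
  expect_identical(a, b)
  c <- gen_trajectories(sim_config(n_peptides = 50, noise_sd = 8,
                                   missing_rate = 0.2, seed = 8))
  expect_false(identical(a$replicates, c$replicates))
  vals <- unlist(a$replicates)
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 100)))
  expect_equal(mean(is.na(vals)), 0.2, tolerance = 0.15)
})

test_that("label proportions control generated truth labels exactly", {
  sim <- gen_trajectories(sim_config(n_peptides = 100,
                                     label_proportions = c(A = 1),
                                     seed = 1))
  expect_identical(unname(sim$truth$labels), rep("A", 100))
  expect_length(sim$truth$labels, 100)
  expect_setequal(names(sim$truth$labels), rownames(sim$truth$values))
  expect_error(sim_config(label_proportions = c(Z = 1)), "unknown archetype")
})

test_that("unboosted peptide libraries match the background; boosted do not", {
  lib0 <- gen_peptide_library(600, planted_cys_boost = 1, seed = 11)
  w0 <- extract_windows(lib0$proteins, lib0$sites)
  counts <- type_counts(w0)
  p_c <- background_aa_freqs()[["C"]]
  n_pos <- sum(counts)
  # cysteine occurrence within 4 binomial SDs of the background rate
  expect_lt(abs(counts[["cysteine"]] - n_pos * p_c),
            4 * sqrt(n_pos * p_c * (1 - p_c)))

  # with the default class proportions the boosted D/E minority stands out
  # while the unboosted majority stays near the library average
  lib3 <- gen_peptide_library(700, planted_cys_boost = 3, seed = 11)
  w3 <- extract_windows(lib3$proteins, lib3$sites)
  grp <- combine_clusters(w3)
  enr <- enrichment(grp$DE, w3)
  expect_gt(enr$ratio[enr$type == "cysteine"], 1.5)
  enr_ab <- enrichment(grp$AB, w3)
  expect_equal(enr_ab$ratio[enr_ab$type == "cysteine"], 1, tolerance = 0.35)
})

test_that("degenerate library inputs are handled", {
  empty <- gen_peptide_library(0)
  expect_length(empty$proteins, 0)
  expect_identical(nrow(empty$sites), 0L)
  expect_error(gen_peptide_library(5, planted_cys_boost = -1), ">= 0")
})

test_that("simulated spectra place envelope weight by oxidation fraction", {
  pep <- peptide_spec("p", cys_pos = c(10, 14), reduced_mz = 2161.13)
  cfg <- label_config()
  s0 <- gen_spectrum(pep, 0, cfg, noise = 0)
  heavy_mz <- pep$reduced_mz + 2 * cfg$per_label_delta
  expect_false(any(abs(s0$mz - heavy_mz) < 0.5 & s0$intensity > 0))

  s7 <- gen_spectrum(pep, 0.7, cfg, noise = 0)
  heavy <- sum(s7$intensity[s7$mz > pep$reduced_mz +
                              cfg$per_label_delta])
  expect_equal(heavy / sum(s7$intensity), 0.7, tolerance = 1e-12)
  expect_true(all(s7$intensity >= 0))
})

test_that("metabolite curves reproduce the condition physiology", {
  for (seed in c(1, 5, 9)) {
    ms <- gen_metabolites("standard", seed = seed)
    expect_gt(mean_lifespan(ms), 6)
    expect_lt(mean_lifespan(ms), 8)
  }
  ms <- gen_metabolites("standard", seed = 2)
  mc <- gen_metabolites("caloric_restriction", seed = 2)
  expect_equal(as.numeric(condition_delay(ms, mc)), 48, tolerance = 25)
  # ATP maintained at or near the day-0 level deep into stationary phase
  expect_true(all(ms$atp[ms$day <= 5] > 0.95 * ms$atp[1]))
  expect_true(all(mc$atp[mc$day <= 7] > 0.95 * mc$atp[1]))
  # water: no NADPH decline, no E_GSH shift, flat general-oxidation class
  mw <- gen_metabolites("water", seed = 2)
  expect_true(is.na(nadph_decline_onset(mw)))
  expect_true(is.na(egsh_shift_day(mw)))
  arch_w <- oxidation_archetypes("water")
  expect_lt(max(arch_w["A", ]), 30)
  expect_error(gen_metabolites("mars"), "arg")
})
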