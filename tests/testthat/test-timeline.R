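test_that("mean lifespan interpolates the first 50% viability crossing", {
  v <- data.frame(day = 0:4, viability = c(100, 100, 100, 48, 0))
  expect_equal(mean_lifespan(v), 2 + 50 / 52)  # ~2.96
  exact <- data.frame(day = 0:7,
                      viability = c(rep(100, 7), 50))
  expect_equal(mean_lifespan(exact), 7)
  never <- data.frame(day = 0:4, viability = c(100, 99, 98, 97, 96))
  ml <- mean_lifespan(never)
  expect_true(is.na(ml))
  expect_true(attr(ml, "undefined"))
  expect_error(mean_lifespan(data.frame(day = 0:1, viability = c(40, 30))),
               "50")
})

test_that("collapse day is when the A/B median first exceeds 50%", {
  ref <- reference_panel()
  sched <- timepoint_schedule("standard")
  arch <- oxidation_archetypes("standard")
  extra <- arch[rep("A", 5), ]
  rownames(extra) <- paste0("arch", 1:5)
  mat <- oxidation_matrix(rbind(ref$std$mean, extra), condition = "standard",
                          days = 0:4)
  a <- classify_trajectories(mat, sched)
  expect_equal(collapse_day(mat, a), 3)

  crsim <- gen_trajectories(sim_config(140, seed = 2,
                                       condition = "caloric_restriction"))
  crmat <- sim_oxidation_matrix(crsim)
  crmat <- impute_missing(crmat)
  acr <- classify_trajectories(crmat,
                               timepoint_schedule("caloric_restriction"))
  expect_equal(collapse_day(crmat, acr), 5)

  allf <- matrix(10, 4, 5, dimnames = list(paste0("p", 1:4),
                                           paste0("D", 0:4)))
  fmat <- oxidation_matrix(allf, days = 0:4)
  fa <- classify_trajectories(fmat, sched)
  expect_true(is.na(collapse_day(fmat, fa)))
})

test_that("the standard-condition timeline is ordered as in aging yeast", {
  res <- run_pipeline(seed = 3, n_peptides = 200)
  tl <- res$standard$timeline
  expect_identical(tl$event[tl$defined],
                   c("nadph_decline", "egsh_shift", "early_oxidation_onset",
                     "redox_collapse", "viability_50"))
  d <- setNames(tl$day, tl$event)
  expect_true(d["nadph_decline"] <= d["egsh_shift"])
  expect_true(d["egsh_shift"] <= d["early_oxidation_onset"])
  expect_true(d["early_oxidation_onset"] <= d["redox_collapse"])
  expect_true(d["redox_collapse"] <= d["viability_50"])
  expect_true(all(tl$lag_h[-1][tl$defined[-1]] >= 0))
})

test_that("caloric restriction delays each event by about 48 h", {
  res <- run_pipeline(seed = 4, n_peptides = 200)
  std <- res$standard$timeline
  cr <- res$caloric_restriction$timeline
  for (ev in c("nadph_decline", "egsh_shift", "early_oxidation_onset",
               "redox_collapse")) {
    delay <- 24 * (cr$day[cr$event == ev] - std$day[std$event == ev])
    expect_equal(delay, 48, tolerance = 24 / 48)  # within one sampling step
  }
  # lifespan extension is larger still
  expect_gt(cr$day[cr$event == "viability_50"],
            std$day[std$event == "viability_50"] + 2)
})

test_that("water-shifted cultures show no collapse within 10 days", {
  res <- run_pipeline(seed = 5, n_peptides = 120, conditions = "water")
  tl <- res$water$timeline
  expect_false(tl$defined[tl$event == "redox_collapse"])
  expect_false(tl$defined[tl$event == "nadph_decline"])
  expect_gt(tl$day[tl$event == "viability_50"], 10)
})

test_that("timeline ordering survives metabolite unit rescaling", {
  met <- gen_metabolites("standard", seed = 6)
  sim <- gen_trajectories(sim_config(120, seed = 6))
  mat <- impute_missing(sim_oxidation_matrix(sim))
  a <- classify_trajectories(mat, sim$schedule)
  t1 <- build_timeline(met, mat, a)
  met2 <- met
  met2$nadph <- met2$nadph * 1000   # different assay units
  met2$gsh_M <- met2$gsh_M          # concentrations unchanged
  t2 <- build_timeline(met2, mat, a)
  expect_identical(t1$event, t2$event)
  expect_equal(t1$day, t2$day)
})

test_that("a fixed seed reproduces the pipeline byte for byte", {
  d1 <- file.path(tempdir(), "run1")
  d2 <- file.path(tempdir(), "run2")
  run_pipeline(seed = 11, n_peptides = 60, out_dir = d1)
  run_pipeline(seed = 11, n_peptides = 60, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
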