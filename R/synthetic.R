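#' Oxidation-trajectory archetypes for the seven classes
#'
#' One noise-free percent-oxidation trajectory per class (A-G) on the
#' condition's sampling schedule. Under standard and caloric-restriction
#' cultivation each archetype satisfies its own classification rule under
#' zero noise: A/B start low and collapse on the collapse/late day, C
#' starts near 50\% and rises at collapse, D/E rise at the first/second
#' early day, F stays reduced, G stays oxidized. Under the hypometabolic
#' water condition the same peptide classes are emulated as staying
#' reduced (no collapse through day 10), so their rule labels are not
#' recoverable by design.
#'
#' @param condition cultivation condition.
#' @return numeric matrix (7 x days), rownames A-G, colnames day labels.
#' @export
oxidation_archetypes <- function(condition = c("standard",
                                               "caloric_restriction",
                                               "water")) {
  condition <- match.arg(condition)
  rows <- switch(condition,
    standard = rbind(
      A = c(20, 22, 24, 78, 85),
      B = c(20, 21, 22, 30, 70),
      C = c(50, 52, 56, 80, 85),
      D = c(15, 40, 60, 80, 85),
      E = c(15, 18, 50, 80, 85),
      F = c(8, 8, 8, 8, 8),
      G = c(85, 88, 90, 92, 92)),
    caloric_restriction = rbind(
      A = c(20, 21, 22, 23, 24, 78, 85),
      B = c(20, 20, 21, 22, 23, 30, 70),
      C = c(50, 52, 54, 56, 58, 80, 85),
      D = c(15, 16, 18, 40, 60, 80, 85),
      E = c(15, 16, 18, 20, 50, 80, 85),
      F = c(8, 8, 8, 8, 8, 8, 8),
      G = c(85, 86, 88, 90, 90, 92, 92)),
    water = rbind(
      A = c(20, 20, 21, 22, 23, 24, 25, 26, 27, 27, 28),
      B = c(15, 15, 15, 16, 16, 17, 17, 18, 18, 19, 19),
      C = c(48, 48, 47, 47, 46, 46, 45, 45, 44, 44, 43),
      D = c(18, 22, 24, 25, 25, 26, 26, 27, 27, 28, 28),
      E = c(18, 20, 24, 22, 20, 19, 19, 18, 18, 18, 18),
      F = c(8, 8, 8, 8, 8, 8, 8, 8, 8, 8, 8),
      G = c(85, 85, 86, 86, 87, 87, 88, 88, 88, 89, 89)))
  colnames(rows) <- day_labels(timepoint_schedule(condition))
  rows
}

#' Default class proportions
#'
#' Mirrors the published distribution of trajectory classes: the three
#' collapse classes hold over 70\% of peptides (A the largest), the early
#' risers about 10\% combined, about 8\% remain reduced (F) and the rest
#' stay oxidized (G).
#'
#' @return named numeric vector over A-G, summing to 1.
#' @export
default_label_proportions <- function() {
  c(A = 0.35, B = 0.15, C = 0.20, D = 0.05, E = 0.05, F = 0.08, G = 0.12)
}

#' Simulation configuration for trajectory generation
#'
#' @param n_peptides number of trajectories to generate.
#' @param label_proportions named fractions per archetype label, summing
#'   to 1 (default [default_label_proportions()]). Counts are apportioned
#'   deterministically by largest remainder.
#' @param noise_sd additive Gaussian noise per observation, percentage
#'   points.
#' @param n_replicates biological replicates.
#' @param missing_rate independent per-cell missingness probability.
#' @param seed RNG seed (mandatory; the generators keep no global state).
#' @param condition cultivation condition defining the schedule.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_peptides = 300L,
                       label_proportions = NULL,
                       noise_sd = 5, n_replicates = 4L, missing_rate = 0.1,
                       seed = 1L, condition = "standard") {
  if (is.null(label_proportions))
    label_proportions <- default_label_proportions()
  if (!all(names(label_proportions) %in% CLUSTER_LABELS))
    stop("unknown archetype label(s): ",
         paste(setdiff(names(label_proportions), CLUSTER_LABELS),
               collapse = ", "))
  stopifnot(abs(sum(label_proportions) - 1) < 1e-8, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1, n_replicates >= 1,
            n_peptides >= 0)
  structure(list(n_peptides = as.integer(n_peptides),
                 label_proportions = label_proportions,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 missing_rate = missing_rate, seed = as.integer(seed),
                 schedule = timepoint_schedule(condition)),
            class = "sim_config")
}

# deterministic largest-remainder apportionment of n among proportions
apportion <- function(n, props) {
  raw <- props * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(short)]] <- counts[o[seq_len(short)]] + 1L
  }
  as.integer(counts)
}

#' Generate replicate oxidation trajectories with known class labels
#'
#' Each peptide is drawn from one archetype; every replicate observation
#' is the archetype value plus iid Gaussian noise (`noise_sd` percentage
#' points), clipped to [0, 100], with cells masked missing independently
#' at `missing_rate`. Identical config (including seed) gives bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return object of class `trajectory_sim`: list with `replicates` (list
#'   of peptide x day matrices, NAs at masked cells), `truth` (list:
#'   `labels` named character, `values` noise-free matrix), `config`,
#'   `schedule`.
#' @export
gen_trajectories <- function(config = sim_config()) {
  sched <- config$schedule
  arch <- oxidation_archetypes(sched$condition)
  props <- config$label_proportions
  counts <- apportion(config$n_peptides, props)
  labels <- rep(names(props), counts)
  ids <- sprintf("pep%04d", seq_along(labels))
  names(labels) <- ids
  truth_values <- arch[labels, , drop = FALSE]
  rownames(truth_values) <- ids
  nr <- nrow(truth_values); nc <- ncol(truth_values)
  replicates <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_replicates), function(r) {
      m <- truth_values +
        matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
      m <- pmin(pmax(m, 0), 100)
      if (config$missing_rate > 0)
        m[matrix(stats::runif(nr * nc) < config$missing_rate, nr, nc)] <-
          NA_real_
      m
    })
  })
  structure(list(replicates = replicates,
                 truth = list(labels = labels, values = truth_values),
                 config = config, schedule = sched),
            class = "trajectory_sim")
}

#' Collapse a trajectory simulation into an oxidation matrix
#'
#' Pools the replicate matrices into long form and applies the standard
#' replicate aggregation (mean/SD/count with the `min_replicates` mask).
#'
#' @param sim a `trajectory_sim` from [gen_trajectories()].
#' @param min_replicates reproducibility cutoff per peptide-day.
#' @param strict keep only fully observed peptides (see [build_matrix()]).
#' @return an [oxidation_matrix()].
#' @export
sim_oxidation_matrix <- function(sim, min_replicates = 3L, strict = FALSE) {
  days <- sim$schedule$days
  long <- do.call(rbind, lapply(sim$replicates, function(m) {
    data.frame(peptide = rep(rownames(m), times = length(days)),
               day = rep(days, each = nrow(m)),
               percent_oxidized = as.vector(m))
  }))
  build_matrix(aggregate_replicates(long, min_replicates), sim$schedule,
               strict = strict)
}

#' Background amino-acid frequencies (approximate yeast proteome)
#' @return named numeric vector over the 20 standard residues, summing to 1.
#' @export
background_aa_freqs <- function() {
  c(A = 0.055, R = 0.044, N = 0.061, D = 0.058, C = 0.013, Q = 0.039,
    E = 0.064, G = 0.050, H = 0.022, I = 0.066, L = 0.096, K = 0.073,
    M = 0.021, F = 0.045, P = 0.044, S = 0.090, T = 0.059, W = 0.010,
    Y = 0.034, V = 0.056)
}

#' Generate a protein library with planted cysteine-proximity effects
#'
#' Synthesizes one protein per peptide: residues iid from
#' `background_freqs`, a central identified cysteine at a known position,
#' and — for peptides carrying one of the `boost_labels` — a flanking
#' window (5 residues up- and downstream) drawn from the background with
#' the cysteine probability multiplied by `planted_cys_boost` and the
#' remaining residues renormalized. This plants the extra-cysteine
#' proximity signal the sequence-context stage is meant to recover.
#'
#' @param n number of peptides/proteins.
#' @param background_freqs named probabilities over the 20 residues.
#' @param planted_cys_boost multiplicative boost (>= 0); 1 = null case.
#' @param boost_labels archetype labels receiving the boost.
#' @param label_proportions named label fractions (default
#'   [default_label_proportions()]).
#' @param protein_length length of each synthetic protein.
#' @param flank flanking width of the boosted window.
#' @param seed RNG seed.
#' @return list with `proteins` (named character), `sites` (data.frame
#'   `peptide`, `protein`, `cys_pos`, `label`).
#' @export
gen_peptide_library <- function(n, background_freqs = background_aa_freqs(),
                                planted_cys_boost = 1,
                                boost_labels = c("D", "E"),
                                label_proportions = NULL,
                                protein_length = 61L, flank = 5L,
                                seed = 1L) {
  if (planted_cys_boost < 0) stop("planted_cys_boost must be >= 0")
  stopifnot(abs(sum(background_freqs) - 1) < 1e-6,
            protein_length >= 2 * flank + 1)
  if (is.null(label_proportions))
    label_proportions <- default_label_proportions()
  empty <- list(proteins = character(),
                sites = data.frame(peptide = character(),
                                   protein = character(),
                                   cys_pos = integer(), label = character()))
  if (n == 0L) return(empty)
  aas <- names(background_freqs)
  boosted <- background_freqs
  boosted["C"] <- boosted["C"] * planted_cys_boost
  boosted <- boosted / sum(boosted)
  labels <- rep(names(label_proportions),
                apportion(n, label_proportions))
  withr::with_seed(seed, {
    cys_pos <- sample((flank + 1L):(protein_length - flank), n,
                      replace = TRUE)
    proteins <- vapply(seq_len(n), function(i) {
      res <- sample(aas, protein_length, replace = TRUE,
                    prob = background_freqs)
      win <- setdiff(
        seq(cys_pos[i] - flank, cys_pos[i] + flank), cys_pos[i])
      if (labels[i] %in% boost_labels && planted_cys_boost != 1)
        res[win] <- sample(aas, length(win), replace = TRUE, prob = boosted)
      res[cys_pos[i]] <- "C"
      paste(res, collapse = "")
    }, character(1))
  })
  prot_ids <- sprintf("prot%04d", seq_len(n))
  names(proteins) <- prot_ids
  list(proteins = proteins,
       sites = data.frame(peptide = sprintf("pep%04d", seq_len(n)),
                          protein = prot_ids, cys_pos = cys_pos,
                          label = labels))
}

#' Simulate a light/heavy ICAT label-pair spectrum
#'
#' Emits one isotopologue envelope per labelling state k (k heavy tags) at
#' `reduced_mz + k * delta / charge`. State weights follow the two-state
#' model by default — all-light weight `1 - f`, all-heavy weight `f`,
#' matching cysteines that oxidize as a unit — or, with `mode = "full"`,
#' binomial weights over all k. The envelope shape is an averagine-like
#' binomial in the peptide mass; multiplicative Gaussian noise (relative
#' SD `noise`) is applied per peak and truncated at zero.
#'
#' @param pep a [peptide_spec()].
#' @param oxidation_fraction true oxidized fraction f in [0, 1].
#' @param cfg a [label_config()].
#' @param noise relative SD of per-peak multiplicative noise.
#' @param seed RNG seed.
#' @param mode `"two_state"` or `"full"`.
#' @param base_intensity summed intensity of the whole pattern.
#' @return a [spectrum()] with attribute `envelope_totals` (noise-free
#'   per-state totals, for round-trip checks).
#' @export
gen_spectrum <- function(pep, oxidation_fraction, cfg = label_config(),
                         noise = 0.05, seed = 1L,
                         mode = c("two_state", "full"),
                         base_intensity = 1e5) {
  mode <- match.arg(mode)
  stopifnot(oxidation_fraction >= 0, oxidation_fraction <= 1,
            pep$n_cys >= 1, noise >= 0)
  f <- oxidation_fraction
  n <- pep$n_cys
  ks <- 0:n
  w <- if (mode == "two_state") {
    ww <- numeric(n + 1); ww[1] <- 1 - f; ww[n + 1] <- f; ww
  } else stats::dbinom(ks, n, f)
  n_iso <- cfg$n_isotopologues
  mass <- pep$reduced_mz * pep$charge          # crude neutral-mass proxy
  p_iso <- min(0.95, mass * 6e-4 / (n_iso - 1L))
  shape <- stats::dbinom(0:(n_iso - 1L), n_iso - 1L, p_iso)
  mz <- as.vector(outer(ISOTOPE_SPACING * (0:(n_iso - 1L)) / pep$charge,
                        pep$reduced_mz + ks * cfg$per_label_delta /
                          pep$charge, "+"))
  ideal <- base_intensity * as.vector(outer(shape, w))
  intensity <- if (noise > 0) {
    withr::with_seed(seed,
      pmax(0, ideal * (1 + stats::rnorm(length(ideal), 0, noise))))
  } else ideal
  keep <- ideal > 0
  s <- spectrum(mz[keep], intensity[keep])
  attr(s, "envelope_totals") <- stats::setNames(
    base_intensity * w, paste0("I", ks))
  s
}

#' Simulate metabolite and viability time series
#'
#' Emulates the qualitative redox-metabolite physiology of chronologically
#' aging yeast: NADPH rises through the diauxic shift (~12 h) and then
#' declines, with the decline delayed by ~48 h under caloric restriction
#' and absent under water; the glutathione couple is chosen so that E_GSH
#' (Nernst, E0 = -240 mV) rises by >= 15 mV by day 1 (standard) / day 3
#' (CR) and stays near baseline in water; ATP is maintained at or above
#' the day-0 level through day 5 (standard) / day 7 (CR); viability is a
#' logistic survival curve with 50\% crossings near day 7 / 11 / 16
#' (standard / CR / water). Standard cultures reproduce the unexplained
#' day-4 NADP(H) rebound as a shape feature.
#'
#' @param condition cultivation condition.
#' @param seed RNG seed.
#' @param noise relative SD of multiplicative noise on metabolite
#'   concentrations; viability receives additive noise of `2 * noise * 10`
#'   percentage points, clipped to [0, 100].
#' @return object of class `metabolite_series`: data.frame `day`, `gsh_M`,
#'   `gssg_M`, `nadph`, `nadp`, `atp`, `viability` with attribute
#'   `condition`.
#' @export
gen_metabolites <- function(condition = c("standard", "caloric_restriction",
                                          "water"),
                            seed = 1L, noise = 0.02) {
  condition <- match.arg(condition)
  days <- if (condition == "water") c(0, 0.5, 1:18) else c(0, 0.5, 1:12)
  interp <- function(at, val) stats::approx(at, val, xout = days,
                                            rule = 2)$y
  gsh <- rep(0.01, length(days))               # ~10 mM intracellular GSH
  curves <- switch(condition,
    standard = list(
      egsh = interp(c(0, 0.5, 1, 2, 3, 5, 12),
                    c(-240, -239, -222, -215, -205, -200, -195)),
      nadph = interp(c(0, 0.5, 1, 2, 3, 4, 5, 7, 12),
                     c(1.0, 1.4, 0.9, 0.65, 0.55, 0.85, 0.7, 0.55, 0.4)),
      nadp = interp(c(0, 0.5, 3, 4, 5, 12),
                    c(1.0, 1.05, 1.0, 1.3, 1.05, 0.9)),
      atp = interp(c(0, 2, 4, 5, 7, 12),
                   c(1.0, 1.2, 1.25, 1.05, 0.7, 0.4)),
      t50 = 7),
    caloric_restriction = list(
      egsh = interp(c(0, 1, 2, 3, 5, 7, 12),
                    c(-240, -236, -229, -222, -210, -203, -196)),
      nadph = interp(c(0, 0.5, 1, 2, 3, 4, 5, 7, 12),
                     c(1.0, 1.5, 1.45, 1.35, 1.05, 0.95, 0.8, 0.65, 0.5)),
      nadp = interp(c(0, 0.5, 12), c(1.0, 1.05, 0.95)),
      atp = interp(c(0, 2, 4, 7, 9, 12),
                   c(1.0, 1.15, 1.3, 1.1, 0.8, 0.5)),
      t50 = 11),
    water = list(
      egsh = interp(c(0, 2, 18), c(-240, -234, -230)),
      nadph = interp(c(0, 0.5, 1, 18), c(1.0, 1.1, 1.0, 0.92)),
      nadp = interp(c(0, 18), c(1.0, 0.95)),
      atp = interp(c(0, 2, 18), c(1.0, 0.9, 0.5)),
      t50 = 16))
  slope_mv <- 1000 * GAS_CONSTANT * 303.15 / (2 * FARADAY)
  gssg <- gsh^2 * exp((curves$egsh - (-240)) / slope_mv)
  viability <- 100 / (1 + exp((days - curves$t50) / 0.7))
  out <- withr::with_seed(seed, {
    jitter <- function(v) v * (1 + stats::rnorm(length(v), 0, noise))
    data.frame(day = days,
               gsh_M = jitter(gsh), gssg_M = jitter(gssg),
               nadph = jitter(curves$nadph), nadp = jitter(curves$nadp),
               atp = jitter(curves$atp),
               viability = pmin(100, pmax(0, viability +
                 stats::rnorm(length(days), 0, 20 * noise))))
  })
  structure(out, condition = condition,
            class = c("metabolite_series", "data.frame"))
}
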