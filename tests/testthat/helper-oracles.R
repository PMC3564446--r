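# Independent oracles used across tests.

# Pearson chi-square computed from first principles (sum (O-E)^2 / E).
pearson_oracle <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# equal proportions over the seven classes
equal_props <- stats::setNames(rep(1 / 7, 7), CLUSTER_LABELS)

# single noisy replicate matrix on the standard schedule
one_replicate <- function(n, noise_sd = 5, seed = 1,
                          condition = "standard",
                          label_proportions = NULL) {
  sim <- gen_trajectories(sim_config(
    n_peptides = n, noise_sd = noise_sd, missing_rate = 0,
    n_replicates = 1, seed = seed, condition = condition,
    label_proportions = label_proportions))
  list(m = sim$replicates[[1]], truth = sim$truth, schedule = sim$schedule)
}
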