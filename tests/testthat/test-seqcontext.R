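test_that("window extraction slices 5 residues each side, truncating at ends", {
  w <- extract_window("ACDEFCHIKLM", 6)
  expect_identical(w$window, "ACDEFCHIKLM")
  expect_identical(w$cys_index, 6L)
  expect_identical(w$length, 11L)

  wt <- extract_window("ACDEF", 2)
  expect_identical(wt$window, "ACDEF")  # 1 upstream, 3 downstream
  expect_identical(wt$cys_index, 2L)
  expect_identical(wt$length, 5L)

  expect_error(extract_window("ACDEF", 3), "not C")
  expect_error(extract_window("ACDEF", 9), "outside")

  # generated library windows match a brute-force substring oracle
  lib <- gen_peptide_library(40, seed = 6)
  w40 <- extract_windows(lib$proteins, lib$sites)
  for (i in seq_len(10)) {
    seq <- lib$proteins[[lib$sites$protein[i]]]
    p <- lib$sites$cys_pos[i]
    expect_identical(w40$window[i],
                     substr(seq, max(1, p - 5), min(nchar(seq), p + 5)))
  }
})

test_that("residue typing partitions the 20 amino acids", {
  expect_identical(aa_type("C"), "cysteine")
  expect_identical(aa_type("D"), "negative")
  expect_identical(aa_type("H"), "positive")
  expect_identical(aa_type("G"), "nonpolar")
  all20 <- names(background_aa_freqs())
  types <- aa_type(all20)
  expect_false(anyNA(types))
  expect_setequal(unique(types), AA_TYPES)
  expect_error(aa_type("X"), "nonstandard")
  expect_true(is.na(aa_type("X", on_nonstandard = "skip")))
})

test_that("enrichment self-normalizes and averages to one", {
  lib <- gen_peptide_library(120, seed = 8)
  w <- extract_windows(lib$proteins, lib$sites)
  self <- enrichment(w, w)
  expect_equal(self$ratio, rep(1, 6))

  sub <- w[1:40, ]
  e <- enrichment(sub, w)
  # frequency-weighted mean of ratios is 1 for any cluster
  expect_equal(sum(e$ratio * e$library_freq, na.rm = TRUE), 1,
               tolerance = 1e-12)
  expect_error(enrichment(w[0, ], w), "empty")
})

test_that("chi-square comparisons match a first-principles Pearson oracle", {
  lib <- gen_peptide_library(80, seed = 9)
  w <- extract_windows(lib$proteins, lib$sites)
  same <- cluster_chisq(w[1:30, ], w[1:30, ])
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$df, 5L)
  expect_identical(cluster_chisq(w[1:30, ], w[31:60, ],
                                 include_cys = FALSE)$df, 4L)

  tab <- rbind(a = c(10, 20, 30, 40, 50, 60), b = c(60, 50, 40, 30, 20, 10))
  fake_counts <- function(row) {
    # windows whose flanking residues realize the requested type counts
    res <- c(rep("C", row[1]), rep("K", row[2]), rep("D", row[3]),
             rep("S", row[4]), rep("A", row[5]), rep("F", row[6]))
    data.frame(window = paste0("C", paste(res, collapse = "")),
               cys_index = 1L, length = length(res) + 1L)
  }
  got <- cluster_chisq(fake_counts(tab[1, ]), fake_counts(tab[2, ]))
  expect_equal(got$statistic, pearson_oracle(tab), tolerance = 1e-9)
  expect_identical(unname(got$observed["a", ]),
                   c(10L, 20L, 30L, 40L, 50L, 60L))

  # symmetry in the two groups
  sw <- cluster_chisq(w[1:25, ], w[26:80, ])
  ws <- cluster_chisq(w[26:80, ], w[1:25, ])
  expect_equal(sw$statistic, ws$statistic)
  expect_equal(sw$p_value, ws$p_value)
  expect_error(cluster_chisq(w[0, ], w), "non-empty")
})

test_that("cluster merging pools windows additively", {
  w <- data.frame(peptide = paste0("p", 1:6),
                  label = c("A", "A", "A", "B", "B", "D"),
                  window = "CAAAA", cys_index = 1L, length = 5L)
  g <- combine_clusters(w)
  expect_identical(nrow(g$AB), 5L)
  expect_identical(nrow(g$DE), 1L)  # empty E: DE reduces to D
  expect_equal(type_counts(g$AB),
               type_counts(w[w$label == "A", ]) +
                 type_counts(w[w$label == "B", ]))
  expect_error(combine_clusters(w, list(XY = c("X", "Y"))), "unknown")
})

test_that("position frequency tables are aligned on the cysteine and sum to 1", {
  lib <- gen_peptide_library(50, seed = 10)
  w <- extract_windows(lib$proteins, lib$sites)
  pf <- position_frequencies(w)
  expect_identical(pf$position, -5:5)
  expect_equal(unname(rowSums(pf[, -1])), rep(1, 11))
  expect_equal(pf$C[pf$position == 0], 1)  # central residue is always C
})
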