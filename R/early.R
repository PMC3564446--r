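#' Flag the days of an early-oxidation trajectory
#'
#' A day `d` is flagged when its oxidation is at least 2-fold the day-0
#' level, or at least 1.5-fold the day-0 level while exceeding 60\% total
#' oxidation ("exceeding" read strictly). With day 0 exactly zero every
#' fold is undefined and no day can be flagged by the fold branches; the
#' mask is then all-`NA` to report the undefined folds.
#'
#' @param traj numeric vector of percent oxidation, day 0 first (named
#'   `D0, ...` or positional); `NA` days yield `NA` flags.
#' @param fold_hi,fold_lo the two fold thresholds.
#' @param abs_hi absolute oxidation the lower fold must exceed, percent.
#' @return logical vector, same length/names as `traj`; day 0 is `FALSE`.
#' @examples
#' flag_cells(c(12, 24, 58, 87, 86))  # FALSE TRUE TRUE TRUE TRUE
#' @export
flag_cells <- function(traj, fold_hi = 2, fold_lo = 1.5, abs_hi = 60) {
  v <- as.numeric(traj)
  if (is.na(v[1L])) stop("day-0 value missing")
  v0 <- v[1L]
  if (v0 == 0) {
    out <- rep(NA, length(v))
  } else {
    out <- v >= fold_hi * v0 | (v >= fold_lo * v0 & v > abs_hi)
    out[1L] <- FALSE
  }
  names(out) <- names(traj)
  out
}

#' Early-oxidation targets across cultivation conditions
#'
#' The union, over the supplied per-condition assignments, of peptides
#' classified as early risers (class D or E). A peptide qualifying under
#' either condition is an early target; peptides following the general
#' collapse pattern (class A/B) under both are excluded.
#'
#' @param ... one or more `cluster_assignment` objects (or named label
#'   vectors), e.g. standard and caloric restriction.
#' @return character vector of peptide ids.
#' @export
identify_early_targets <- function(...) {
  assignments <- list(...)
  if (length(assignments) == 0L) stop("at least one assignment required")
  hits <- lapply(assignments, function(a) {
    labels <- if (inherits(a, "cluster_assignment")) a$labels else a
    names(labels)[labels %in% c("D", "E")]
  })
  sort(unique(unlist(hits)))
}

#' Summaries of the early-target set
#'
#' Reports, for the identified early targets: how many exceed
#' `day2_threshold` percent oxidation at day 2 under standard conditions,
#' the range of their day-2 versus day-0 fold changes, the per-peptide
#' day-flag masks, and the overlap with a peroxide-sensitivity
#' annotation.
#'
#' @param targets character vector of early-target peptide ids.
#' @param matrix_std the standard-condition [oxidation_matrix()].
#' @param annotations optional data.frame `peptide`,
#'   `peroxide_sensitive` (0/1 or logical).
#' @param day2_threshold percent threshold (strict) for the day-2 count.
#' @return list: `n_targets`, `n_day2_above`, `fold_day2` (named vector,
#'   `NA` where day 0 is 0), `fold_range` (min/max over the above-threshold
#'   subset), `flags` (logical matrix), `n_peroxide_sensitive`.
#' @export
summarize_early <- function(targets, matrix_std, annotations = NULL,
                            day2_threshold = 45) {
  targets <- intersect(targets, rownames(matrix_std$mean))
  m <- matrix_std$mean[targets, , drop = FALSE]
  if (!"D2" %in% colnames(m)) stop("standard matrix lacks a D2 column")
  d0 <- m[, "D0"]
  d2 <- m[, "D2"]
  fold <- ifelse(!is.na(d0) & d0 > 0, d2 / d0, NA_real_)
  above <- !is.na(d2) & d2 > day2_threshold
  flags <- t(apply(m, 1L, flag_cells))
  n_perox <- if (is.null(annotations)) NA_integer_ else {
    sens <- annotations$peptide[as.logical(annotations$peroxide_sensitive)]
    length(intersect(targets, sens))
  }
  list(n_targets = length(targets),
       n_day2_above = sum(above),
       fold_day2 = fold,
       fold_range = if (any(above & !is.na(fold)))
         range(fold[above], na.rm = TRUE) else c(NA_real_, NA_real_),
       flags = flags,
       n_peroxide_sensitive = n_perox)
}

#' Curated reference panel of aging-yeast oxidation trajectories
#'
#' Loads the packaged panel of 29 cysteine-containing peptides with
#' published per-day percent thiol oxidation under standard and
#' caloric-restriction cultivation, together with peroxide-sensitivity
#' annotations and the flag marking the peptide that follows the general
#' oxidation pattern (a comparison row, not an early target). Peptides
#' not determined under caloric restriction carry `NA` there.
#'
#' @return list with `std` and `cr` [oxidation_matrix()] objects (CR rows
#'   with no data dropped from `cr`), `annotations` (data.frame `peptide`,
#'   `peroxide_sensitive`), `general_pattern` (peptide ids), `info`
#'   (full annotation data.frame).
#' @export
reference_panel <- function() {
  path <- system.file("extdata", "early_oxidation_panel.tsv",
                      package = "redoxtime", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "nd", "NA"))
  std_cols <- paste0("std_D", 0:4)
  cr_cols <- paste0("cr_D", c(0:5, 7))
  std <- as.matrix(df[std_cols])
  dimnames(std) <- list(df$peptide, paste0("D", 0:4))
  cr <- as.matrix(df[cr_cols])
  dimnames(cr) <- list(df$peptide, paste0("D", c(0:5, 7)))
  cr <- cr[rowSums(!is.na(cr)) > 0L, , drop = FALSE]
  list(std = oxidation_matrix(std, condition = "standard", days = 0:4),
       cr = oxidation_matrix(cr, condition = "caloric_restriction",
                             days = c(0:5, 7)),
       annotations = df[c("peptide", "peroxide_sensitive")],
       general_pattern = df$peptide[df$general_pattern == 1],
       info = df)
}
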