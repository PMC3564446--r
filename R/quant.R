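#' ICAT labelling parameters
#'
#' The cysteine-reactive ICAT tag comes in a light (12C) and a heavy (13C)
#' form. Each labelled cysteine therefore shifts the peptide mass by one
#' light/heavy mass difference; a peptide with `n` cysteines appears as up
#' to `n + 1` envelopes spaced by `per_label_delta / charge` on the m/z
#' axis. The default delta is the 9 x 13C-12C difference (9.0302 Da);
#' `nominal = TRUE` uses 9.0 exactly, matching integer-rounded worked
#' examples.
#'
#' @param per_label_delta light/heavy mass difference per labelled
#'   cysteine, Da.
#' @param nominal if `TRUE`, use 9.0 Da exactly.
#' @param light_tag_mass mass added by one light tag, Da (informational).
#' @param n_isotopologues number of isotopologue peaks summed per envelope.
#' @param mz_tolerance peak-matching tolerance, Da.
#' @param charge assumed charge state (the pipeline quantifies at a fixed
#'   charge; the printed worked example is singly protonated).
#' @return object of class `label_config`.
#' @examples
#' label_config()$per_label_delta          # 9.0302
#' label_config(nominal = TRUE)$per_label_delta  # 9
#' @export
label_config <- function(per_label_delta = 9.0302, nominal = FALSE,
                         light_tag_mass = 227.1270, n_isotopologues = 5L,
                         mz_tolerance = 0.1, charge = 1L) {
  if (nominal) per_label_delta <- 9.0
  stopifnot(per_label_delta > 0, n_isotopologues >= 1, mz_tolerance > 0,
            charge >= 1)
  structure(list(per_label_delta = per_label_delta,
                 light_tag_mass = light_tag_mass,
                 n_isotopologues = as.integer(n_isotopologues),
                 mz_tolerance = mz_tolerance, charge = as.integer(charge)),
            class = "label_config")
}

#' Peptide specification for quantification
#'
#' @param id peptide id.
#' @param protein protein id.
#' @param cys_pos 1-based cysteine residue positions in the protein.
#' @param reduced_mz m/z of the all-light (fully reduced in vivo)
#'   monoisotopic peak.
#' @param charge charge state.
#' @param n_cys number of cysteines (defaults to `length(cys_pos)`).
#' @return object of class `peptide_spec`.
#' @export
peptide_spec <- function(id, protein = NA_character_, cys_pos = integer(),
                         reduced_mz, charge = 1L, n_cys = length(cys_pos)) {
  stopifnot(n_cys >= 1, reduced_mz > 0, !anyDuplicated(cys_pos))
  structure(list(id = id, protein = protein, cys_pos = as.integer(cys_pos),
                 n_cys = as.integer(n_cys), reduced_mz = reduced_mz,
                 charge = as.integer(charge)),
            class = "peptide_spec")
}

#' Centroided spectrum
#'
#' @param mz,intensity numeric vectors; intensities must be non-negative.
#'   Peaks are sorted by m/z on construction.
#' @return object of class `spectrum`: a data.frame with columns `mz`,
#'   `intensity`.
#' @export
spectrum <- function(mz = numeric(), intensity = numeric()) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  o <- order(mz)
  structure(data.frame(mz = mz[o], intensity = intensity[o]),
            class = c("spectrum", "data.frame"))
}

# mass of one 13C-12C isotopologue spacing, Da
ISOTOPE_SPACING <- 1.00335

#' Mass shift from heavy versus light labelling
#'
#' A peptide whose `n_cys` cysteines all carry heavy tags is
#' `n_cys * per_label_delta` heavier than the all-light form (18 Da for a
#' 2-cysteine peptide at the nominal 9 Da per label).
#'
#' @param n_cys number of labelled cysteines (>= 0).
#' @param cfg a [label_config()].
#' @return mass shift in Da.
#' @examples
#' label_mass_shift(2, label_config(nominal = TRUE))  # 18
#' @export
label_mass_shift <- function(n_cys, cfg = label_config()) {
  if (n_cys < 0) stop("n_cys must be non-negative")
  n_cys * cfg$per_label_delta
}

#' Sum one isotopologue envelope around a target m/z
#'
#' Takes the most intense peak within `mz_tolerance` of each of the first
#' `n_isotopologues` isotopologue positions
#' `target_mz + j * 1.00335 / charge`, j = 0.. , and sums them. If no peak
#' matches the monoisotopic position the envelope is considered absent:
#' the summed intensity is 0 and the result is flagged, never an error.
#'
#' @param s a [spectrum()].
#' @param target_mz monoisotopic m/z of the envelope.
#' @param cfg a [label_config()].
#' @return numeric intensity with attribute `missing` (logical).
#' @export
locate_envelope <- function(s, target_mz, cfg = label_config()) {
  pos <- target_mz + (seq_len(cfg$n_isotopologues) - 1L) *
    ISOTOPE_SPACING / cfg$charge
  top <- vapply(pos, function(p) {
    hit <- which(abs(s$mz - p) <= cfg$mz_tolerance)
    if (length(hit) == 0L) 0 else max(s$intensity[hit])
  }, numeric(1))
  mono_hit <- any(abs(s$mz - pos[1L]) <= cfg$mz_tolerance)
  structure(if (mono_hit) sum(top) else 0, missing = !mono_hit)
}

#' Percent thiol oxidation from a light/heavy envelope pair
#'
#' In differential thiol trapping, in vivo reduced cysteines carry the
#' light tag and in vivo oxidized cysteines (reduced in vitro) carry the
#' heavy tag, so the intensity ratio of the envelope pair reads out the
#' fraction of the peptide population that was oxidized in vivo. For a
#' peptide with `n` cysteines the envelope carrying `k` heavy labels sits
#' at `reduced_mz + k * delta / charge`; percent oxidation is the
#' label-weighted fraction `100 * sum(k * I_k) / (n * sum(I_k))`.
#'
#' `mode = "two_state"` (default) uses only the all-light and all-heavy
#' envelopes (k = 0 and k = n), appropriate when the cysteines oxidize as
#' a unit, e.g. an intramolecular disulfide couple; `mode = "full"` uses
#' every labelling state.
#'
#' @param s a [spectrum()].
#' @param pep a [peptide_spec()].
#' @param cfg a [label_config()].
#' @param mode `"two_state"` or `"full"`.
#' @return A one-row data.frame (class `quant_result`): `peptide`,
#'   `percent_oxidized`, summed state intensities `I0..In`,
#'   `quantifiable`, `missing_envelopes`, `low_signal`.
#' @examples
#' cfg <- label_config(nominal = TRUE)
#' pep <- peptide_spec("gapdh", cys_pos = c(150, 154), reduced_mz = 2161.13)
#' s <- spectrum(c(2161.13, 2179.13), c(30, 70))
#' quantify_oxidation(s, pep, cfg)$percent_oxidized  # 70
#' @export
quantify_oxidation <- function(s, pep, cfg = label_config(),
                               mode = c("two_state", "full")) {
  mode <- match.arg(mode)
  n <- pep$n_cys
  ks <- if (mode == "two_state") c(0L, n) else 0:n
  cfg$charge <- pep$charge
  env <- lapply(ks, function(k) {
    locate_envelope(s, pep$reduced_mz + k * cfg$per_label_delta / pep$charge,
                    cfg)
  })
  I <- vapply(env, as.numeric, numeric(1))
  miss <- vapply(env, function(e) attr(e, "missing"), logical(1))
  total <- sum(I)
  pct <- if (total > 0) 100 * sum(ks * I) / (n * total) else NA_real_
  out <- data.frame(peptide = pep$id, percent_oxidized = pct,
                    quantifiable = total > 0,
                    missing_envelopes = sum(miss),
                    low_signal = total > 0 && total < .Machine$double.eps)
  Imat <- matrix(NA_real_, 1L, n + 1L,
                 dimnames = list(NULL, paste0("I", 0:n)))
  Imat[1L, ks + 1L] <- I
  out <- cbind(out, as.data.frame(Imat))
  class(out) <- c("quant_result", "data.frame")
  out
}

#' Aggregate replicate quantifications per peptide and day
#'
#' Arithmetic mean and sample SD over the quantifiable replicates of each
#' peptide-day; a peptide-day with fewer quantified replicates than
#' `min_replicates` is masked as missing. The default cutoff of 3
#' implements the reproducibility filter of keeping only peptides seen in
#' at least three biological replicates.
#'
#' @param results data.frame with columns `peptide`, `day`,
#'   `percent_oxidized` (NA = not quantifiable), one row per replicate
#'   observation.
#' @param min_replicates minimum quantified replicates per peptide-day.
#' @return data.frame `peptide`, `day`, `mean`, `sd`, `n`, `missing`.
#' @export
aggregate_replicates <- function(results, min_replicates = 3L) {
  if (nrow(results) == 0L) {
    return(data.frame(peptide = character(), day = numeric(),
                      mean = numeric(), sd = numeric(), n = integer(),
                      missing = logical()))
  }
  stopifnot(all(c("peptide", "day", "percent_oxidized") %in% names(results)))
  key <- interaction(results$peptide, results$day, drop = TRUE)
  rows <- lapply(split(results, key), function(g) {
    v <- g$percent_oxidized[!is.na(g$percent_oxidized)]
    n <- length(v)
    data.frame(peptide = g$peptide[1L], day = g$day[1L],
               mean = if (n >= min_replicates) mean(v) else NA_real_,
               sd = if (n >= max(2L, min_replicates)) stats::sd(v)
                    else NA_real_,
               n = n, missing = n < min_replicates)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$peptide, out$day), , drop = FALSE]
}

#' Assemble aggregated values into an oxidation matrix
#'
#' @param aggregates output of [aggregate_replicates()].
#' @param schedule a [timepoint_schedule()]; aggregate days must be a
#'   subset of its sampled days.
#' @param strict if `TRUE`, keep only peptides quantified (unmasked) at
#'   every sampled day — the "reproducibly identified in all samples" set.
#' @return an [oxidation_matrix()].
#' @export
build_matrix <- function(aggregates, schedule, strict = FALSE) {
  days <- schedule$days
  if (!all(aggregates$day %in% days))
    stop("aggregate days outside the schedule: ",
         paste(setdiff(unique(aggregates$day), days), collapse = ", "))
  if (anyDuplicated(aggregates[c("peptide", "day")]))
    stop("duplicate peptide-day entries")
  peps <- unique(aggregates$peptide)
  shape <- function(field, default) {
    m <- matrix(default, length(peps), length(days),
                dimnames = list(peps, paste0("D", days)))
    i <- cbind(match(aggregates$peptide, peps),
               match(aggregates$day, days))
    m[i] <- aggregates[[field]]
    m
  }
  mean <- shape("mean", NA_real_)
  mean[shape("missing", TRUE)] <- NA_real_
  x <- oxidation_matrix(mean, sd = shape("sd", NA_real_),
                        n = shape("n", 0L),
                        condition = schedule$condition, days = days)
  if (strict) x <- subset_peptides(x, rowSums(is.na(x$mean)) == 0L)
  x
}
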