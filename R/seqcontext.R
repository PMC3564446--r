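#' Default residue-to-type mapping
#'
#' Six amino-acid types: cysteine on its own, negatively charged (D, E),
#' positively charged (K, R, H), aromatic (F, W, Y), polar uncharged
#' (S, T, N, Q) and nonpolar (A, V, L, I, M, P, G). Histidine is counted
#' as positive and glycine as nonpolar; pass a modified vector to change
#' the mapping.
#'
#' @return named character vector, residue -> type.
#' @export
aa_type_map <- function() {
  c(C = "cysteine",
    D = "negative", E = "negative",
    K = "positive", R = "positive", H = "positive",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    S = "polar", T = "polar", N = "polar", Q = "polar",
    A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
    M = "nonpolar", P = "nonpolar", G = "nonpolar")
}

#' All type names, in canonical order
#' @export
AA_TYPES <- c("cysteine", "positive", "negative", "polar", "nonpolar",
              "aromatic")

#' Type of one amino-acid residue
#'
#' @param residue one-letter code(s).
#' @param map residue-to-type mapping, see [aa_type_map()].
#' @param on_nonstandard `"error"` (default) or `"skip"` (returns `NA`).
#' @return character type(s).
#' @export
aa_type <- function(residue, map = aa_type_map(),
                    on_nonstandard = c("error", "skip")) {
  on_nonstandard <- match.arg(on_nonstandard)
  out <- unname(map[toupper(residue)])
  if (anyNA(out) && on_nonstandard == "error")
    stop("nonstandard residue(s): ",
         paste(unique(residue[is.na(out)]), collapse = ", "))
  out
}

#' Extract the flanking window around an identified cysteine
#'
#' Up to `flank` residues up- and downstream of the cysteine (11-mer for
#' the default flank of 5), truncated — not padded — at the protein
#' termini.
#'
#' @param protein_seq protein sequence (character or `AAString`).
#' @param cys_pos 1-based position of the cysteine; must be a `C`.
#' @param flank flanking width.
#' @return list of class `sequence_window`: `window` (string), `cys_index`
#'   (position of the central C within the window), `length`.
#' @export
extract_window <- function(protein_seq, cys_pos, flank = 5L) {
  seq <- as.character(protein_seq)
  len <- nchar(seq)
  if (cys_pos < 1 || cys_pos > len)
    stop("cys_pos ", cys_pos, " outside sequence of length ", len)
  if (substr(seq, cys_pos, cys_pos) != "C")
    stop("residue at position ", cys_pos, " is ",
         substr(seq, cys_pos, cys_pos), ", not C")
  from <- max(1L, cys_pos - flank)
  to <- min(len, cys_pos + flank)
  w <- substr(seq, from, to)
  structure(list(window = w, cys_index = as.integer(cys_pos - from + 1L),
                 length = nchar(w)),
            class = "sequence_window")
}

#' Windows for every site of a library
#'
#' @param proteins named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @param sites data.frame with `peptide`, `protein`, `cys_pos` and
#'   optionally `label`.
#' @param flank flanking width.
#' @return data.frame `peptide`, `label`, `window`, `cys_index`, `length`.
#' @export
extract_windows <- function(proteins, sites, flank = 5L) {
  seqs <- stats::setNames(as.character(proteins), names(proteins))
  ws <- lapply(seq_len(nrow(sites)), function(i) {
    extract_window(seqs[[sites$protein[i]]], sites$cys_pos[i], flank)
  })
  data.frame(peptide = sites$peptide,
             label = if ("label" %in% names(sites)) sites$label
                     else NA_character_,
             window = vapply(ws, `[[`, character(1), "window"),
             cys_index = vapply(ws, `[[`, integer(1), "cys_index"),
             length = vapply(ws, `[[`, integer(1), "length"))
}

# flanking residues of a window set, central cysteine excluded
flanking_residues <- function(windows) {
  unlist(lapply(seq_len(nrow(windows)), function(i) {
    res <- strsplit(windows$window[i], "")[[1L]]
    res[-windows$cys_index[i]]
  }), use.names = FALSE)
}

#' Amino-acid-type counts of a window set
#'
#' Counts flanking positions by type; the central identified cysteine is
#' never counted. With `include_cys = FALSE` all cysteine residues are
#' removed from the tally (5 types, as in the cysteine-free comparison).
#'
#' @param windows data.frame from [extract_windows()].
#' @param include_cys keep flanking cysteines as their own type?
#' @param map residue-to-type mapping.
#' @return named integer vector over [AA_TYPES] (cysteine dropped when
#'   `include_cys = FALSE`).
#' @export
type_counts <- function(windows, include_cys = TRUE, map = aa_type_map()) {
  types <- aa_type(flanking_residues(windows), map)
  keep <- if (include_cys) AA_TYPES else setdiff(AA_TYPES, "cysteine")
  if (!include_cys) types <- types[types != "cysteine"]
  tab <- table(factor(types, levels = keep))
  stats::setNames(as.integer(tab), keep)
}

#' Amino-acid-type enrichment of a cluster versus the whole library
#'
#' Ratio of the type's relative occurrence among the cluster's flanking
#' residues to its relative occurrence in the entire window library
#' (central cysteines excluded from both). 1 means the type occurs
#' exactly as often as in the library; the frequency-weighted mean of the
#' ratios is 1 by construction.
#'
#' @param cluster_windows,library_windows window data.frames; the library
#'   must contain the cluster.
#' @param map residue-to-type mapping.
#' @return data.frame `type`, `cluster_freq`, `library_freq`, `ratio`
#'   (`NA` where the library frequency is zero).
#' @export
enrichment <- function(cluster_windows, library_windows,
                       map = aa_type_map()) {
  if (nrow(cluster_windows) == 0L) stop("empty cluster")
  cc <- type_counts(cluster_windows, TRUE, map)
  lc <- type_counts(library_windows, TRUE, map)
  cf <- cc / sum(cc)
  lf <- lc / sum(lc)
  data.frame(type = AA_TYPES,
             cluster_freq = unname(cf), library_freq = unname(lf),
             ratio = unname(ifelse(lf > 0, cf / lf, NA_real_)))
}

#' Chi-square comparison of two clusters' type distributions
#'
#' Pearson chi-square on the 2 x k contingency table of amino-acid-type
#' counts of the two window sets (k = 6 with flanking cysteines included,
#' df = 5; k = 5 with cysteines removed, df = 4), without continuity
#' correction.
#'
#' @param windows_a,windows_b window data.frames.
#' @param include_cys include flanking cysteines as a type?
#' @param map residue-to-type mapping.
#' @return list `statistic`, `df`, `p_value`, `observed` (2 x k matrix).
#' @export
cluster_chisq <- function(windows_a, windows_b, include_cys = TRUE,
                          map = aa_type_map()) {
  if (nrow(windows_a) == 0L || nrow(windows_b) == 0L)
    stop("both window sets must be non-empty")
  tab <- rbind(a = type_counts(windows_a, include_cys, map),
               b = type_counts(windows_b, include_cys, map))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("zero expected count; merge sparse types before testing")
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = unname(fit$p.value), observed = tab)
}

#' Pool windows of merged clusters
#'
#' Combines classes with similar trajectories to increase sample size,
#' e.g. A with B and D with E (the defaults).
#'
#' @param windows window data.frame with a `label` column.
#' @param merge_map named list: merged label -> component labels.
#' @return named list of window data.frames, one per merged label;
#'   labels not mentioned in `merge_map` keep their own group.
#' @export
combine_clusters <- function(windows,
                             merge_map = list(AB = c("A", "B"),
                                              DE = c("D", "E"))) {
  all_merged <- unlist(merge_map)
  bad <- setdiff(all_merged, c(CLUSTER_LABELS, "unassigned"))
  if (length(bad)) stop("unknown labels in merge_map: ",
                        paste(bad, collapse = ", "))
  groups <- merge_map
  for (l in setdiff(unique(windows$label), all_merged))
    groups[[l]] <- l
  lapply(groups, function(members)
    windows[windows$label %in% members, , drop = FALSE])
}

#' Per-position residue frequency table of aligned windows
#'
#' Logo-style output: windows aligned on the central cysteine, relative
#' residue frequency per alignment position (positions -flank..+flank;
#' truncated windows contribute only the positions they cover).
#'
#' @param windows window data.frame.
#' @param flank flanking width used at extraction.
#' @return data.frame: `position` (-flank..flank), one column per residue
#'   observed, frequencies summing to 1 per row.
#' @export
position_frequencies <- function(windows, flank = 5L) {
  pos_res <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    res <- strsplit(windows$window[i], "")[[1L]]
    data.frame(position = seq_along(res) - windows$cys_index[i],
               residue = res)
  }))
  tab <- table(pos_res$position, pos_res$residue)
  freq <- tab / rowSums(tab)
  out <- data.frame(position = as.integer(rownames(tab)))
  cbind(out, as.data.frame.matrix(freq))
}
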