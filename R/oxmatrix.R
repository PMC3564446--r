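#' Per-condition oxidation matrix
#'
#' Container for peptide x day percent-oxidation summaries of one
#' cultivation condition: mean percent oxidation (0-100), sample SD and the
#' number of quantified replicates per peptide-day. Missing peptide-days
#' (fewer replicates than the reproducibility cutoff) are `NA` in `mean`
#' and 0/`NA` in `n`/`sd`; the SD is `NA` whenever fewer than two
#' replicates contributed.
#'
#' @param mean numeric matrix (peptides x days) of mean percent oxidation;
#'   rownames are peptide ids, colnames day labels `D0, D1, ...`.
#' @param sd,n matrices of the same shape (may be `NULL`, e.g. for
#'   noise-free synthetic data, in which case `n` defaults to 1 observation
#'   everywhere and `sd` to `NA`).
#' @param condition cultivation condition string.
#' @param days numeric vector of sampled days, matching the columns.
#' @return object of class `oxidation_matrix`.
#' @export
oxidation_matrix <- function(mean, sd = NULL, n = NULL,
                             condition = "standard",
                             days = NULL) {
  mean <- as.matrix(mean)
  if (is.null(days)) {
    if (is.null(colnames(mean)))
      stop("`days` missing and matrix has no day-label colnames")
    days <- as.numeric(sub("^D", "", colnames(mean)))
  }
  days <- as.numeric(days)
  if (anyNA(days)) stop("unparseable day labels")
  colnames(mean) <- paste0("D", days)
  if (is.null(rownames(mean)))
    rownames(mean) <- sprintf("pep%04d", seq_len(nrow(mean)))
  ok <- mean[is.finite(mean)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 100))
    stop("mean percent oxidation outside [0, 100]")
  if (is.null(n)) {
    n <- matrix(ifelse(is.na(mean), 0L, 1L), nrow(mean),
                dimnames = dimnames(mean))
  }
  if (is.null(sd)) {
    sd <- matrix(NA_real_, nrow(mean), ncol(mean), dimnames = dimnames(mean))
  }
  sd[!is.na(n) & n < 2] <- NA_real_
  stopifnot(identical(dim(mean), dim(sd)), identical(dim(mean), dim(n)))
  structure(list(condition = condition, days = days,
                 mean = mean, sd = sd, n = n),
            class = "oxidation_matrix")
}

#' @export
print.oxidation_matrix <- function(x, ...) {
  cat("<oxidation_matrix> ", x$condition, ": ", nrow(x$mean), " peptides x ",
      length(x$days), " days (", paste0("D", x$days, collapse = " "), "); ",
      sum(is.na(x$mean)), " missing cells\n", sep = "")
  invisible(x)
}

#' @export
dim.oxidation_matrix <- function(x) dim(x$mean)

#' Subset an oxidation matrix by peptide
#' @param x an `oxidation_matrix`.
#' @param peptides row indices or peptide ids.
#' @return an `oxidation_matrix` restricted to those peptides.
#' @export
subset_peptides <- function(x, peptides) {
  oxidation_matrix(x$mean[peptides, , drop = FALSE],
                   x$sd[peptides, , drop = FALSE],
                   x$n[peptides, , drop = FALSE],
                   condition = x$condition, days = x$days)
}

#' Write / read an oxidation matrix as TSV
#'
#' One file per condition with columns `peptide`, `D0..Dk` (mean percent),
#' `sd_D0..` and `n_D0..`. Missing cells are empty fields.
#'
#' @param x an `oxidation_matrix`.
#' @param path file path.
#' @return `write_oxidation_matrix` returns `path` invisibly;
#'   `read_oxidation_matrix` returns an `oxidation_matrix`.
#' @export
write_oxidation_matrix <- function(x, path) {
  dl <- paste0("D", x$days)
  df <- data.frame(peptide = rownames(x$mean), x$mean,
                   check.names = FALSE)
  sd <- x$sd; colnames(sd) <- paste0("sd_", dl)
  n <- x$n; colnames(n) <- paste0("n_", dl)
  df <- cbind(df, sd, n)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_oxidation_matrix
#' @param condition condition recorded in the returned object.
#' @export
read_oxidation_matrix <- function(path, condition = "standard") {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  dl <- grep("^D[0-9]+$", names(df), value = TRUE)
  if (length(dl) == 0L) stop("no day columns (D0, D1, ...) in ", path)
  days <- as.numeric(sub("^D", "", dl))
  pick <- function(prefix) {
    cols <- paste0(prefix, dl)
    if (all(cols %in% names(df))) {
      m <- as.matrix(df[cols]); dimnames(m) <- list(df$peptide, dl); m
    } else NULL
  }
  m <- as.matrix(df[dl]); dimnames(m) <- list(df$peptide, dl)
  oxidation_matrix(m, sd = pick("sd_"), n = pick("n_"),
                   condition = condition, days = days)
}
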