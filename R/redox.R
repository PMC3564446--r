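#' @name constants
#' @title Physical constants used in the Nernst computation
#' @description Gas constant in J/(mol K) and Faraday constant in C/mol.
#' @export
GAS_CONSTANT <- 8.314462

#' @rdname constants
#' @export
FARADAY <- 96485.332

#' Glutathione-couple redox potential (Nernst equation)
#'
#' For the 2-electron GSH/GSSG couple,
#' `E = E0 + 1000 * (R T / 2 F) * ln(GSSG / GSH^2)` in mV, with
#' concentrations in molar and the standard potential E0 = -240 mV. At the
#' 30 C cultivation temperature (303.15 K) the slope is 13.062 mV per
#' ln-unit; E equals E0 exactly when GSSG/GSH^2 = 1 per molar.
#'
#' @param gsh,gssg molar concentrations (> 0).
#' @param temperature Kelvin.
#' @param e0 standard potential, mV.
#' @return potential in mV.
#' @examples
#' egsh(1e-2, 1e-4)             # -240
#' egsh(1e-3, 1e-4)             # -240 + 13.062 * log(100) ~ -179.8
#' @export
egsh <- function(gsh, gssg, temperature = 303.15, e0 = -240) {
  if (any(gsh <= 0) || any(gssg <= 0))
    stop("GSH and GSSG concentrations must be positive")
  stopifnot(temperature > 0)
  e0 + 1000 * GAS_CONSTANT * temperature / (2 * FARADAY) *
    log(gssg / gsh^2)
}

#' First day with a pro-oxidizing E_GSH shift
#'
#' Computes E_GSH per day from a metabolite series and returns the first
#' day whose potential sits at least `threshold_mv` above the first
#' sampled day. Days with missing GSH or GSSG are skipped with a warning.
#'
#' @param series a [gen_metabolites()]-style data.frame (`day`, `gsh_M`,
#'   `gssg_M`).
#' @param threshold_mv shift threshold, mV.
#' @param temperature Kelvin, passed to [egsh()].
#' @return day (numeric) or `NA` if the shift never occurs.
#' @export
egsh_shift_day <- function(series, threshold_mv = 15, temperature = 303.15) {
  stopifnot(nrow(series) >= 2)
  ok <- !is.na(series$gsh_M) & !is.na(series$gssg_M)
  if (any(!ok)) warning(sum(!ok), " day(s) missing GSH/GSSG, skipped")
  s <- series[ok, , drop = FALSE]
  e <- egsh(s$gsh_M, s$gssg_M, temperature)
  hit <- which(e - e[1L] >= threshold_mv)
  if (length(hit) == 0L) NA_real_ else s$day[hit[1L]]
}

#' Onset of the NADPH decline
#'
#' First sampled day after the series maximum at which NADPH has dropped
#' to at most `(1 - drop_frac)` of the maximum. Invariant to uniform
#' rescaling of the NADPH unit. Returns `NA` for series that never
#' decline that far.
#'
#' @param series data.frame with `day` and `nadph`.
#' @param drop_frac fractional drop defining "declined".
#' @return day or `NA`.
#' @examples
#' s <- data.frame(day = 0:3, nadph = c(1, 2, 1.4, 1))
#' nadph_decline_onset(s)  # 2
#' @export
nadph_decline_onset <- function(series, drop_frac = 0.2) {
  stopifnot(!is.null(series$nadph), drop_frac > 0, drop_frac < 1)
  v <- series$nadph
  imax <- which.max(v)
  after <- seq_along(v) > imax
  hit <- which(after & v <= (1 - drop_frac) * v[imax])
  if (length(hit) == 0L) NA_real_ else series$day[hit[1L]]
}

#' Delay of a metabolic event under caloric restriction
#'
#' Applies `metric` (a function of a series returning an onset day, e.g.
#' [nadph_decline_onset()] or [egsh_shift_day()]) to both conditions and
#' returns the caloric-restriction delay in hours, `24 * (cr - std)`.
#' `NA` (flagged) when either onset is undefined.
#'
#' @param series_std,series_cr metabolite series for the two conditions.
#' @param metric function mapping a series to an onset day.
#' @return hours (numeric), or `NA` with attribute `undefined = TRUE`.
#' @export
condition_delay <- function(series_std, series_cr,
                            metric = nadph_decline_onset) {
  a <- metric(series_std)
  b <- metric(series_cr)
  if (is.na(a) || is.na(b))
    return(structure(NA_real_, undefined = TRUE))
  24 * (b - a)
}

#' Write / read a metabolite series TSV
#'
#' Columns `day, gsh_M, gssg_M, nadph, nadp, atp, viability`.
#' @param series a `metabolite_series` data.frame.
#' @param path file path.
#' @param condition condition recorded on read.
#' @return the path (write, invisibly) or a `metabolite_series` (read).
#' @export
write_metabolites <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolites
#' @export
read_metabolites <- function(path, condition = "standard") {
  df <- utils::read.delim(path)
  stopifnot("day" %in% names(df))
  structure(df, condition = condition,
            class = c("metabolite_series", "data.frame"))
}
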