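#' Mean lifespan from a viability curve
#'
#' Linear interpolation of the first crossing of 50\% viability. A day at
#' exactly 50\% is itself the crossing.
#'
#' @param series data.frame with `day` and `viability` (percent), or a
#'   `metabolite_series`.
#' @return fractional day, or `NA` (flagged via attribute `undefined`)
#'   when the curve never reaches 50\%.
#' @examples
#' mean_lifespan(data.frame(day = 0:4,
#'                          viability = c(100, 100, 100, 48, 0)))  # ~2.96
#' @export
mean_lifespan <- function(series) {
  d <- series$day
  v <- series$viability
  if (v[1L] < 50) stop("viability must start at or above 50%")
  below <- which(v <= 50)
  if (length(below) == 0L) return(structure(NA_real_, undefined = TRUE))
  i <- below[1L]
  if (v[i] == 50) return(d[i])
  d[i - 1L] + (v[i - 1L] - 50) / (v[i - 1L] - v[i]) * (d[i] - d[i - 1L])
}

#' Day of the global redox collapse
#'
#' First sampled day at which the median oxidation of the
#' general-collapse peptides (classes A and B) exceeds 50\%.
#'
#' @param matrix an [oxidation_matrix()].
#' @param assignment a `cluster_assignment` (or named label vector) for
#'   the same peptides.
#' @return day, or `NA` if there are no A/B peptides or the median never
#'   exceeds 50\%.
#' @export
collapse_day <- function(matrix, assignment) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  ab <- names(labels)[labels %in% c("A", "B")]
  ab <- intersect(ab, rownames(matrix$mean))
  if (length(ab) == 0L) return(NA_real_)
  med <- apply(matrix$mean[ab, , drop = FALSE], 2L, stats::median,
               na.rm = TRUE)
  hit <- which(med > 50)
  if (length(hit) == 0L) NA_real_ else matrix$days[hit[1L]]
}

#' Onset of early protein oxidation
#'
#' First of the schedule's candidate early days at which any early-riser
#' peptide (class D or E) satisfies the early-rise criterion (at least
#' `early_fold` times its day-0 oxidation and at least `early_abs_min`
#' points above it) — the same criterion, evaluated at the same days,
#' that defines classes D and E.
#'
#' @param matrix an [oxidation_matrix()].
#' @param assignment `cluster_assignment` or named label vector.
#' @param schedule a [timepoint_schedule()] supplying the early days.
#' @param rules a [cluster_rules()].
#' @return day or `NA`.
#' @export
early_oxidation_onset <- function(matrix, assignment,
                                  schedule = timepoint_schedule(
                                    matrix$condition),
                                  rules = cluster_rules()) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  de <- intersect(names(labels)[labels %in% c("D", "E")],
                  rownames(matrix$mean))
  if (length(de) == 0L) return(NA_real_)
  m <- matrix$mean[de, , drop = FALSE]
  for (d in sort(schedule$early_days)) {
    v <- m[, paste0("D", d)]
    v0 <- m[, "D0"]
    ok <- !is.na(v) & !is.na(v0) & v >= rules$early_fold * v0 &
      (v - v0) >= rules$early_abs_min
    if (any(ok)) return(d)
  }
  NA_real_
}

#' Integrated timeline of redox events
#'
#' Orders the five landmark events of one cultivation condition — NADPH
#' decline, pro-oxidizing E_GSH shift, early protein oxidation, global
#' redox collapse and 50\% viability — by the day each is first observed,
#' and reports the lag between consecutive defined events in hours.
#' Undefined events (e.g. no collapse under water) are carried with
#' `day = NA` and flagged.
#'
#' @param metabolites a [gen_metabolites()]-style series.
#' @param matrix an [oxidation_matrix()] for the same condition.
#' @param assignment `cluster_assignment` for `matrix`.
#' @param condition condition string (defaults to the matrix's).
#' @param schedule a [timepoint_schedule()] (defaults to the condition's).
#' @param rules a [cluster_rules()].
#' @return object of class `redox_timeline`: data.frame `event`, `day`,
#'   `lag_h` (hours since the previous defined event), `defined`,
#'   `condition`, sorted chronologically with undefined events last.
#' @export
build_timeline <- function(metabolites, matrix, assignment,
                           condition = matrix$condition,
                           schedule = timepoint_schedule(condition),
                           rules = cluster_rules()) {
  days <- c(nadph_decline = nadph_decline_onset(metabolites),
            egsh_shift = egsh_shift_day(metabolites),
            early_oxidation_onset = early_oxidation_onset(matrix, assignment,
                                                          schedule, rules),
            redox_collapse = collapse_day(matrix, assignment),
            viability_50 = as.numeric(mean_lifespan(metabolites)))
  df <- data.frame(event = names(days), day = unname(days),
                   defined = !is.na(days), condition = condition)
  df <- df[order(!df$defined, df$day), , drop = FALSE]
  def <- which(df$defined)
  df$lag_h <- NA_real_
  if (length(def) > 1L)
    df$lag_h[def[-1L]] <- 24 * diff(df$day[def])
  rownames(df) <- NULL
  structure(df, class = c("redox_timeline", "data.frame"))
}

#' @export
print.redox_timeline <- function(x, ...) {
  cat("<redox_timeline> ", x$condition[1L], "\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Write a timeline as JSON plus a heatmap-ready parameter-by-day grid
#'
#' @param timeline a `redox_timeline`.
#' @param metabolites the metabolite series used to build it.
#' @param matrix the oxidation matrix used to build it.
#' @param json_path,grid_path output paths (`NULL` skips either).
#' @return invisible list of written paths.
#' @export
write_timeline <- function(timeline, metabolites, matrix,
                           json_path = NULL, grid_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(timeline), json_path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(grid_path)) {
    days <- matrix$days
    met <- metabolites[metabolites$day %in% days, , drop = FALSE]
    e <- egsh(met$gsh_M, met$gssg_M)
    grid <- rbind(
      viability = met$viability[match(days, met$day)],
      atp = met$atp[match(days, met$day)],
      nadph = met$nadph[match(days, met$day)],
      egsh_mv = e[match(days, met$day)],
      median_oxidation = apply(matrix$mean, 2L, stats::median, na.rm = TRUE))
    df <- data.frame(parameter = rownames(grid), grid, check.names = FALSE)
    colnames(df)[-1L] <- paste0("D", days)
    utils::write.table(df, grid_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(json = json_path, grid = grid_path))
}
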