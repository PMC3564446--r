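#' Sampling schedule for a cultivation condition
#'
#' Chronological-lifespan cultures are sampled at 24-h intervals starting in
#' exponential growth (day 0). Standard (2\% glucose) cultures are followed
#' through day 4; caloric-restriction (0.5\% glucose) cultures through day 7
#' with day 6 unsampled; water-shifted (hypometabolic) cultures through day
#' 10. The schedule also names the days the trajectory classifier needs:
#' the two candidate early-rise days, the day of the global redox collapse,
#' and the late day used for delayed collapses. Under caloric restriction
#' the late collapse nominally falls on day 6; because day 6 is not sampled
#' it is mapped to the first sampled day at or after it (day 7).
#'
#' @param condition one of `"standard"`, `"caloric_restriction"`, `"water"`.
#' @return An object of class `timepoint_schedule`: a list with elements
#'   `condition`, `days` (sampled days), `early_days` (length 2),
#'   `collapse_day`, `late_day`.
#' @examples
#' timepoint_schedule("standard")$days            # 0 1 2 3 4
#' timepoint_schedule("caloric_restriction")$late_day  # 7 (day 6 unsampled)
#' @export
timepoint_schedule <- function(condition = c("standard", "caloric_restriction",
                                             "water")) {
  condition <- match.arg(condition)
  sched <- switch(condition,
    standard = list(days = 0:4, early_days = c(1L, 2L),
                    collapse_day = 3L, late_day = 4L),
    caloric_restriction = list(days = c(0:5, 7L), early_days = c(3L, 4L),
                               collapse_day = 5L, late_day = 6L),
    water = list(days = 0:10, early_days = c(1L, 2L),
                 collapse_day = 3L, late_day = 4L)
  )
  # map named days that are not sampled to the first sampled day >= them
  map_day <- function(d) {
    hit <- sched$days[sched$days >= d]
    if (length(hit) == 0L)
      stop("named day ", d, " beyond sampled range", call. = FALSE)
    hit[1L]
  }
  sched$collapse_day <- map_day(sched$collapse_day)
  sched$late_day <- map_day(sched$late_day)
  sched$early_days <- vapply(sched$early_days, map_day, numeric(1))
  stopifnot(all(sched$early_days < sched$collapse_day))
  structure(c(list(condition = condition), sched),
            class = "timepoint_schedule")
}

#' Column labels ("D0", "D1", ...) for a schedule's sampled days
#' @param schedule a `timepoint_schedule`.
#' @return character vector of day labels.
#' @export
day_labels <- function(schedule) paste0("D", schedule$days)

#' @export
print.timepoint_schedule <- function(x, ...) {
  cat("<timepoint_schedule> ", x$condition, "\n",
      "  days: ", paste(x$days, collapse = " "), "\n",
      "  early: ", paste(x$early_days, collapse = ","),
      "  collapse: ", x$collapse_day, "  late: ", x$late_day, "\n", sep = "")
  invisible(x)
}
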