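#' Thresholds for the rule-based trajectory classifier
#'
#' Numeric operationalization of the seven oxidation-trajectory classes:
#' \describe{
#'   \item{A}{starts below `low_start` (log phase) and exceeds `high_ox`
#'     on the collapse day.}
#'   \item{B}{starts below `low_start` and exceeds `high_ox` only on the
#'     late day.}
#'   \item{C}{starts at or above `high_start` and rises by at least
#'     `flat_range` points by the collapse day.}
#'   \item{D/E}{early risers: at least `early_fold`-fold above day 0 and
#'     at least `early_abs_min` points above it, first satisfied on the
#'     first (D) or second (E) early day of the schedule.}
#'   \item{F/G}{remain reduced (range below `flat_range`, maximum below
#'     `low_start`) or remain oxidized (minimum at or above
#'     `oxidized_floor`, never reaching `early_fold` times day 0).}
#' }
#' `early_abs_min` suppresses spurious fold calls on near-zero baselines.
#'
#' @param low_start,high_ox,high_start,oxidized_floor percent thresholds.
#' @param early_fold fold increase over day 0 defining an early riser.
#' @param early_abs_min minimum absolute rise, percentage points.
#' @param flat_range flat-trajectory range / minimum class-C rise, points.
#' @return object of class `cluster_rules`.
#' @export
cluster_rules <- function(low_start = 30, high_ox = 50, high_start = 40,
                          early_fold = 1.5, early_abs_min = 10,
                          flat_range = 15, oxidized_floor = 50) {
  stopifnot(low_start > 0, low_start < 100, high_ox > 0, high_ox < 100,
            high_start > 0, high_start < 100, early_fold > 1,
            early_abs_min >= 0, flat_range > 0, oxidized_floor > 0,
            oxidized_floor < 100)
  structure(list(low_start = low_start, high_ox = high_ox,
                 high_start = high_start, early_fold = early_fold,
                 early_abs_min = early_abs_min, flat_range = flat_range,
                 oxidized_floor = oxidized_floor),
            class = "cluster_rules")
}

#' All trajectory class labels
#' @export
CLUSTER_LABELS <- c("A", "B", "C", "D", "E", "F", "G")

#' k-nearest-neighbour imputation of missing trajectory values
#'
#' Rows (peptides) in which more than `min_known_frac` of the days are
#' observed get each missing entry replaced by the mean of that column in
#' the `k` nearest rows that are observed on the column, with distance the
#' root-mean-square difference over the days observed in both rows. Rows
#' at or below the threshold are dropped and reported in the
#' `dropped` attribute. Imputed values are clipped to [0, 100].
#'
#' @param x an [oxidation_matrix()] (or plain matrix with NAs).
#' @param k number of neighbours.
#' @param min_known_frac minimum observed fraction for a row to be kept.
#' @return an imputed `oxidation_matrix` with attribute `dropped` (peptide
#'   ids removed).
#' @export
impute_missing <- function(x, k = 5L, min_known_frac = 0.3) {
  stopifnot(k >= 1)
  m <- if (inherits(x, "oxidation_matrix")) x$mean else as.matrix(x)
  known <- rowMeans(!is.na(m))
  dropped <- rownames(m)[known <= min_known_frac]
  m <- m[known > min_known_frac, , drop = FALSE]
  filled <- m
  for (i in which(rowSums(is.na(m)) > 0L)) {
    for (j in which(is.na(m[i, ]))) {
      cand <- setdiff(which(!is.na(m[, j])), i)
      if (length(cand) == 0L)
        stop("no neighbour observed on day ", colnames(m)[j])
      d <- vapply(cand, function(r) {
        shared <- !is.na(m[i, ]) & !is.na(m[r, ])
        if (!any(shared)) return(Inf)
        sqrt(mean((m[i, shared] - m[r, shared])^2))
      }, numeric(1))
      if (length(cand) < k)
        warning("only ", length(cand), " eligible neighbours (k = ", k,
                ") for ", rownames(m)[i], " on ", colnames(m)[j])
      nn <- cand[order(d)][seq_len(min(k, length(cand)))]
      filled[i, j] <- min(100, max(0, mean(m[nn, j])))
    }
  }
  out <- if (inherits(x, "oxidation_matrix")) {
    keep <- rownames(filled)
    oxidation_matrix(filled, x$sd[keep, , drop = FALSE],
                     x$n[keep, , drop = FALSE],
                     condition = x$condition, days = x$days)
  } else filled
  attr(out, "dropped") <- dropped
  out
}

#' k-means clustering of oxidation trajectories
#'
#' Euclidean k-means over complete (imputed) trajectories, best of
#' `restarts` random starts, reproducible for a given seed.
#'
#' @param x an [oxidation_matrix()] or complete numeric matrix.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param restarts number of random starts.
#' @return a `stats::kmeans` fit.
#' @export
kmeans_trajectories <- function(x, k = 7L, seed = 1L, restarts = 10L) {
  m <- if (inherits(x, "oxidation_matrix")) x$mean else as.matrix(x)
  if (anyNA(m)) stop("matrix contains missing values; impute first")
  if (k > nrow(m)) stop("k (", k, ") exceeds number of trajectories (",
                        nrow(m), ")")
  withr::with_seed(seed, stats::kmeans(m, centers = k, nstart = restarts,
                                       iter.max = 100L))
}

#' Assign one trajectory to a rule-defined class
#'
#' Rules are evaluated in the fixed priority order F, G, D, E, A, B, C
#' (flat classes first, then early risers, then the collapse classes), so
#' labels are mutually exclusive; the first match wins and a trajectory
#' matching none is `"unassigned"`. An early riser that would also satisfy
#' the general-collapse rule is therefore reported as D/E.
#'
#' @param traj numeric vector of percent oxidation named `D0, D1, ...` (or
#'   in schedule day order), complete on the schedule's named days.
#' @param schedule a [timepoint_schedule()].
#' @param rules a [cluster_rules()].
#' @return single character label in `c(CLUSTER_LABELS, "unassigned")`.
#' @examples
#' sched <- timepoint_schedule("standard")
#' assign_rule_cluster(c(26, 22, 28, 70, 81), sched)  # "A"
#' assign_rule_cluster(c(33, 33, 65, 77, 82), sched)  # "E"
#' @export
assign_rule_cluster <- function(traj, schedule, rules = cluster_rules()) {
  v <- as.numeric(traj)
  if (is.null(names(traj)) || !all(grepl("^D", names(traj)))) {
    if (length(v) != length(schedule$days))
      stop("unnamed trajectory length differs from schedule")
    names(v) <- paste0("D", schedule$days)
  } else names(v) <- names(traj)
  required <- unique(c(0, schedule$early_days, schedule$collapse_day,
                       schedule$late_day))
  have <- names(v)[!is.na(v)]
  absent <- setdiff(paste0("D", required), have)
  if (length(absent))
    stop("trajectory misses required day(s) ",
         paste(absent, collapse = ", "))
  at <- function(day) v[[paste0("D", day)]]
  v0 <- at(0)
  early_ok <- function(day) {
    val <- at(day)
    val >= rules$early_fold * v0 && (val - v0) >= rules$early_abs_min
  }
  vv <- v[!is.na(v)]
  if ((max(vv) - min(vv)) < rules$flat_range && max(vv) < rules$low_start)
    return("F")
  if (min(vv) >= rules$oxidized_floor && !any(vv > v0 &
      vv >= rules$early_fold * v0))
    return("G")
  if (early_ok(schedule$early_days[1L])) return("D")
  if (early_ok(schedule$early_days[2L])) return("E")
  if (v0 < rules$low_start && at(schedule$collapse_day) > rules$high_ox)
    return("A")
  if (v0 < rules$low_start && at(schedule$late_day) > rules$high_ox)
    return("B")
  if (v0 >= rules$high_start &&
      at(schedule$collapse_day) >= v0 + rules$flat_range)
    return("C")
  "unassigned"
}

#' Classify every trajectory of a matrix and cross-tabulate with k-means
#'
#' Applies [assign_rule_cluster()] row-wise and, optionally, runs
#' [kmeans_trajectories()] on the same (complete) matrix so rule labels
#' and the unsupervised partition can be compared.
#'
#' @param x an [oxidation_matrix()] (complete; impute first) or matrix.
#' @param schedule a [timepoint_schedule()].
#' @param rules a [cluster_rules()].
#' @param kmeans_k clusters for the k-means partition; `NULL` skips it.
#' @param seed RNG seed for k-means.
#' @return object of class `cluster_assignment`: list with `labels` (named
#'   character), `kmeans` (the fit or `NULL`), `table` (data.frame
#'   peptide, rule_label, kmeans_cluster), `cluster_means`.
#' @export
classify_trajectories <- function(x, schedule, rules = cluster_rules(),
                                  kmeans_k = NULL, seed = 1L) {
  m <- if (inherits(x, "oxidation_matrix")) x$mean else as.matrix(x)
  labels <- vapply(seq_len(nrow(m)),
                   function(i) assign_rule_cluster(m[i, ], schedule, rules),
                   character(1))
  names(labels) <- rownames(m)
  km <- if (!is.null(kmeans_k))
    kmeans_trajectories(m, k = kmeans_k, seed = seed) else NULL
  means <- do.call(rbind, lapply(split(seq_along(labels), labels),
                                 function(i) colMeans(m[i, , drop = FALSE])))
  structure(list(labels = labels, kmeans = km,
                 table = data.frame(peptide = names(labels),
                                    rule_label = unname(labels),
                                    kmeans_cluster = if (is.null(km))
                                      NA_integer_ else km$cluster),
                 cluster_means = means),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$labels), " trajectories; ",
      sprintf("%.1f%%", fraction_assigned(x)), " assigned\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Percent of trajectories assigned to one of the seven classes
#'
#' @param assignment a `cluster_assignment` or character vector of labels.
#' @return percent in [0, 100].
#' @export
fraction_assigned <- function(assignment) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  if (length(labels) == 0L) stop("empty assignment")
  100 * mean(labels != "unassigned")
}
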