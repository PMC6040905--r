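# Per-cluster characterisation: the Runs / Locations / Area / M-Dist /
# N-200 / P-200 / M-Age / P-Female table, the runs-per-location frequency
# profile that exposes single-location spikes, and subgroup comparison for a
# flagged location.

#' Summarise one cluster
#'
#' Centroid and the median run-to-centroid distance are computed over runs
#' (with multiplicity — they describe where demand is); the convex-hull area
#' is computed over unique locations by default (so multiplicity cannot
#' change geometry). Demographic summaries exclude missing values. All
#' quantiles use linear interpolation between order statistics
#' (\code{quantile type 7}).
#'
#' @param xy planar coordinates of the cluster's runs (one row per run).
#' @param location_ids location id per run.
#' @param age,sex per-run demographics (NA allowed).
#' @param radius site-accessibility radius in metres for the N/P counts
#'   (default 200).
#' @param hull_on \code{"locations"} (default) or \code{"runs"}.
#' @param centroid_on \code{"runs"} (default) or \code{"locations"}.
#' @return list of class \code{cluster_summary}: \code{runs},
#'   \code{locations}, \code{area}, \code{centroid}, \code{m_dist},
#'   \code{n_in_radius}, \code{pct_in_radius}, \code{m_age},
#'   \code{pct_female}, \code{hull}.
#' @export
summarize_cluster <- function(xy, location_ids, age = NULL, sex = NULL,
                              radius = 200,
                              hull_on = c("locations", "runs"),
                              centroid_on = c("runs", "locations")) {
  xy <- as_xy(xy)
  if (nrow(xy) == 0) stop("cannot summarise an empty cluster")
  stopifnot(radius > 0, length(location_ids) == nrow(xy))
  hull_on <- match.arg(hull_on)
  centroid_on <- match.arg(centroid_on)

  first <- !duplicated(location_ids)
  loc_xy <- xy[first, , drop = FALSE]
  hull <- convex_hull(if (hull_on == "locations") loc_xy else xy)
  ctr <- centroid_points(if (centroid_on == "runs") xy else loc_xy)

  dist_run <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  n_in <- sum(dist_run <= radius)
  n_runs <- nrow(xy)

  structure(list(
    runs = n_runs,
    locations = sum(first),
    area = hull$area,
    centroid = ctr,
    m_dist = median(dist_run),
    n_in_radius = n_in,
    pct_in_radius = 100 * n_in / n_runs,
    m_age = if (!is.null(age) && any(!is.na(age))) {
      median(age, na.rm = TRUE)
    } else NA_real_,
    pct_female = if (!is.null(sex) && any(!is.na(sex))) {
      100 * mean(sex[!is.na(sex)] == "female")
    } else NA_real_,
    radius = radius,
    hull = hull), class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf(
    "<cluster_summary> %d runs at %d location(s); area %.1f m^2, m_dist %.1f m, %d/%d (%.1f%%) within %g m\n",
    x$runs, x$locations, x$area, x$m_dist, x$n_in_radius, x$runs,
    x$pct_in_radius, x$radius))
  invisible(x)
}

#' Characteristics table for the kept clusters
#'
#' One row per kept cluster with the standard columns (Runs, Locations,
#' Area, M-Dist, N-200, P-200, M-Age, P-Female), areas and distances rounded
#' to 0.1 and percentages to 0.1 — the reporting precision used throughout.
#'
#' @param runs data frame of kept runs with \code{x, y, location_id, age,
#'   sex}.
#' @param assignment filtered [dbscan_runs()] assignment aligned with
#'   \code{runs}.
#' @param radius accessibility radius for the N/P columns.
#' @param ... forwarded to [summarize_cluster()].
#' @return data frame, plus the unrounded summaries in
#'   \code{attr(, "summaries")}.
#' @export
cluster_table <- function(runs, assignment, radius = 200, ...) {
  ids <- sort(unique(assignment$labels[assignment$labels > 0]))
  summaries <- lapply(ids, function(k) {
    sel <- assignment$labels == k
    summarize_cluster(cbind(runs$x, runs$y)[sel, , drop = FALSE],
                      runs$location_id[sel], runs$age[sel], runs$sex[sel],
                      radius = radius, ...)
  })
  tab <- data.frame(
    cluster = if (length(ids)) LETTERS[seq_along(ids)] else character(0),
    runs = vapply(summaries, `[[`, 0, "runs"),
    locations = vapply(summaries, `[[`, 0, "locations"),
    area = round(vapply(summaries, `[[`, 0, "area"), 1),
    m_dist = round(vapply(summaries, `[[`, 0, "m_dist"), 1),
    n_200 = vapply(summaries, `[[`, 0, "n_in_radius"),
    p_200 = round(vapply(summaries, `[[`, 0, "pct_in_radius"), 1),
    m_age = vapply(summaries, `[[`, 0, "m_age"),
    p_female = round(vapply(summaries, `[[`, 0, "pct_female"), 1),
    stringsAsFactors = FALSE)
  attr(tab, "summaries") <- setNames(summaries, ids)
  tab
}

#' Runs-per-location frequency profile
#'
#' How many locations saw exactly m runs, plus the modal ("outlier")
#' location and its share of all runs — the diagnostic that surfaces a
#' single-address spike (e.g. one building accounting for 11% of a city's
#' runs).
#'
#' @param location_ids location id per run (over all runs considered).
#' @return list: \code{profile} (data frame: multiplicity, n_locations,
#'   pct_locations), \code{n_locations}, \code{n_runs},
#'   \code{top_location}, \code{top_runs}, \code{top_share_pct}.
#' @export
location_frequency_profile <- function(location_ids) {
  if (!length(location_ids)) stop("no locations to profile")
  per_loc <- table(location_ids)
  mult <- table(as.integer(per_loc))
  profile <- data.frame(
    multiplicity = as.integer(names(mult)),
    n_locations = as.integer(mult),
    pct_locations = 100 * as.integer(mult) / length(per_loc))
  top <- which.max(per_loc)
  list(profile = profile,
       n_locations = length(per_loc),
       n_runs = length(location_ids),
       top_location = names(per_loc)[top],
       top_runs = as.integer(per_loc[top]),
       top_share_pct = 100 * as.integer(per_loc[top]) / length(location_ids))
}

group_demo <- function(age, sex) {
  a <- age[!is.na(age)]
  s <- sex[!is.na(sex)]
  list(n = length(age),
       median_age = if (length(a)) median(a) else NA_real_,
       age_iqr = if (length(a)) unname(quantile(a, c(0.25, 0.75), type = 7))
                 else c(NA_real_, NA_real_),
       pct_female = if (length(s)) 100 * mean(s == "female") else NA_real_,
       pct_male = if (length(s)) 100 * mean(s == "male") else NA_real_)
}

#' Compare demographics of a flagged location vs. everyone else
#'
#' Medians, IQRs (linear-interpolation quantiles) and sex shares per group,
#' missing values excluded. Both groups must be nonempty.
#'
#' @param age_flag,sex_flag demographics of runs at the flagged location.
#' @param age_rest,sex_rest demographics of all other runs.
#' @return list with elements \code{flagged} and \code{rest}, each as from
#'   the internal group summary (n, median_age, age_iqr, pct_female,
#'   pct_male).
#' @export
compare_subgroups <- function(age_flag, sex_flag, age_rest, sex_rest) {
  if (!length(age_flag) || !length(age_rest)) {
    stop("both comparison groups must be nonempty")
  }
  list(flagged = group_demo(age_flag, sex_flag),
       rest = group_demo(age_rest, sex_rest))
}
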