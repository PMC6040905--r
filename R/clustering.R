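# Local cluster discovery: kNN-distance diagnostics for choosing epsilon,
# DBSCAN on run-level points (coincident runs count toward density, which is
# what lets a 76-run single building anchor a cluster), a minimum-size
# filter, and single- vs multi-location classification.

#' Sorted k-th nearest-neighbour distances
#'
#' The y-values of the classical kNN plot used to choose DBSCAN's epsilon by
#' eye: for each point, the distance to its k-th nearest neighbour
#' (coincident points give 0), sorted ascending.
#'
#' @param xy n x 2 matrix of planar points, n > k.
#' @param k neighbour rank (>= 1).
#' @return ascending numeric vector of length n.
#' @export
knn_distances <- function(xy, k = 3) {
  xy <- as_xy(xy)
  n <- nrow(xy)
  if (n <= k) stop("need more than k points for k-th neighbour distances")
  d <- as.matrix(stats::dist(xy))
  kd <- vapply(seq_len(n), function(i) sort(d[i, -i], partial = k)[k], 0)
  sort(kd)
}

#' Knee heuristic for the kNN curve
#'
#' Maximum-curvature (discrete second difference) point of the sorted kNN
#' curve — offered as a starting value only; epsilon selection remains a
#' judgement call and the pipeline never applies this automatically.
#'
#' @param kdist output of [knn_distances()].
#' @return suggested epsilon (metres).
#' @export
knee_eps <- function(kdist) {
  if (length(kdist) < 3) return(kdist[length(kdist)])
  d2 <- diff(kdist, differences = 2)
  kdist[which.max(d2) + 1]
}

#' DBSCAN on planar run points
#'
#' Standard DBSCAN: a point is core iff its closed eps-neighbourhood
#' (including itself) holds at least \code{min_pts} points; clusters are the
#' density-connected components of core points, border points attach to the
#' first core cluster that reaches them in input order, the rest is noise.
#' The neighbour predicate is inclusive (\code{d <= eps}). Runs participate
#' with multiplicity: many runs at one address all count toward density.
#' Labels are deterministic for a fixed input order; the core set and the
#' partition restricted to core points do not depend on order at all.
#'
#' @param xy n x 2 matrix of planar points (n >= 1).
#' @param eps neighbourhood radius in metres (> 0).
#' @param min_pts core threshold, self-inclusive (>= 1).
#' @return object of class \code{cluster_assignment}: integer \code{labels}
#'   (0 = noise, 1..k = clusters), logical \code{core}, \code{eps},
#'   \code{min_pts}, \code{n}.
#' @export
dbscan_runs <- function(xy, eps = 200, min_pts = 3) {
  xy <- as_xy(xy)
  stopifnot(eps > 0, min_pts >= 1)
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # includes self
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      for (p in nb[[q]]) {
        if (labels[p] == 0L) {
          labels[p] <- cl
          if (core[p]) queue <- c(queue, p)
        }
      }
    }
  }
  structure(list(labels = labels, core = core, eps = eps,
                 min_pts = min_pts, n = n),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- tabulate(x$labels)
  cat(sprintf(
    "<cluster_assignment> n = %d, eps = %g, min_pts = %d: %d cluster(s) %s, %d noise\n",
    x$n, x$eps, x$min_pts, length(sizes),
    if (length(sizes)) paste0("(", paste(sizes, collapse = ", "), ")") else "",
    sum(x$labels == 0)))
  invisible(x)
}

#' Summarise a cluster assignment
#'
#' @param object a \code{cluster_assignment}.
#' @param ... unused.
#' @return list: \code{n}, \code{sizes} (runs per cluster),
#'   \code{n_clustered}, \code{pct_clustered}, \code{n_noise}.
#' @export
summary.cluster_assignment <- function(object, ...) {
  sizes <- tabulate(object$labels)
  list(n = object$n, sizes = sizes,
       n_clustered = sum(object$labels > 0),
       pct_clustered = 100 * sum(object$labels > 0) / object$n,
       n_noise = sum(object$labels == 0))
}

#' Demote small clusters to noise
#'
#' Keeps clusters with at least \code{ceiling(min_fraction * total_runs)}
#' runs (with the shipped 10% of 690 runs that threshold is 69) and demotes
#' the rest to noise; kept clusters are relabelled 1..m in discovery order.
#'
#' @param assignment a [dbscan_runs()] result.
#' @param total_runs denominator for the fraction (all geocoded runs).
#' @param min_fraction fraction in (0, 1].
#' @return list: \code{assignment} (filtered copy), \code{kept} (original
#'   cluster ids kept), \code{threshold}.
#' @export
filter_clusters <- function(assignment, total_runs, min_fraction = 0.10) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  threshold <- ceiling(min_fraction * total_runs)
  sizes <- tabulate(assignment$labels)
  kept <- which(sizes >= threshold)
  remap <- integer(length(sizes))
  remap[kept] <- seq_along(kept)
  out <- assignment
  new_labels <- assignment$labels
  pos <- new_labels > 0L
  new_labels[pos] <- remap[new_labels[pos]]
  out$labels <- as.integer(new_labels)
  # demoted points are no longer in any cluster; keep their core flags as
  # computed (core-ness is a density fact, membership is a reporting choice)
  list(assignment = out, kept = kept, threshold = threshold)
}

#' Classify a cluster as single- or multi-location
#'
#' A cluster is "single-location" when its modal location holds at least
#' \code{dominance} of the runs (default one half, with >= at the boundary);
#' when several locations tie for modal the cluster counts as
#' multi-location.
#'
#' @param location_ids location id per run in the cluster (nonempty).
#' @param dominance share threshold in (0, 1].
#' @return list: \code{type} ("single-location"/"multi-location"),
#'   \code{modal_location}, \code{modal_runs}, \code{modal_share}.
#' @export
classify_cluster <- function(location_ids, dominance = 0.5) {
  if (!length(location_ids)) stop("cannot classify an empty cluster")
  tab <- table(location_ids)
  top <- max(tab)
  modal <- names(tab)[tab == top]
  share <- top / length(location_ids)
  single <- share >= dominance && length(modal) == 1
  list(type = if (single) "single-location" else "multi-location",
       modal_location = modal[1],
       modal_runs = as.integer(top),
       modal_share = as.numeric(share))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between partitions; 1 means identical
#' partitions, 0 is the expectation under independent random labelings. Used
#' to score recovery of planted clusters (noise/background treated as one
#' class).
#'
#' @param a,b label vectors of equal length.
#' @return numeric in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(length(a))
  expected <- sum_a * sum_b / total
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
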