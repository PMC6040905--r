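# Publicly deployed naloxone (PDN) siting model. One kit per kept cluster:
# at the cluster centroid for multi-location clusters (covering the
# cluster's runs within a straight-line accessibility radius), or inside the
# dominant building for single-location clusters (covering exactly the runs
# at that location). Sites never claim noise or other clusters' runs, so
# per-site counts sum without double counting.

#' Place PDN sites for the kept clusters
#'
#' @param summaries list of [summarize_cluster()] results, one per kept
#'   cluster (names/order give site ids).
#' @param classifications list of [classify_cluster()] results aligned with
#'   \code{summaries}.
#' @param locations locations data frame (from [dedupe_locations()]), used
#'   to position modal-location sites.
#' @param radius accessibility radius in metres (> 0).
#' @return data frame of sites: \code{site_id, cluster, mode, x, y, radius,
#'   location_id}.
#' @export
site_clusters <- function(summaries, classifications, locations,
                          radius = 200) {
  stopifnot(radius > 0, length(summaries) == length(classifications))
  if (!length(summaries)) {
    return(data.frame(site_id = character(0), cluster = integer(0),
                      mode = character(0), x = numeric(0), y = numeric(0),
                      radius = numeric(0), location_id = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(summaries), function(k) {
    cls <- classifications[[k]]
    if (cls$type == "single-location") {
      i <- match(cls$modal_location, locations$location_id)
      data.frame(site_id = sprintf("S%02d", k), cluster = k,
                 mode = "modal-location",
                 x = locations$x[i], y = locations$y[i], radius = radius,
                 location_id = cls$modal_location, stringsAsFactors = FALSE)
    } else {
      ctr <- summaries[[k]]$centroid
      data.frame(site_id = sprintf("S%02d", k), cluster = k,
                 mode = "centroid", x = ctr[1], y = ctr[2], radius = radius,
                 location_id = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count runs potentially modifiable by PDN sites
#'
#' Centroid sites cover their own cluster's runs within \code{radius} of the
#' site; modal-location sites cover exactly the runs at that location (a kit
#' inside the building serves the building). The per-cluster accounting
#' means a single-location cluster's covered count can differ from its
#' centroid N-200 — both views are computable, and \code{modal_disc = TRUE}
#' switches modal sites to disc coverage for sensitivity analysis.
#'
#' @param sites data frame from [site_clusters()].
#' @param runs kept runs with \code{x, y, location_id}.
#' @param labels cluster label per run (filtered assignment labels).
#' @param total_runs denominator for the total percentage (all geocoded
#'   runs).
#' @param modal_disc treat modal-location sites as discs too.
#' @return object of class \code{coverage_result}: \code{per_site} (data
#'   frame: site_id, cluster, mode, cluster_runs, covered_runs,
#'   covered_pct_of_cluster), \code{total_covered}, \code{total_runs},
#'   \code{total_pct}.
#' @export
evaluate_coverage <- function(sites, runs, labels, total_runs,
                              modal_disc = FALSE) {
  stopifnot(length(labels) == nrow(runs))
  per <- lapply(seq_len(nrow(sites)), function(s) {
    site <- sites[s, ]
    sel <- labels == site$cluster
    if (site$mode == "modal-location" && !modal_disc) {
      covered <- sum(sel & runs$location_id == site$location_id)
    } else {
      d <- sqrt((runs$x - site$x)^2 + (runs$y - site$y)^2)
      covered <- sum(sel & d <= site$radius)
    }
    data.frame(site_id = site$site_id, cluster = site$cluster,
               mode = site$mode, cluster_runs = sum(sel),
               covered_runs = covered,
               covered_pct_of_cluster = 100 * covered / max(sum(sel), 1),
               stringsAsFactors = FALSE)
  })
  per_site <- if (length(per)) do.call(rbind, per) else
    data.frame(site_id = character(0), cluster = integer(0),
               mode = character(0), cluster_runs = integer(0),
               covered_runs = integer(0),
               covered_pct_of_cluster = numeric(0), stringsAsFactors = FALSE)
  total_covered <- sum(per_site$covered_runs)
  structure(list(per_site = per_site,
                 total_covered = total_covered,
                 total_runs = total_runs,
                 total_pct = 100 * total_covered / total_runs),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %d site(s); %d/%d runs covered (%.1f%%)\n",
              nrow(x$per_site), x$total_covered, x$total_runs, x$total_pct))
  for (i in seq_len(nrow(x$per_site))) {
    with(x$per_site[i, ], cat(sprintf(
      "  %s cluster %d [%s]: %d/%d runs (%.1f%%)\n",
      site_id, cluster, mode, covered_runs, cluster_runs,
      covered_pct_of_cluster)))
  }
  invisible(x)
}
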