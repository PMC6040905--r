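# Orchestration: a single config object drives ingest -> project -> dedupe
# -> clip -> Ripley envelope -> DBSCAN -> filter -> classify -> summarise ->
# coverage, with every artifact written to disk and a manifest that makes a
# run reproducible byte-for-byte.

#' Pipeline configuration
#'
#' Defaults encode the shipped analysis settings: eps 200 m / min_pts 3 for
#' DBSCAN, a 10% minimum cluster size, 999 envelope simulations, and a 200 m
#' site-accessibility radius.
#'
#' @param runs_csv path to the runs CSV.
#' @param boundary_geojson path to the boundary GeoJSON.
#' @param out_dir artifact directory (created if needed).
#' @param lookup_csv optional address -> coordinate lookup CSV.
#' @param dedupe_tolerance location merge radius (m).
#' @param ripley list: \code{nsim}, \code{n_radii}, \code{resolution},
#'   \code{statistic}, \code{alternative}.
#' @param dbscan list: \code{eps}, \code{min_pts}.
#' @param filter list: \code{min_fraction}.
#' @param classify list: \code{dominance}.
#' @param coverage list: \code{radius}, \code{modal_disc}.
#' @param report list: \code{jitter_sd} (display only).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(runs_csv, boundary_geojson, out_dir,
                            lookup_csv = NULL,
                            dedupe_tolerance = 0.5,
                            ripley = list(),
                            dbscan = list(),
                            filter = list(),
                            classify = list(),
                            coverage = list(),
                            report = list(),
                            seed = 1L) {
  merge_defaults <- function(given, defaults) {
    for (nm in names(given)) defaults[[nm]] <- given[[nm]]
    defaults
  }
  cfg <- structure(list(
    runs_csv = runs_csv, boundary_geojson = boundary_geojson,
    out_dir = out_dir, lookup_csv = lookup_csv,
    dedupe_tolerance = dedupe_tolerance,
    ripley = merge_defaults(ripley, list(
      nsim = 999L, n_radii = 128L, resolution = 256L,
      statistic = "L", alternative = "two.sided")),
    dbscan = merge_defaults(dbscan, list(eps = 200, min_pts = 3L)),
    filter = merge_defaults(filter, list(min_fraction = 0.10)),
    classify = merge_defaults(classify, list(dominance = 0.5)),
    coverage = merge_defaults(coverage, list(radius = 200, modal_disc = FALSE)),
    report = merge_defaults(report, list(jitter_sd = 5)),
    seed = as.integer(seed)), class = "pipeline_config")
  stopifnot(cfg$dedupe_tolerance >= 0, cfg$ripley$nsim >= 1,
            cfg$dbscan$eps > 0, cfg$dbscan$min_pts >= 1,
            cfg$filter$min_fraction > 0, cfg$filter$min_fraction <= 1,
            cfg$coverage$radius > 0, cfg$report$jitter_sd >= 0)
  cfg
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_config
#' @param config a \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Derive a per-stage seed from the master seed
#'
#' Fixed mapping so every stage is individually reproducible; results stay
#' below 2^31.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}

#' Gaussian display jitter
#'
#' Adds isotropic Gaussian noise (sd metres) so coincident runs are visible
#' on a map. Display only: analysis never sees jittered coordinates, and
#' jittered points may legitimately fall outside cluster hulls.
#'
#' @param xy planar points.
#' @param sd jitter standard deviation in metres (0 = identity).
#' @param seed optional seed.
#' @return jittered copy of \code{xy}.
#' @export
jitter_for_display <- function(xy, sd, seed = NULL) {
  xy <- as_xy(xy)
  stopifnot(sd >= 0)
  if (sd == 0) return(xy)
  if (!is.null(seed)) set.seed(seed)
  xy + matrix(rnorm(2 * nrow(xy), 0, sd), ncol = 2)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage and writes the artifact set to \code{out_dir}:
#' cleaned runs, locations, clip report, envelope curves, kNN curve, cluster
#' assignment, characteristics table, coverage report, GeoJSON layers
#' (boundary, hulls, centroids, sites) and a JSON manifest. Re-running with
#' the same config and inputs reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list (class \code{ems_pipeline_result}): \code{runs},
#'   \code{locations}, \code{envelope}, \code{assignment}, \code{table},
#'   \code{profile}, \code{coverage}, \code{sites}, \code{window},
#'   \code{counts}.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  window <- stage("boundary", read_boundary_geojson(config$boundary_geojson))
  runs_all <- stage("ingest", load_runs(config$runs_csv, config$lookup_csv,
                                        quiet = quiet))
  geo <- geocoding_summary(runs_all)
  say("ingest: %d runs, %d with coordinates (%.1f%%)",
      geo$n_runs, geo$runs_with_coord, geo$pct_runs)

  runs <- stage("project", project_runs(runs_all, window, quiet = quiet))
  dd <- stage("dedupe", dedupe_locations(runs, config$dedupe_tolerance))
  say("dedupe: %d runs at %d unique locations",
      nrow(runs), nrow(dd$locations))
  clip <- stage("clip", clip_to_boundary(dd, runs, window))
  runs <- clip$runs
  locations <- clip$locations
  say("clip: %d runs at %d locations inside the boundary",
      nrow(runs), nrow(locations))

  pts <- cbind(runs$x, runs$y)
  k_obs <- stage("ripley", k_estimate(
    pts, window, default_radii(window, config$ripley$n_radii),
    resolution = config$ripley$resolution))
  envelope <- stage("ripley", global_envelope_test(
    k_obs, window, nsim = config$ripley$nsim,
    seed = derive_seed(config$seed, "ripley"),
    statistic = config$ripley$statistic,
    alternative = config$ripley$alternative))
  say("ripley: global envelope p = %.4g (nsim %d)",
      envelope$p_global, envelope$nsim)

  kdist <- stage("cluster", knn_distances(pts, k = config$dbscan$min_pts))
  raw_assignment <- stage("cluster", dbscan_runs(
    pts, eps = config$dbscan$eps, min_pts = config$dbscan$min_pts))
  filt <- stage("cluster", filter_clusters(
    raw_assignment, total_runs = nrow(runs),
    min_fraction = config$filter$min_fraction))
  assignment <- filt$assignment
  say("cluster: %d cluster(s) of >= %d runs",
      length(filt$kept), filt$threshold)

  tab <- stage("summarize", cluster_table(
    runs, assignment, radius = config$coverage$radius))
  summaries <- attr(tab, "summaries")
  classifications <- stage("summarize", lapply(
    sort(unique(assignment$labels[assignment$labels > 0])),
    function(k) classify_cluster(runs$location_id[assignment$labels == k],
                                 config$classify$dominance)))
  profile <- stage("summarize",
                   location_frequency_profile(runs$location_id))

  sites <- stage("coverage", site_clusters(
    summaries, classifications, locations, radius = config$coverage$radius))
  coverage <- stage("coverage", evaluate_coverage(
    sites, runs, assignment$labels, total_runs = nrow(runs),
    modal_disc = config$coverage$modal_disc))
  say("coverage: %d/%d runs (%.1f%%) within reach of a PDN site",
      coverage$total_covered, coverage$total_runs, coverage$total_pct)

  counts <- list(
    runs_loaded = geo$n_runs,
    runs_with_coord = geo$runs_with_coord,
    addresses = geo$n_addresses,
    addresses_with_coord = geo$addresses_with_coord,
    locations = nrow(dd$locations),
    locations_removed = nrow(clip$removed),
    runs_final = nrow(runs))

  result <- structure(list(
    runs = runs, locations = locations, envelope = envelope,
    knn = kdist, assignment = assignment, table = tab,
    classifications = classifications, profile = profile,
    coverage = coverage, sites = sites, window = window,
    counts = counts, config = config), class = "ems_pipeline_result")
  write_artifacts(result, clip)
  result
}

num_csv <- function(df, path) {
  # fixed 15-significant-digit formatting => byte-identical reruns
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = 15, format = "g")
    }
  }
  write.csv(df, path, row.names = FALSE, na = "")
}

write_artifacts <- function(result, clip) {
  out <- result$config$out_dir
  p <- function(f) file.path(out, f)
  runs_out <- result$runs
  runs_out$cluster <- result$assignment$labels
  runs_out$is_core <- result$assignment$core
  num_csv(runs_out, p("runs_clean.csv"))
  loc_out <- result$locations
  loc_out$addresses <- vapply(loc_out$addresses, paste, "", collapse = "; ")
  loc_out$run_ids <- vapply(loc_out$run_ids, paste, "", collapse = "; ")
  num_csv(loc_out, p("locations.csv"))
  num_csv(clip$report, p("clip_report.csv"))
  num_csv(as.data.frame(result$envelope), p("envelope.csv"))
  num_csv(data.frame(rank = seq_along(result$knn), kdist = result$knn),
          p("knn.csv"))
  num_csv(data.frame(run_id = result$runs$run_id,
                     cluster_label = result$assignment$labels,
                     is_core = result$assignment$core),
          p("assignment.csv"))
  num_csv(result$table, p("table1.csv"))
  num_csv(result$coverage$per_site, p("coverage.csv"))

  w <- result$window
  write_boundary_geojson(w, p("boundary.geojson"))
  summaries <- attr(result$table, "summaries")
  hulls <- lapply(seq_along(summaries), function(k) {
    s <- summaries[[k]]
    h <- s$hull
    h$reference <- w$reference
    if (h$degenerate) {
      geojson_feature(geojson_point(s$centroid, w$reference),
                      list(cluster = k, degenerate = TRUE))
    } else {
      geojson_feature(geojson_polygon(h),
                      list(cluster = k, area_m2 = round(h$area, 1)))
    }
  })
  write_feature_collection(hulls, p("hulls.geojson"))
  cents <- lapply(seq_along(summaries), function(k) {
    geojson_feature(geojson_point(summaries[[k]]$centroid, w$reference),
                    list(cluster = k, role = "centroid"))
  })
  site_feats <- lapply(seq_len(nrow(result$sites)), function(s) {
    site <- result$sites[s, ]
    geojson_feature(geojson_point(c(site$x, site$y), w$reference),
                    list(site_id = site$site_id, mode = site$mode,
                         radius_m = site$radius))
  })
  write_feature_collection(c(cents, site_feats), p("sites.geojson"))

  manifest <- list(
    package = "emsclust",
    version = as.character(utils::packageVersion("emsclust")),
    seed = result$config$seed,
    stage_seeds = list(ripley = derive_seed(result$config$seed, "ripley"),
                       jitter = derive_seed(result$config$seed, "jitter")),
    config = unclass(result$config),
    counts = result$counts,
    p_global = result$envelope$p_global,
    total_coverage_pct = result$coverage$total_pct)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}

#' @export
print.ems_pipeline_result <- function(x, ...) {
  cat("<ems_pipeline_result>\n")
  cat(sprintf("  runs: %d at %d locations (of %d loaded)\n",
              x$counts$runs_final, nrow(x$locations), x$counts$runs_loaded))
  cat(sprintf("  global clustering: p = %.4g (nsim %d)\n",
              x$envelope$p_global, x$envelope$nsim))
  cat(sprintf("  clusters kept: %d\n", nrow(x$table)))
  cat(sprintf("  PDN coverage: %d/%d runs (%.1f%%)\n",
              x$coverage$total_covered, x$coverage$total_runs,
              x$coverage$total_pct))
  invisible(x)
}
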