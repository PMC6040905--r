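# Synthetic city generator. The study's EMS records are not public, so every
# downstream stage is exercised on generated data with the same statistical
# skeleton: a uniform (CSR) background, a few Gaussian multi-location
# clusters whose runs pile up on a limited set of locations, one
# single-location spike, and demographic attributes with small missingness.

#' Default synthetic city boundary
#'
#' An irregular 12-vertex polygon scaled to exactly 17 km^2 (a small-city
#' footprint, roughly 5.5 x 3.5 km), centred on the projection origin.
#'
#' @param reference lon/lat the planar origin corresponds to (only used when
#'   writing geographic output).
#' @return a [poly_window()].
#' @export
default_boundary <- function(reference = c(lon = -71.11, lat = 42.37)) {
  v <- rbind(
    c(0.00, 0.30), c(1.20, 0.00), c(2.60, 0.35), c(3.90, 0.10),
    c(4.80, 1.00), c(4.40, 2.20), c(3.60, 3.10), c(2.30, 3.40),
    c(1.10, 3.00), c(0.30, 2.20), c(-0.20, 1.30), c(-0.10, 0.70)) * 1000
  v <- sweep(v, 2, colMeans(v))
  v <- v * sqrt(17e6 / shoelace_area(v))
  poly_window(v, reference = reference)
}

#' Uniform (CSR) points in a window
#'
#' Rejection sampling from the bounding box; the exact-n counterpart of a
#' binomial point process, used both by the generator's background component
#' and by the Monte-Carlo envelope simulations.
#'
#' @param n number of points (>= 0).
#' @param window a [poly_window()].
#' @param seed optional integer seed (untouched RNG state if NULL).
#' @return n x 2 matrix of planar points.
#' @export
generate_csr <- function(n, window, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  bb <- apply(window$rings[[1]], 2, range)
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
    out <- rbind(out, cand[points_in_window(cand, window), , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

# Gaussian points truncated to the window by resampling (keeps counts exact).
rnorm_in_window <- function(n, center, sigma, window) {
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 8)
    cand <- cbind(rnorm(m, center[1], sigma), rnorm(m, center[2], sigma))
    out <- rbind(out, cand[points_in_window(cand, window), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Solve a shifted log-normal from median and IQR
#'
#' Three-parameter family \eqn{age = \gamma + e^{\mu + \sigma Z}}. The three
#' quantile conditions have the closed-form solution
#' \eqn{\gamma = (q_{25} q_{75} - med^2) / (q_{25} + q_{75} - 2\,med)}
#' (because the 25/75 normal quantiles are symmetric), then \eqn{\mu, \sigma}
#' follow. If the implied shift is negative or the IQR is symmetric around
#' the median, falls back to \eqn{\gamma = 0} matching the median and the
#' IQR ratio.
#'
#' @param med target median.
#' @param iqr length-2 target (q25, q75).
#' @return list with \code{gamma}, \code{mu}, \code{sigma}.
#' @export
solve_shifted_lognormal <- function(med, iqr) {
  z75 <- qnorm(0.75)
  den <- iqr[1] + iqr[2] - 2 * med
  gamma <- if (abs(den) < 1e-9) -Inf else (iqr[1] * iqr[2] - med^2) / den
  if (!is.finite(gamma) || gamma < 0 || gamma >= iqr[1]) {
    gamma <- 0
  }
  mu <- log(med - gamma)
  sigma <- log((iqr[2] - gamma) / (iqr[1] - gamma)) / (2 * z75)
  list(gamma = gamma, mu = mu, sigma = sigma)
}

draw_ages <- function(n, med, iqr) {
  p <- solve_shifted_lognormal(med, iqr)
  a <- p$gamma + exp(rnorm(n, p$mu, p$sigma))
  pmin(pmax(round(a), 0), 130)
}

#' Synthetic dataset configuration
#'
#' Declares the generative world: boundary, background intensity, Gaussian
#' clusters (each a two-level process: locations scattered around a centre,
#' runs multinomially piled on those locations), an optional single-location
#' spike, and demographics.
#'
#' @param seed integer seed.
#' @param boundary a [poly_window()] or \code{"default"}.
#' @param n_background uniform background runs.
#' @param clusters list of lists with \code{center} (planar, inside the
#'   boundary), \code{sigma} (m), \code{n_runs}, \code{n_locations}
#'   (\code{n_locations <= n_runs}; every location receives at least one run).
#' @param spike NULL or list with \code{location} (planar), \code{n_runs},
#'   and optional \code{age_median}/\code{age_iqr} overriding the population
#'   age model at the spike (emulating a distinct served population).
#' @param demographics list: \code{p_male}, \code{age_median},
#'   \code{age_iqr}, \code{missing_sex}, \code{missing_age}.
#' @return validated config object (class \code{synthetic_config}).
#' @export
synthetic_config <- function(seed = 1L,
                             boundary = "default",
                             n_background = 0L,
                             clusters = list(),
                             spike = NULL,
                             demographics = list(
                               p_male = 0.618, age_median = 36,
                               age_iqr = c(29, 49),
                               missing_sex = 0.01, missing_age = 0.02)) {
  if (identical(boundary, "default")) boundary <- default_boundary()
  stopifnot(inherits(boundary, "poly_window"), n_background >= 0)
  for (cl in clusters) {
    stopifnot(cl$sigma > 0, cl$n_runs >= 0,
              cl$n_locations >= 1, cl$n_locations <= max(cl$n_runs, 1))
    if (!points_in_window(matrix(cl$center, ncol = 2), boundary)) {
      stop("cluster center lies outside the boundary")
    }
  }
  if (!is.null(spike)) {
    stopifnot(spike$n_runs >= 0)
    if (!points_in_window(matrix(spike$location, ncol = 2), boundary)) {
      stop("spike location lies outside the boundary")
    }
  }
  d <- demographics
  stopifnot(d$p_male >= 0, d$p_male <= 1,
            d$missing_sex >= 0, d$missing_sex <= 1,
            d$missing_age >= 0, d$missing_age <= 1)
  structure(list(seed = as.integer(seed), boundary = boundary,
                 n_background = as.integer(n_background),
                 clusters = clusters, spike = spike, demographics = d),
            class = "synthetic_config")
}

#' The shipped "small-city" preset
#'
#' Calibrated to the study-scale world the pipeline targets: 690 runs in a
#' 17 km^2 city — a 328-run uniform background, two busy multi-location
#' clusters (86 runs / 42 locations and 191 runs / 81 locations), and an
#' 85-run single-location-dominated cluster whose spike holds 76 co-located
#' runs; ~61.8% male, median age 36 (IQR 29-49), with the spike population
#' older (median 43, IQR 36.5-58.5) and ~1-2% missing demographics.
#' Cluster spreads are set so median run-to-centroid distances land near
#' 100 m, 170 m and 20 m respectively.
#'
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
preset_paper_like <- function(seed = 1L) {
  spike_loc <- c(1400, -500)
  synthetic_config(
    seed = seed,
    boundary = "default",
    n_background = 328L,
    clusters = list(
      list(center = c(-1500, 400), sigma = 82, n_runs = 86L, n_locations = 42L),
      list(center = c(0, 0), sigma = 146, n_runs = 191L, n_locations = 81L),
      list(center = spike_loc, sigma = 40, n_runs = 9L, n_locations = 7L)),
    spike = list(location = spike_loc, n_runs = 76L,
                 age_median = 43, age_iqr = c(36.5, 58.5)),
    demographics = list(p_male = 0.618, age_median = 36, age_iqr = c(29, 49),
                        missing_sex = 7 / 690, missing_age = 13 / 690))
}

#' Generate a synthetic run dataset
#'
#' Fully reproducible for a given config (the config seed drives all draws).
#' Each run receives a synthetic address string (one per distinct generated
#' coordinate), a timestamp uniform over a ~7-month study window, an age from
#' the shifted log-normal model, sex as Bernoulli(p_male), and independent
#' missingness. Truth labels record each run's generating component.
#'
#' @param config a [synthetic_config()].
#' @return list with \code{runs} (an \code{ems_runs}-style data frame with
#'   lon/lat), \code{window}, and \code{truth} (data frame: run_id,
#'   component).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  w <- config$boundary
  d <- config$demographics

  pts <- list(); comp <- list()
  if (config$n_background > 0) {
    pts[[length(pts) + 1]] <- generate_csr(config$n_background, w)
    comp[[length(comp) + 1]] <- rep("background", config$n_background)
  }
  for (k in seq_along(config$clusters)) {
    cl <- config$clusters[[k]]
    if (cl$n_runs == 0) next
    locs <- rnorm_in_window(cl$n_locations, cl$center, cl$sigma, w)
    extra <- cl$n_runs - cl$n_locations
    counts <- rep(1L, cl$n_locations)
    if (extra > 0) {
      counts <- counts + as.integer(rmultinom(1, extra, rep(1, cl$n_locations)))
    }
    pts[[length(pts) + 1]] <- locs[rep(seq_len(cl$n_locations), counts), , drop = FALSE]
    comp[[length(comp) + 1]] <- rep(sprintf("cluster%d", k), cl$n_runs)
  }
  if (!is.null(config$spike) && config$spike$n_runs > 0) {
    sp <- config$spike
    pts[[length(pts) + 1]] <- matrix(rep(sp$location, each = sp$n_runs), ncol = 2)
    comp[[length(comp) + 1]] <- rep("spike", sp$n_runs)
  }
  xy <- do.call(rbind, pts)
  component <- unlist(comp)
  n <- nrow(xy)
  if (n == 0) stop("config generates no runs")

  # addresses: one synthetic street address per distinct coordinate
  key <- paste(sprintf("%.6f", xy[, 1]), sprintf("%.6f", xy[, 2]))
  addr_idx <- match(key, unique(key))
  address <- sprintf("%d Synthetic Ave", 100 + addr_idx)

  age <- draw_ages(n, d$age_median, d$age_iqr)
  if (!is.null(config$spike) && !is.null(config$spike$age_median)) {
    is_spike <- component == "spike"
    age[is_spike] <- draw_ages(sum(is_spike), config$spike$age_median,
                               config$spike$age_iqr)
  }
  sex <- ifelse(rbinom(n, 1, d$p_male) == 1, "male", "female")
  sex[runif(n) < d$missing_sex] <- NA
  age[runif(n) < d$missing_age] <- NA

  t0 <- as.POSIXct("2016-10-16 00:00:00", tz = "UTC")
  t1 <- as.POSIXct("2017-05-10 23:59:59", tz = "UTC")
  ts <- format(t0 + runif(n) * as.numeric(difftime(t1, t0, units = "secs")),
               "%Y-%m-%dT%H:%M:%SZ")

  ll <- plane_to_geo(xy, w$reference)
  ord <- sample.int(n)  # shuffle so components are not input-ordered
  runs <- data.frame(
    run_id = sprintf("R%04d", seq_len(n)),
    address = address[ord],
    lon = ll[ord, 1], lat = ll[ord, 2],
    timestamp = ts[ord], age = age[ord], sex = sex[ord],
    stringsAsFactors = FALSE)
  class(runs) <- c("ems_runs", "data.frame")
  list(runs = runs,
       window = w,
       truth = data.frame(run_id = runs$run_id, component = component[ord],
                          stringsAsFactors = FALSE))
}

#' Write runs to the standard CSV layout
#'
#' @param runs runs data frame.
#' @param path output CSV.
#' @export
write_runs_csv <- function(runs, path) {
  write.csv(runs[, RUNS_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @importFrom stats qnorm
NULL
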