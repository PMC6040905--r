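# Fixture builders. Everything is generated in code at test time; nothing is
# stored on disk.

unit_square <- function() {
  poly_window(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

rect_window <- function(xmin, xmax, ymin, ymax) {
  poly_window(rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax)))
}

# a runs data frame straight from planar coordinates (lon/lat synthesised
# through the window's reference so ingest functions can round-trip it)
runs_from_xy <- function(xy, window = default_boundary(),
                         age = NA_real_, sex = NA_character_,
                         address = NULL) {
  xy <- matrix(as.numeric(unlist(xy)), ncol = 2)
  n <- nrow(xy)
  ll <- plane_to_geo(xy, window$reference)
  if (is.null(address)) address <- sprintf("%d Fixture St", seq_len(n))
  df <- data.frame(
    run_id = sprintf("F%04d", seq_len(n)),
    address = rep_len(address, n),
    lon = ll[, 1], lat = ll[, 2],
    timestamp = "2017-01-01T00:00:00Z",
    age = rep_len(age, n), sex = rep_len(sex, n),
    stringsAsFactors = FALSE)
  class(df) <- c("ems_runs", "data.frame")
  df
}

write_runs_fixture <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "runs.csv")
  write.csv(df[, c("run_id", "address", "lon", "lat", "timestamp", "age", "sex")],
            path, row.names = FALSE, na = "")
  path
}

# Study-shaped ingest fixture: 700 runs over 359 addresses; 6 addresses (7
# runs, one address having two) lack coordinates; the 353 geocoded addresses
# collapse to 349 physical locations (4 coordinate-sharing address pairs);
# 3 single-run locations sit outside the boundary -> 690 runs survive.
make_study_fixture <- function(window = default_boundary(), seed = 42) {
  set.seed(seed)
  n_addr <- 359
  addr <- sprintf("A%03d Fixture St", seq_len(n_addr))
  geocoded <- 7:359                      # 353 addresses with coordinates
  coords <- matrix(NA_real_, n_addr, 2)
  inside <- generate_csr(349, window)
  # 4 address pairs share coordinates: addresses 8..11 reuse 7..10's coords
  ci <- 1L
  for (a in geocoded) {
    if (a %in% 8:11) coords[a, ] <- coords[a - 1, ]
    else { coords[a, ] <- inside[ci, ]; ci <- ci + 1L }
  }
  # 3 outside locations: far east of the boundary, single-run addresses
  outside_addr <- c(100, 200, 300)
  for (k in seq_along(outside_addr)) {
    coords[outside_addr[k], ] <- c(10000 + 50 * k, 0)
  }
  # runs: addresses 1..6 ungeocoded (address 1 has 2 runs -> 7 runs lack
  # coords); geocoded addresses get 1 run each + 340 extra on early ones
  runs_per_addr <- rep(1L, n_addr)
  runs_per_addr[1] <- 2L
  extra <- 340L
  pool <- setdiff(geocoded, outside_addr)
  runs_per_addr[pool[1:85]] <- runs_per_addr[pool[1:85]] + 4L
  idx <- rep(seq_len(n_addr), runs_per_addr)
  stopifnot(length(idx) == 700)
  ll <- matrix(NA_real_, length(idx), 2)
  has <- !is.na(coords[idx, 1])
  ll[has, ] <- plane_to_geo(coords[idx[has], , drop = FALSE], window$reference)
  df <- data.frame(
    run_id = sprintf("S%04d", seq_along(idx)),
    address = addr[idx],
    lon = ll[, 1], lat = ll[, 2],
    timestamp = "2017-01-01T00:00:00Z",
    age = NA_real_, sex = NA_character_,
    stringsAsFactors = FALSE)
  class(df) <- c("ems_runs", "data.frame")
  df
}

local_boundary_geojson <- function(window = default_boundary(),
                                   dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "boundary.geojson")
  write_boundary_geojson(window, path)
  path
}
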