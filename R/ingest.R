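# Data preparation: parse the runs CSV, collapse runs to unique physical
# locations, and clip to the city boundary. Mirrors the attrition chain of a
# typical EMS dataset: all runs -> runs with usable coordinates -> unique
# locations -> in-boundary runs.

RUNS_COLUMNS <- c("run_id", "address", "lon", "lat", "timestamp", "age", "sex")
SEX_LEVELS <- c("male", "female", "unknown")

#' Load EMS run records from CSV
#'
#' Expected columns: \code{run_id, address, lon, lat, timestamp, age, sex}.
#' Missing age/sex/coordinates are preserved as \code{NA} (never imputed).
#' Rows that cannot be parsed (non-numeric coordinates, ages outside
#' \[0, 130\], unrecognised sex codes) are skipped with a warning and counted
#' in \code{attr(, "n_skipped")}. Duplicate \code{run_id}s are an error.
#' Geocoding (address to coordinate) is out of scope: coordinates either
#' arrive in the CSV or are filled from an optional address lookup table.
#'
#' @param path runs CSV.
#' @param lookup optional data frame or CSV path with columns
#'   \code{address, lon, lat}, used to fill missing coordinates by exact
#'   address match.
#' @param quiet suppress the summary message.
#' @return data frame of runs (class \code{ems_runs}) with numeric
#'   \code{lon/lat/age} and \code{sex} in \code{male/female/unknown/NA}.
#' @export
load_runs <- function(path, lookup = NULL, quiet = FALSE) {
  raw <- tryCatch(
    read.csv(path, colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse runs file ", path, ": ",
                             conditionMessage(e)))
  missing_cols <- setdiff(RUNS_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("runs file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) stop("runs file ", path, " contains no records")

  blank <- function(v) is.na(v) | !nzchar(trimws(v))
  num_or_na <- function(v) suppressWarnings(as.numeric(ifelse(blank(v), NA, v)))

  lon <- num_or_na(raw$lon)
  lat <- num_or_na(raw$lat)
  age <- num_or_na(raw$age)
  sex <- tolower(trimws(raw$sex))
  sex[blank(raw$sex)] <- NA

  bad <- (!blank(raw$lon) & is.na(lon)) |
    (!blank(raw$lat) & is.na(lat)) |
    (is.na(lon) != is.na(lat)) |
    (!blank(raw$age) & (is.na(age) | age < 0 | age > 130)) |
    (!is.na(sex) & !sex %in% SEX_LEVELS) |
    blank(raw$run_id)
  if (any(bad)) {
    warning(sprintf("skipped %d malformed row(s) in %s", sum(bad), path))
  }
  runs <- data.frame(
    run_id = trimws(raw$run_id), address = raw$address,
    lon = lon, lat = lat, timestamp = raw$timestamp,
    age = age, sex = sex,
    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(runs) <- NULL

  dup <- unique(runs$run_id[duplicated(runs$run_id)])
  if (length(dup)) {
    stop("duplicate run_id(s): ", paste(head(dup, 5), collapse = ", "))
  }

  if (!is.null(lookup)) {
    if (is.character(lookup)) {
      lookup <- read.csv(lookup, stringsAsFactors = FALSE)
    }
    hit <- is.na(runs$lon) & runs$address %in% lookup$address
    m <- match(runs$address[hit], lookup$address)
    runs$lon[hit] <- as.numeric(lookup$lon[m])
    runs$lat[hit] <- as.numeric(lookup$lat[m])
  }

  n_geo <- sum(!is.na(runs$lon))
  if (!quiet) {
    message(sprintf("loaded %d run(s): %d with coordinates, %d without%s",
                    nrow(runs), n_geo, nrow(runs) - n_geo,
                    if (any(bad)) sprintf(" (%d skipped)", sum(bad)) else ""))
  }
  attr(runs, "n_skipped") <- sum(bad)
  class(runs) <- c("ems_runs", "data.frame")
  runs
}

#' Geocoding attrition summary
#'
#' Counts and percentages at both the run and the unique-address level, the
#' two denominators used when reporting geocoding success.
#'
#' @param runs an \code{ems_runs} data frame.
#' @return list with \code{n_runs}, \code{runs_with_coord}, \code{pct_runs},
#'   \code{n_addresses}, \code{addresses_with_coord}, \code{pct_addresses}.
#' @export
geocoding_summary <- function(runs) {
  has <- !is.na(runs$lon) & !is.na(runs$lat)
  addr <- unique(runs$address)
  addr_has <- vapply(addr, function(a) any(has[runs$address == a]), TRUE)
  list(
    n_runs = nrow(runs),
    runs_with_coord = sum(has),
    pct_runs = 100 * sum(has) / nrow(runs),
    n_addresses = length(addr),
    addresses_with_coord = sum(addr_has),
    pct_addresses = 100 * sum(addr_has) / length(addr))
}

#' Project run coordinates into a window's planar system
#'
#' @param runs an \code{ems_runs} data frame; rows without coordinates are
#'   dropped (with a message stating how many).
#' @param window the analysis [poly_window()]; its reference is used.
#' @param quiet suppress the message.
#' @return runs with added planar \code{x}, \code{y} columns (metres).
#' @export
project_runs <- function(runs, window, quiet = FALSE) {
  has <- !is.na(runs$lon) & !is.na(runs$lat)
  if (!all(has) && !quiet) {
    message(sprintf("dropping %d run(s) without coordinates", sum(!has)))
  }
  runs <- runs[has, , drop = FALSE]
  xy <- geo_to_plane(cbind(runs$lon, runs$lat), window$reference)
  runs$x <- xy[, 1]
  runs$y <- xy[, 2]
  rownames(runs) <- NULL
  runs
}

#' Collapse runs to unique physical locations
#'
#' Greedy, in input order: a run joins the first existing location whose
#' representative coordinate (that of its first run) lies within
#' \code{tolerance} metres; otherwise it founds a new location. Distinct
#' address strings at one coordinate (e.g. units of one building) collapse to
#' a single location — a location-based rather than address-based view.
#' The 0.5 m default is deliberately below the ~2 m NAD83/WGS84 equivalence
#' bound; raise it to 2 m to merge mixed-datum duplicates.
#'
#' @param runs projected runs (must carry \code{x}, \code{y}; error if any
#'   coordinate is missing).
#' @param tolerance merge radius in metres, >= 0.
#' @return list with \code{locations} (data frame: \code{location_id, x, y,
#'   runs, addresses, run_ids}; the last two are list columns) and
#'   \code{assignment} (location_id per run, aligned with \code{runs}).
#' @export
dedupe_locations <- function(runs, tolerance = 0.5) {
  if (is.null(runs$x) || any(is.na(runs$x) | is.na(runs$y))) {
    stop("dedupe_locations requires projected coordinates for every run")
  }
  if (tolerance < 0) stop("tolerance must be >= 0")
  n <- nrow(runs)
  loc_x <- numeric(0); loc_y <- numeric(0)
  members <- list()
  assignment <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    if (length(loc_x)) {
      d2 <- (loc_x - runs$x[i])^2 + (loc_y - runs$y[i])^2
      ok <- which(d2 <= tolerance^2)
      if (length(ok)) hit <- ok[1]
    }
    if (hit == 0L) {
      loc_x <- c(loc_x, runs$x[i]); loc_y <- c(loc_y, runs$y[i])
      members[[length(loc_x)]] <- i
      hit <- length(loc_x)
    } else {
      members[[hit]] <- c(members[[hit]], i)
    }
    assignment[i] <- hit
  }
  ids <- sprintf("L%04d", seq_along(loc_x))
  locations <- data.frame(
    location_id = ids, x = loc_x, y = loc_y,
    runs = lengths(members), stringsAsFactors = FALSE)
  locations$addresses <- lapply(members, function(m) unique(runs$address[m]))
  locations$run_ids <- lapply(members, function(m) runs$run_id[m])
  list(locations = locations, assignment = ids[assignment])
}

#' Clip locations (and their runs) to the city boundary
#'
#' Locations inside or on the boundary are kept; removals are reported per
#' location with their run counts. Idempotent.
#'
#' @param dedupe result of [dedupe_locations()].
#' @param runs the projected runs the dedupe was built from.
#' @param window the city [poly_window()].
#' @return list with \code{runs} (kept runs, with \code{location_id} column),
#'   \code{locations} (kept), \code{removed} (locations outside), and
#'   \code{report} (data frame: location_id, x, y, runs, kept).
#' @export
clip_to_boundary <- function(dedupe, runs, window) {
  loc <- dedupe$locations
  inside <- points_in_window(cbind(loc$x, loc$y), window)
  runs$location_id <- dedupe$assignment
  keep_run <- runs$location_id %in% loc$location_id[inside]
  report <- data.frame(
    location_id = loc$location_id, x = loc$x, y = loc$y,
    runs = loc$runs, kept = inside, stringsAsFactors = FALSE)
  removed <- loc[!inside, , drop = FALSE]
  if (nrow(removed)) {
    message(sprintf(
      "removed %d location(s) outside the boundary (%d run(s))",
      nrow(removed), sum(removed$runs)))
  }
  list(runs = runs[keep_run, , drop = FALSE],
       locations = loc[inside, , drop = FALSE],
       removed = removed,
       report = report)
}
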