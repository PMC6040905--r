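# Independent oracles used to certify the main implementations. Each is a
# deliberately naive / closed-form alternative: slow or special-cased, but
# easy to convince yourself is correct.

# great-circle distance in metres (haversine, sphere radius as the package's)
haversine_m <- function(lon1, lat1, lon2, lat2, R = 6371000) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# winding-number point-in-polygon (single ring, boundary not special-cased)
winding_inside <- function(px, py, ring) {
  n <- nrow(ring)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[j, 1]; y2 <- ring[j, 2]
    isleft <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    if (y1 <= py) {
      if (y2 > py && isleft > 0) wn <- wn + 1
    } else {
      if (y2 <= py && isleft < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# exact fraction of a circle inside an axis-aligned rectangle, by interval
# union of the four half-plane violation arcs
rect_circle_fraction <- function(cx, cy, r, xmin, xmax, ymin, ymax) {
  arcs <- list()
  add <- function(a, b) arcs[[length(arcs) + 1]] <<- c(a, b)
  two_pi <- 2 * pi
  # cos(theta) < c  (left violation)
  c1 <- (xmin - cx) / r
  if (c1 >= 1) return(0)
  if (c1 > -1) add(acos(c1), two_pi - acos(c1))
  # cos(theta) > c  (right violation)
  c2 <- (xmax - cx) / r
  if (c2 <= -1) return(0)
  if (c2 < 1) { add(0, acos(c2)); add(two_pi - acos(c2), two_pi) }
  # sin(theta) < s  (bottom violation)
  s1 <- (ymin - cy) / r
  if (s1 >= 1) return(0)
  if (s1 > -1) add(pi - asin(s1), two_pi + asin(s1))
  # sin(theta) > s  (top violation)
  s2 <- (ymax - cy) / r
  if (s2 <= -1) return(0)
  if (s2 < 1) add(asin(s2), pi - asin(s2))
  if (!length(arcs)) return(1)
  # normalise to [0, 2pi), split wrap-around arcs, merge the union
  flat <- list()
  for (ab in arcs) {
    a <- ab[1] %% two_pi; b <- a + (ab[2] - ab[1])
    if (b <= two_pi) flat[[length(flat) + 1]] <- c(a, b)
    else { flat[[length(flat) + 1]] <- c(a, two_pi)
           flat[[length(flat) + 1]] <- c(0, b - two_pi) }
  }
  m <- do.call(rbind, flat)
  m <- m[order(m[, 1]), , drop = FALSE]
  outside <- 0
  cur <- m[1, ]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= cur[2]) cur[2] <- max(cur[2], m[i, 2])
    else { outside <- outside + cur[2] - cur[1]; cur <- m[i, ] }
  }
  outside <- outside + cur[2] - cur[1]
  1 - outside / two_pi
}

# gift-wrapping (Jarvis march) convex hull; returns vertex rows
gift_wrap_hull <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 3) return(xy)
  start <- which.min(xy[, 1] + 1e-12 * xy[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- 1L
    for (j in seq_len(n)) {
      if (j == cur) next
      cross <- (xy[cand, 1] - xy[cur, 1]) * (xy[j, 2] - xy[cur, 2]) -
        (xy[cand, 2] - xy[cur, 2]) * (xy[j, 1] - xy[cur, 1])
      d_cand <- sum((xy[cand, ] - xy[cur, ])^2)
      d_j <- sum((xy[j, ] - xy[cur, ])^2)
      if (cand == cur || cross < 0 || (cross == 0 && d_j > d_cand)) cand <- j
    }
    cur <- cand
    if (cur == start) break
  }
  xy[hull, , drop = FALSE]
}

# O(n^2) k-th nearest neighbour distances by full sort
brute_knn <- function(xy, k) {
  n <- nrow(xy)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    out[i] <- sort(d[-i])[k]
  }
  sort(out)
}

# DBSCAN by definition: core flags + density-reachability transitive closure
# over core points; border points are *not* assigned (their cluster is
# order-dependent), so comparisons restrict to cores
brute_dbscan_cores <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  d <- as.matrix(dist(xy))
  adj <- d <= eps
  core <- rowSums(adj) >= min_pts
  reach <- adj & outer(core, core, "&")
  diag(reach) <- core
  # transitive closure (Floyd-Warshall style on the core subgraph)
  for (k in which(core)) {
    reach <- reach | (reach[, k] %o% reach[k, ])
  }
  comp <- rep(NA_integer_, n)
  cl <- 0
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    cl <- cl + 1
    comp[reach[i, ] & core] <- cl
    comp[i] <- cl
  }
  list(core = core, comp = comp)
}

# brute-force Ripley K in a rectangle using the closed-form arc fractions
brute_k_rect <- function(xy, radii, xmin, xmax, ymin, ymax) {
  n <- nrow(xy)
  area <- (xmax - xmin) * (ymax - ymin)
  k <- numeric(length(radii))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    w <- if (d == 0) 1 else
      1 / rect_circle_fraction(xy[i, 1], xy[i, 2], d, xmin, xmax, ymin, ymax)
    k <- k + w * (radii >= d)
  }
  k * area / (n * (n - 1))
}

# partitions as co-membership: identical up to label permutation?
same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}
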