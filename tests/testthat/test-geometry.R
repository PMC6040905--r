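test_that("local projection: identity at reference, haversine agreement, round trip", {
  ref <- c(-71.11, 42.37)
  expect_equal(unname(geo_to_plane(ref, ref)[1, ]), c(0, 0))

  # 0.01 degrees of latitude is ~1111.95 m; planar distance must match the
  # great-circle oracle to within the 2 m datum-equivalence tolerance
  p <- rbind(c(-71.11, 42.37), c(-71.11, 42.38))
  xy <- geo_to_plane(p, ref)
  planar <- sqrt(sum((xy[2, ] - xy[1, ])^2))
  expect_equal(planar, 1111.95, tolerance = 1e-4)
  expect_lt(abs(planar - haversine_m(p[1, 1], p[1, 2], p[2, 1], p[2, 2])), 2)

  # pairs across a ~5 km extent stay within 2 m of great-circle distances
  set.seed(7)
  q <- cbind(ref[1] + runif(50, -0.03, 0.03), ref[2] + runif(50, -0.02, 0.02))
  pq <- geo_to_plane(q, ref)
  for (i in c(1, 10, 25)) {
    dp <- sqrt((pq[, 1] - pq[i, 1])^2 + (pq[, 2] - pq[i, 2])^2)
    dh <- haversine_m(q[, 1], q[, 2], q[i, 1], q[i, 2])
    expect_lt(max(abs(dp - dh)), 2)
  }

  # inverse reprojection recovers inputs
  back <- plane_to_geo(pq, ref)
  expect_lt(max(abs(back - q)), 1e-9)

  expect_error(geo_to_plane(c(-70, 42.37), ref), "0.5 degrees")
})

test_that("point-in-window matches winding-number oracle and counts boundary as inside", {
  w <- unit_square()
  expect_true(points_in_window(c(0.5, 0.5), w))
  expect_true(points_in_window(c(0.5, 0), w))   # on an edge
  expect_true(points_in_window(c(0, 0), w))     # at a vertex
  expect_false(points_in_window(c(1.5, 0.5), w))

  set.seed(11)
  pts <- cbind(runif(1000, -0.3, 1.3), runif(1000, -0.3, 1.3))
  got <- points_in_window(pts, w)
  want <- vapply(seq_len(nrow(pts)),
                 function(i) winding_inside(pts[i, 1], pts[i, 2], w$rings[[1]]),
                 TRUE)
  expect_identical(got, want)

  # irregular polygon too
  wb <- default_boundary()
  pts <- cbind(runif(500, -3000, 3000), runif(500, -3000, 3000))
  got <- points_in_window(pts, wb)
  want <- vapply(seq_len(nrow(pts)),
                 function(i) winding_inside(pts[i, 1], pts[i, 2], wb$rings[[1]]),
                 TRUE)
  expect_identical(got, want)
})

test_that("circle_inside_fraction: interior, half-plane formula, rectangle oracle", {
  w <- rect_window(0, 1000, 0, 1000)
  expect_identical(circle_inside_fraction(c(500, 500), 100, w), 1)
  # centre 5 m from one straight edge, radius 10: 1 - acos(0.5)/pi = 2/3
  expect_equal(circle_inside_fraction(c(500, 5), 10, w), 2 / 3,
               tolerance = 2 / 720)

  set.seed(3)
  res <- 720
  for (rep in 1:40) {
    cx <- runif(1, 1, 999); cy <- runif(1, 1, 999)
    r <- runif(1, 5, 600)
    got <- circle_inside_fraction(c(cx, cy), r, w, resolution = res)
    want <- rect_circle_fraction(cx, cy, r, 0, 1000, 0, 1000)
    expect_lt(abs(got - want), 2 / res)
  }

  expect_error(circle_inside_fraction(c(-5, 500), 10, w), "outside")
  expect_error(circle_inside_fraction(c(500, 500), 10, w, resolution = 10),
               "resolution")
})

test_that("circle_inside_fraction is monotone non-increasing in radius (convex window)", {
  w <- rect_window(0, 1000, 0, 800)
  set.seed(5)
  for (rep in 1:10) {
    ctr <- c(runif(1, 10, 990), runif(1, 10, 790))
    radii <- seq(10, 700, by = 50)
    fr <- vapply(radii, function(r) circle_inside_fraction(ctr, r, w), 0)
    expect_true(all(diff(fr) <= 1e-9))
    expect_true(all(fr >= 0 & fr <= 1))
  }
})

test_that("convex hull matches gift-wrapping oracle and contains its inputs", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- convex_hull(sq)
  expect_equal(h$area, 1.0)
  expect_false(h$degenerate)

  col <- rbind(c(0, 0), c(1, 1), c(2, 2))
  hd <- convex_hull(col)
  expect_true(hd$degenerate)
  expect_equal(hd$area, 0)

  expect_error(convex_hull(matrix(numeric(0), ncol = 2)), "empty")

  set.seed(21)
  xy <- cbind(rnorm(200), rnorm(200))
  h <- convex_hull(xy)
  oracle <- gift_wrap_hull(xy)
  # same vertex set (order may differ)
  expect_setequal(apply(h$rings[[1]], 1, paste, collapse = ","),
                  apply(oracle, 1, paste, collapse = ","))
  expect_true(all(points_in_window(xy, h)))
  bbox_area <- diff(range(xy[, 1])) * diff(range(xy[, 2]))
  expect_gte(h$area, 0)
  expect_lte(h$area, bbox_area)
})

test_that("centroid: multiplicity weighting and hull containment", {
  expect_equal(unname(centroid_points(c(3, 4))), c(3, 4))
  expect_equal(unname(centroid_points(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))),
               c(1, 1))
  # 76 co-located runs drag the centroid: 9 * 85 / 85 = 9
  xy <- rbind(matrix(rep(c(0, 0), 76), ncol = 2, byrow = TRUE),
              matrix(rep(c(85, 0), 9), ncol = 2, byrow = TRUE))
  expect_equal(unname(centroid_points(xy)), c(9, 0))

  set.seed(9)
  pts <- cbind(runif(50), runif(50))
  ctr <- centroid_points(pts)
  expect_true(points_in_window(matrix(ctr, ncol = 2), convex_hull(pts)))
})
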