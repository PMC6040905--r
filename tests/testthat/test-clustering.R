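test_that("knn distances: corner square, coincident zeros, brute-force oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(knn_distances(sq, k = 1), c(1, 1, 1, 1))
  expect_error(knn_distances(sq, k = 4), "more than k")

  dup <- rbind(c(0, 0), c(0, 0), c(5, 5))
  expect_equal(knn_distances(dup, k = 1)[1:2], c(0, 0))

  set.seed(61)
  for (rep in 1:10) {
    xy <- cbind(runif(30, 0, 100), runif(30, 0, 100))
    k <- sample(1:5, 1)
    expect_equal(knn_distances(xy, k), brute_knn(xy, k))
  }
})

test_that("dbscan: trivial all-noise and spike-driven cluster", {
  # 5 points pairwise farther than eps: all noise
  far <- cbind(seq(0, 4000, by = 1000), rep(0, 5))
  a <- dbscan_runs(far, eps = 200, min_pts = 3)
  expect_true(all(a$labels == 0))
  expect_true(all(!a$core))

  # 76 coincident runs plus 2 within 200 m: one cluster of all 78
  xy <- rbind(matrix(rep(c(0, 0), 76), ncol = 2, byrow = TRUE),
              c(150, 0), c(0, 180))
  a <- dbscan_runs(xy, eps = 200, min_pts = 3)
  expect_equal(unique(a$labels), 1L)
  expect_equal(sum(a$labels == 1), 78)
})

test_that("dbscan equals the density-reachability closure oracle on random instances", {
  set.seed(67)
  for (rep in 1:60) {
    n <- sample(5:50, 1)
    xy <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
    # mix in duplicates so multiplicity matters
    if (n > 10) xy[1:3, ] <- xy[rep(4, 3), ]
    eps <- runif(1, 50, 400)
    min_pts <- sample(2:5, 1)
    a <- dbscan_runs(xy, eps, min_pts)
    o <- brute_dbscan_cores(xy, eps, min_pts)
    expect_identical(a$core, unname(o$core))
    # partition restricted to core points identical up to relabelling
    if (any(o$core)) {
      expect_true(same_partition(a$labels[o$core], o$comp[o$core]))
    }
    # every core point clustered; noise never core
    expect_true(all(a$labels[a$core] > 0))
    expect_true(all(!a$core[a$labels == 0]))
  }
})

test_that("dbscan core partition is permutation invariant; labels deterministic", {
  set.seed(71)
  xy <- rbind(matrix(rnorm(60, 100, 30), ncol = 2),
              matrix(rnorm(60, 600, 30), ncol = 2),
              cbind(runif(20, 0, 800), runif(20, 0, 800)))
  a1 <- dbscan_runs(xy, 120, 3)
  perm <- sample(nrow(xy))
  a2 <- dbscan_runs(xy[perm, ], 120, 3)
  expect_identical(a1$core[perm], a2$core)
  core <- a2$core
  expect_true(same_partition(a1$labels[perm][core], a2$labels[core]))
  # re-run identical
  expect_identical(a1$labels, dbscan_runs(xy, 120, 3)$labels)
})

test_that("growing eps never shrinks the cluster around a fixed core point", {
  set.seed(73)
  for (rep in 1:5) {
    xy <- rbind(matrix(rnorm(80, 0, 60), ncol = 2),
                matrix(rnorm(40, 500, 80), ncol = 2))
    sizes <- vapply(c(60, 100, 150, 220, 300), function(eps) {
      a <- dbscan_runs(xy, eps, 3)
      if (!a$core[1]) return(0L)
      sum(a$labels == a$labels[1])
    }, 0L)
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("filter_clusters: threshold arithmetic and run conservation", {
  # synthetic assignment with cluster sizes 86, 191, 85, 12
  labels <- rep(c(1L, 2L, 3L, 4L, 0L), c(86, 191, 85, 12, 316))
  a <- structure(list(labels = labels, core = labels > 0, eps = 200,
                      min_pts = 3, n = length(labels)),
                 class = "cluster_assignment")
  f <- filter_clusters(a, total_runs = 690, min_fraction = 0.10)
  expect_equal(f$threshold, 69)
  expect_equal(f$kept, c(1L, 2L, 3L))
  expect_equal(tabulate(f$assignment$labels), c(86, 191, 85))
  expect_equal(length(f$assignment$labels), a$n)  # kept + demoted + noise = n

  f1 <- filter_clusters(a, total_runs = 690, min_fraction = 1.0)
  expect_lte(length(f1$kept), 1)

  # regression: noise interleaved among clusters must not shift labels
  set.seed(99)
  labels2 <- sample(labels)
  a2 <- structure(list(labels = labels2, core = labels2 > 0, eps = 200,
                       min_pts = 3, n = length(labels2)),
                  class = "cluster_assignment")
  f2 <- filter_clusters(a2, total_runs = 690, min_fraction = 0.10)
  expect_equal(tabulate(f2$assignment$labels), c(86, 191, 85))
  # every kept run keeps its co-membership
  for (k in 1:3) {
    expect_true(all(labels2[f2$assignment$labels == k] == k))
  }
})

test_that("classify_cluster: dominance conventions", {
  # modal share 76/85 = 89.4% -> single-location
  ids <- c(rep("L1", 76), paste0("L", 2:10))
  cl <- classify_cluster(ids)
  expect_equal(cl$type, "single-location")
  expect_equal(cl$modal_runs, 76)
  expect_equal(round(100 * cl$modal_share, 1), 89.4)

  expect_equal(classify_cluster(paste0("L", 1:8))$type, "multi-location")
  # exactly at the threshold: single (>= convention)
  expect_equal(classify_cluster(c("A", "A", "B", "C"), dominance = 0.5)$type,
               "single-location")
  # two locations tying at the top: multi
  expect_equal(classify_cluster(c("A", "A", "B", "B"))$type, "multi-location")
  expect_error(classify_cluster(character(0)), "empty")
})

test_that("adjusted Rand index behaves at the reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
  set.seed(79)
  a <- sample(1:4, 400, replace = TRUE)
  b <- sample(1:4, 400, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.1)
})
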