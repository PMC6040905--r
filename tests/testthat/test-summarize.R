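test_that("summarize_cluster: degenerate coincident cluster and radius counts", {
  xy <- matrix(rep(c(10, 20), 30), ncol = 2, byrow = TRUE)
  s <- summarize_cluster(xy, rep("L1", 30), age = rep(40, 30),
                         sex = rep("female", 30))
  expect_equal(s$runs, 30)
  expect_equal(s$locations, 1)
  expect_equal(s$area, 0)
  expect_equal(s$m_dist, 0)
  expect_equal(s$n_in_radius, 30)
  expect_equal(s$pct_in_radius, 100)
  expect_equal(s$m_age, 40)
  expect_equal(s$pct_female, 100)
  expect_error(summarize_cluster(xy[0, , drop = FALSE], character(0)), "empty")
})

test_that("p200 arithmetic: 75 of 86 runs within 200 m gives 87.2%", {
  # 75 runs at one spot, 11 runs 1 km away: centroid sits 127.9 m from the
  # big group (within 200), 872 m from the small one (beyond)
  xy <- rbind(matrix(rep(c(0, 0), 75), ncol = 2, byrow = TRUE),
              matrix(rep(c(0, 1000), 11), ncol = 2, byrow = TRUE))
  ids <- c(rep("L1", 75), rep("L2", 11))
  s <- summarize_cluster(xy, ids)
  expect_equal(s$runs, 86)
  expect_equal(s$n_in_radius, 75)
  expect_equal(round(s$pct_in_radius, 1), 87.2)
})

test_that("median run-to-centroid distance is spike-dominated and matches a sort oracle", {
  set.seed(83)
  # 76 runs at a spot 15 m from where the centroid will land, 9 spread out
  spread <- cbind(runif(9, 10, 400), 0)
  spike <- matrix(rep(c(0, 0), 76), ncol = 2, byrow = TRUE)
  xy <- rbind(spike, spread)
  ctr <- centroid_points(xy)
  d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  # oracle: full sort; n = 85 is odd so the median is the 43rd order statistic
  sorted <- sort(d)
  s <- summarize_cluster(xy, c(rep("L1", 76), paste0("L", 2:10)))
  expect_equal(s$m_dist, median(d))
  expect_equal(s$m_dist, sorted[43])
  expect_equal(s$m_dist, d[1])             # the spike's own distance
  expect_lte(s$m_dist, max(d))

  # even-count median: mean of the two middle order statistics
  s2 <- summarize_cluster(xy[1:84, ], rep("L", 84))
  d2 <- sqrt((xy[1:84, 1] - mean(xy[1:84, 1]))^2 +
             (xy[1:84, 2] - mean(xy[1:84, 2]))^2)
  expect_equal(s2$m_dist, mean(sort(d2)[42:43]))
})

test_that("hull area uses unique locations; centroid uses runs", {
  xy <- rbind(matrix(rep(c(0, 0), 20), ncol = 2, byrow = TRUE),
              c(100, 0), c(0, 100), c(100, 100))
  ids <- c(rep("L1", 20), "L2", "L3", "L4")
  s <- summarize_cluster(xy, ids)
  expect_equal(s$area, 100 * 100)  # multiplicity cannot inflate geometry
  expect_equal(unname(s$centroid),
               c((100 + 100) / 23, (100 + 100) / 23))
  s2 <- summarize_cluster(xy, ids, hull_on = "runs")
  expect_equal(s2$area, s$area)    # same unique support here
  s3 <- summarize_cluster(xy, ids, centroid_on = "locations")
  expect_equal(unname(s3$centroid), c(50, 50))
})

test_that("location frequency profile reproduces the study's shape", {
  # 242 single-run locations, 40 x 3, 63 x 4, one 76-run outlier = 690 runs
  counts <- c(rep(1, 242), rep(3, 40), rep(4, 63), 76)
  ids <- rep(sprintf("L%03d", seq_along(counts)), counts)
  p <- location_frequency_profile(ids)
  expect_equal(p$n_locations, 346)
  expect_equal(p$n_runs, 690)
  expect_equal(p$profile$n_locations[p$profile$multiplicity == 1], 242)
  expect_equal(round(100 * 242 / 346, 1), 69.9)
  expect_equal(p$top_runs, 76)
  expect_equal(round(p$top_share_pct, 1), 11.0)
  # conservation: sum(multiplicity * count) = total runs
  expect_equal(sum(p$profile$multiplicity * p$profile$n_locations), 690)

  p1 <- location_frequency_profile(letters[1:5])
  expect_equal(p1$profile, data.frame(multiplicity = 1L, n_locations = 5L,
                                      pct_locations = 100))
  expect_equal(p1$top_share_pct, 20)
})

test_that("subgroup comparison uses linear-interpolation quantiles", {
  g <- compare_subgroups(c(36.5, 43, 58.5), c("male", "male", "female"),
                         c(20, 35, 50), c("female", "female", "male"))
  expect_equal(g$flagged$median_age, 43)
  # type-7 quantiles: q25 = 36.5 + 0.5*(43-36.5), q75 = 43 + 0.5*(58.5-43)
  expect_equal(g$flagged$age_iqr, c(39.75, 50.75))
  # independent oracle for the quantile rule
  oracle_q <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(g$flagged$age_iqr,
               c(oracle_q(c(36.5, 43, 58.5), 0.25),
                 oracle_q(c(36.5, 43, 58.5), 0.75)))
  expect_equal(g$flagged$pct_female, 100 / 3)

  # identical groups give identical summaries
  s <- compare_subgroups(c(30, 40), c("male", "female"),
                         c(30, 40), c("male", "female"))
  expect_identical(s$flagged, s$rest)
  expect_error(compare_subgroups(numeric(0), character(0), 1, "male"),
               "nonempty")
})

test_that("spike subgroup age parameter is recovered on the shipped preset", {
  meds <- vapply(1:30, function(s) {
    d <- generate_dataset(preset_paper_like(seed = s))
    spike <- d$truth$component == "spike"
    median(d$runs$age[spike], na.rm = TRUE)
  }, 0)
  expect_lt(abs(mean(meds) - 43), 3)
})

test_that("cluster_table is reproducible bit-for-bit from a saved assignment", {
  d <- generate_dataset(preset_paper_like(seed = 3))
  runs <- project_runs(d$runs, d$window, quiet = TRUE)
  dd <- dedupe_locations(runs, 0.5)
  runs$location_id <- dd$assignment
  a <- dbscan_runs(cbind(runs$x, runs$y), 200, 3)
  f <- filter_clusters(a, nrow(runs), 0.10)
  t1 <- cluster_table(runs, f$assignment)
  t2 <- cluster_table(runs, f$assignment)
  expect_identical(t1, t2)
  expect_true(all(t1$locations <= t1$runs))
  expect_true(all(t1$p_200 >= 0 & t1$p_200 <= 100))
})
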