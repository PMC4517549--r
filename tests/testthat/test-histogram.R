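test_that("histogram bins are equal-width with a right-closed final bin", {
  h1 <- compute_histogram(vol3(c(0, 1, 2, 3)), n_bins = 4, foreground_only = FALSE)
  expect_identical(h1$counts, rep(1L, 4))

  h2 <- compute_histogram(vol3(c(1, 2, 2, 3, 3, 3, 4)), n_bins = 4)
  expect_equal(h2$bin_edges, seq(1, 4, length.out = 5))
  expect_identical(h2$counts, c(1L, 2L, 3L, 1L))   # hand count
  expect_identical(h2$n_voxels, 7L)
})

test_that("histogram counts are conserved over random volumes", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(50:5000, 1)
    v <- vol3(runif(n, 0, sample(10:1000, 1)))
    nb <- sample(2:64, 1)
    h <- compute_histogram(v, n_bins = nb, foreground_only = FALSE)
    expect_identical(sum(h$counts), n)
    expect_true(all(diff(h$bin_edges) > 0))
  }
})

test_that("degenerate histogram inputs raise informative errors", {
  expect_error(compute_histogram(vol3(rep(2, 10))), "degenerate constant")
  masked <- vol3(1:10, mask = array(FALSE, c(10, 1, 1)))
  expect_error(compute_histogram(masked), "mask")
})

test_that("histogram_mode is the argmax bin center with low-intensity tie-break", {
  h <- compute_histogram(vol3(c(1, 2, 2, 3, 3, 3, 4)), n_bins = 4)
  expect_equal(histogram_mode(h), (2.5 + 3.25) / 2)  # third bin of [1,4]/4

  tie <- structure(list(bin_edges = c(0, 1, 2), counts = c(5L, 5L), n_voxels = 10L),
                   class = "intensity_histogram")
  expect_equal(histogram_mode(tie), 0.5)

  dom <- structure(list(bin_edges = 0:4, counts = c(0L, 0L, 100L, 0L), n_voxels = 100L),
                   class = "intensity_histogram")
  expect_equal(histogram_mode(dom), 2.5)
})

test_that("a dominant intensity spike sets the histogram mode", {
  v <- vol3(c(seq(0, 100, length.out = 200), rep(77.3, 300)))
  h <- compute_histogram(v, n_bins = 100, foreground_only = FALSE)
  expect_lt(abs(histogram_mode(h) - 77.3), diff(h$bin_edges[1:2]))
})

test_that("percentiles follow the order-statistic oracle on 0..100", {
  v <- vol3(0:100)
  expect_equal(intensity_percentile(v, 0.10, foreground_only = FALSE), 10)
  expect_equal(intensity_percentile(v, 0.90, foreground_only = FALSE), 90)
  expect_equal(intensity_percentile(v, 0, foreground_only = FALSE), 0)
  expect_equal(intensity_percentile(v, 1, foreground_only = FALSE), 100)
  expect_equal(intensity_percentile(vol3(rep(7, 9)), 0.42), 7)
  expect_error(intensity_percentile(v, 1.5), "\\[0, 1\\]")
})

test_that("percentile is non-decreasing in q", {
  set.seed(5)
  v <- vol3(rlnorm(2000, 3, 1))
  qs <- sort(runif(30))
  expect_true(all(diff(intensity_percentile(v, qs)) >= 0))
})

test_that("landmarks of a uniform 0..100 foreground match the closed form", {
  v <- vol3(0:100, mask = array(TRUE, c(101, 1, 1)))
  lm <- compute_landmarks(v)
  expect_equal(lm$low, 10)
  expect_equal(lm$mean_val, 50)
  expect_equal(lm$high, 90)
  expect_equal(lm$obs_min, 0)
  expect_equal(lm$obs_max, 100)
})

test_that("landmarks are affine-equivariant", {
  set.seed(31)
  for (i in 1:10) {
    v <- vol3(rgamma(3000, 4, 0.05) + 1)
    a <- runif(1, 0.2, 5); b <- runif(1, 0, 50)
    lm <- compute_landmarks(v)
    lm2 <- compute_landmarks(vol3(a * v$data + b))
    for (f in c("low", "mean_val", "high", "obs_min", "obs_max"))
      expect_equal(lm2[[f]], a * lm[[f]] + b, tolerance = 1e-9)
  }
})

test_that("degenerate landmark configurations are rejected with advice", {
  expect_error(compute_landmarks(vol3(rep(5, 100))), "quantiles")
  skewed <- vol3(c(rep(1, 95), rep(100, 5)))
  expect_error(compute_landmarks(skewed), "quantiles")
  expect_error(landmark_set(10, 5, 90, 0, 100), "ordering")
})
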