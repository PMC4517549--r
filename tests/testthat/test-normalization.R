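test_that("scale_reference maps LIR to 0 and HIR to 1, leaving background at 0", {
  lm <- landmark_set(10, 60, 110, 5, 200)
  v <- vol3(c(10, 60, 110, 200, 0))
  out <- scale_reference(v, lm)
  expect_equal(out$data[1:4, 1, 1], c(0, 0.5, 1, 1.9))
  expect_equal(out$data[5, 1, 1], 0)  # background untouched
})

test_that("re-scaling a scaled reference is the identity at the landmark quantiles", {
  v <- vol3(1:1000, mask = array(TRUE, c(1000, 1, 1)))
  s1 <- scale_reference(v, compute_landmarks(v))
  lm2 <- compute_landmarks(s1)
  expect_equal(lm2$low, 0, tolerance = 1e-12)
  expect_equal(lm2$high, 1, tolerance = 1e-12)
})

test_that("the worked unit-slope and slope-1.25 mappings give the stated values", {
  il <- landmark_set(0, 50, 100, 0, 100)
  rl <- landmark_set(10, 60, 110, 10, 110)
  m <- normalization_map(il, rl)
  expect_equal(strip_attrs(apply_map(m, c(25, 75))), c(35, 85))
  expect_equal(strip_attrs(apply_map(m, 50)), ceiling(60))  # g = mean -> ceil(mean_ref)

  il2 <- landmark_set(0, 40, 100, 0, 100)
  rl2 <- landmark_set(0, 50, 100, 0, 100)
  m2 <- normalization_map(il2, rl2)
  expect_equal(strip_attrs(apply_map(m2, 20)), 25)  # slope (0-50)/(0-40) = 1.25
})

test_that("apply_map matches a literal scalar transcription of the two-segment formula", {
  set.seed(41)
  for (i in 1:100) {
    il <- random_landmarks(); rl <- random_landmarks()
    g <- runif(50, il$obs_min, il$obs_max)
    for (ceil in c(TRUE, FALSE)) {
      m <- normalization_map(il, rl, apply_ceiling = ceil)
      expect_identical(strip_attrs(apply_map(m, g)),
                       oracle_two_segment(g, il, rl, ceil))
    }
  }
})

test_that("the fitted map is monotone and fixes the landmarks up to ceiling slack", {
  set.seed(42)
  for (i in 1:50) {
    il <- random_landmarks(); rl <- random_landmarks()
    m <- normalization_map(il, rl)
    g <- sort(runif(200, il$obs_min, il$obs_max))
    y <- strip_attrs(apply_map(m, g))
    expect_true(all(diff(y) >= 0))
    expect_lte(abs(strip_attrs(apply_map(m, il$mean_val)) - rl$mean_val), 1)
    expect_lte(abs(strip_attrs(apply_map(m, il$low)) - rl$low), 1)
    expect_lte(abs(strip_attrs(apply_map(m, il$high)) - rl$high), 1)
  }
})

test_that("mapping preserves the intensity ranking up to ceiling ties", {
  set.seed(43)
  il <- random_landmarks(); rl <- random_landmarks()
  m <- normalization_map(il, rl)
  g <- runif(500, il$obs_min, il$obs_max)
  y <- strip_attrs(apply_map(m, g))
  expect_true(all(diff(y[order(g)]) >= 0))
})

test_that("out-of-range gray values are clamped and counted, not raised", {
  il <- landmark_set(10, 50, 90, 5, 95)
  rl <- landmark_set(20, 60, 100, 15, 105)
  m <- normalization_map(il, rl)
  y <- apply_map(m, c(0, 2, 50, 200))
  expect_identical(attr(y, "clamp"), c(below = 2L, above = 1L))
  expect_equal(y[1], y[2])                                 # both clamped to obs_min
  expect_equal(y[1], strip_attrs(apply_map(m, 5)))
  expect_equal(y[4], strip_attrs(apply_map(m, 95)))
})

test_that("single-segment mode reproduces the plain linear stretch", {
  il <- landmark_set(10, 50, 90, 0, 100)
  rl <- landmark_set(30, 55, 130, 20, 140)
  m1 <- normalization_map(il, rl, segments = 1, apply_ceiling = FALSE)
  g <- seq(0, 100, by = 0.5)
  stretch <- (rl$high - rl$low) / (il$high - il$low) * (g - il$low) + rl$low
  expect_equal(strip_attrs(apply_map(m1, g)), stretch, tolerance = 1e-12)
})

test_that("fitting input == reference yields a near-identity transfer", {
  set.seed(44)
  v <- vol3(rgamma(5000, 6, 0.04))
  m <- fit_map(v, v)
  g <- foreground_values(v)[1:500]
  expect_lte(max(abs(strip_attrs(apply_map(m, g)) - g)), 1)  # ceiling slack only
})

test_that("self-normalization changes no voxel by more than one gray level", {
  p <- simulate_pair(small_spec(seed = 3))
  res <- normalize_volume(p$vol_a, p$vol_a)
  expect_lte(max(abs(res$volume$data - p$vol_a$data)), 1 + 1e-9)
})

test_that("fit_map identifies the offending image on degenerate landmarks", {
  good <- vol3(1:1000)
  flat <- vol3(rep(5, 1000))
  expect_error(fit_map(flat, good), "input image")
  expect_error(fit_map(good, flat), "reference image")
})

test_that("normalizing a phantom pair shrinks the histogram distance to the reference", {
  p <- simulate_pair(small_spec(seed = 7))
  res <- normalize_volume(p$vol_b, p$vol_a)
  rep <- res$report
  expect_lt(rep$w1_to_reference_after, rep$w1_to_reference_before)
  il <- res$map$input_landmarks; rl <- res$map$reference_landmarks
  expect_gt((rl$low - rl$mean_val) / (il$low - il$mean_val), 0)
  expect_gt((rl$high - rl$mean_val) / (il$high - il$mean_val), 0)
  # range contract: output foreground lies within the mapped input extrema
  out_fg <- res$volume$data[foreground_mask(p$vol_b)]
  ends <- strip_attrs(apply_map(res$map, c(il$obs_min, il$obs_max)))
  expect_gte(min(out_fg), ends[1])
  expect_lte(max(out_fg), ends[2])
})

test_that("unit_scale mode maps onto the unit reference scale without ceiling", {
  p <- simulate_pair(small_spec(seed = 5))
  cfg <- run_config(scale_mode = "unit_scale", ceiling = TRUE)
  res <- normalize_volume(p$vol_b, p$vol_a, cfg)
  expect_false(res$map$apply_ceiling)  # fractional gray levels: ceiling off
  il <- res$map$input_landmarks
  expect_equal(strip_attrs(apply_map(res$map, il$low)), 0)
  expect_equal(strip_attrs(apply_map(res$map, il$high)), 1)
})

test_that("wasserstein1 matches hand-computable cases", {
  expect_equal(wasserstein1(c(0, 1), c(0, 1)), 0)
  expect_equal(wasserstein1(c(0, 1), c(2, 3)), 2)   # pure shift by 2
  expect_equal(wasserstein1(0, 5), 5)
  set.seed(45)
  x <- rnorm(1000)
  expect_equal(wasserstein1(x, x + 3), 3, tolerance = 1e-9)
})
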