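test_that("strength survival curve counts nodes above threshold", {
  # all strengths equal: step function
  m <- matrix(0.4, 3, 3); diag(m) <- NA
  sc <- strength_survival_curve(m, tau_grid = seq(0, 1, 0.05))
  s0 <- 0.4 * 2 / 2  # strength 0.8 normalized by n - 1 = 2
  expect_true(all(sc$normalized_degree[sc$tau < s0] == 1))
  expect_true(all(sc$normalized_degree[sc$tau > s0] == 0))

  # strengths 0.3, 0.6, 0.9, 1.2 over 3 partners => normalized {0.1 .. 0.4}:
  # survival at tau = 0.25 is 0.5
  tgt <- c(0.3, 0.6, 0.9, 1.2)
  m2 <- matrix(0, 4, 4)
  m2[1, ] <- c(0, 0.1, 0.1, 0.1); m2[2, ] <- c(0.1, 0, 0.1, 0.4)
  m2[3, ] <- c(0.1, 0.1, 0, 0.7); m2[4, ] <- c(0.1, 0.4, 0.7, 0)
  expect_equal(unname(total_flow(m2)), tgt)
  sc2 <- strength_survival_curve(m2, tau_grid = 0.25)
  expect_equal(sc2$normalized_degree, 0.5)

  # monotone nonincreasing for random input, negatives floored
  set.seed(8)
  m3 <- matrix(rnorm(100, 0, 0.4), 10, 10); m3 <- (m3 + t(m3)) / 2
  sc3 <- strength_survival_curve(m3)
  expect_true(all(diff(sc3$normalized_degree) <= 0))
  expect_equal(sc3$normalized_degree[length(sc3$tau)], 0)
})

test_that("stretched exponential fit recovers exact generative parameters", {
  tau <- seq(0, 1, length.out = 50)
  fit <- fit_stretched_exponential(
    data.frame(tau = tau, normalized_degree = exp(-2 * tau^0.5)))
  expect_equal(fit$alpha, 2, tolerance = 1e-3)
  expect_equal(fit$beta, 0.5, tolerance = 1e-3)
  expect_true(fit$converged)

  # beta = 1 plain-exponential limit
  fit2 <- fit_stretched_exponential(
    data.frame(tau = tau, normalized_degree = exp(-3 * tau)))
  expect_equal(fit2$alpha, 3, tolerance = 1e-3)
  expect_equal(fit2$beta, 1, tolerance = 1e-3)

  expect_error(fit_stretched_exponential(
    data.frame(tau = tau, normalized_degree = rep(1, 50))), "degenerate|inside")
})

test_that("refitting a curve sampled from its own fit is idempotent", {
  tau <- seq(0, 1, length.out = 101)
  f1 <- list(alpha = 1.7, beta = 0.8)
  curve <- data.frame(tau = tau, normalized_degree = exp(-1.7 * tau^0.8))
  f2 <- fit_stretched_exponential(curve)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-6)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
})

test_that("ICD difference is zero for identical epochs and matches closed form", {
  set.seed(21)
  m <- matrix(runif(64, 0, 0.5), 8, 8); m <- (m + t(m)) / 2
  sc <- strength_survival_curve(m)
  for (grid in list(NULL, seq(0, 1, 0.02))) {
    d <- icd_difference(sc, sc, tau_grid = grid)
    expect_true(all(abs(d$difference) < 1e-9))
  }
  d_emp <- icd_difference(sc, sc, source = "empirical")
  expect_true(all(d_emp$difference == 0))

  # fits alpha=1 vs alpha=3 (beta = 1): peak at ln(3)/2 in closed form
  g <- seq(0, 1, length.out = 2001)
  dc <- data.frame(tau = g, difference = exp(-g) - exp(-3 * g))
  mt <- difference_metrics(dc)
  expect_equal(mt$peak_location, log(3) / 2, tolerance = 1e-3)
  expect_equal(mt$peak_height, exp(-log(3) / 2) - exp(-3 * log(3) / 2),
               tolerance = 1e-6)
})

test_that("difference metrics reproduce analytic triangle and Gaussian geometry", {
  # symmetric triangle: peak 0.4 at 0.3, base width 0.2
  g <- seq(0, 1, length.out = 1001)
  tri <- pmax(0, 0.4 * (1 - abs(g - 0.3) / 0.1))
  mt <- difference_metrics(data.frame(tau = g, difference = tri))
  expect_equal(mt$width_half_peak, 0.1, tolerance = 1e-6)
  expect_equal(mt$peak_location, 0.3, tolerance = 1e-3)
  expect_equal(mt$peak_height, 0.4, tolerance = 1e-6)
  expect_equal(mt$auc, 0.04, tolerance = 1e-4)

  z <- difference_metrics(data.frame(tau = g, difference = rep(0, length(g))))
  expect_equal(z$width_half_peak, 0)
  expect_equal(z$auc, 0)

  sigma <- 0.08
  gauss <- 0.3 * exp(-(g - 0.4)^2 / (2 * sigma^2))
  mg <- difference_metrics(data.frame(tau = g, difference = gauss))
  expect_equal(mg$width_half_peak, 2.3548 * sigma, tolerance = 0.01)
})

test_that("refinement classification requires thresholds and separates the benchmark", {
  mt <- structure(list(width_half_peak = 0.2, peak_height = 0.3,
                       peak_location = 0.2, auc = 0.05, refined = NA),
                  class = "icd_metrics")
  expect_error(classify_refinement(mt), "thresholds")
  expect_true(classify_refinement(mt, 0.1, 0.1)$refined)
  expect_false(classify_refinement(mt, 0.25, 0.1)$refined)

  thr <- default_refinement_thresholds()
  ref <- lapply(1:6, function(s) culture_icd_metrics(TRUE, s, n_neurons = 50))
  non <- lapply(1:6, function(s) culture_icd_metrics(FALSE, 100 + s, n_neurons = 50))
  calls_ref <- vapply(ref, function(m)
    classify_refinement(m, thr$width_min, thr$location_min)$refined, logical(1))
  calls_non <- vapply(non, function(m)
    classify_refinement(m, thr$width_min, thr$location_min)$refined, logical(1))
  expect_true(all(calls_ref))
  expect_false(any(calls_non))
})
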