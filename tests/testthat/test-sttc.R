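test_that("tiled time fraction matches hand evaluation, with boundary clipping and tile merging", {
  expect_equal(tiled_time_fraction(spike_train(1.0, 60)), 0.1 / 60)
  # tile clipped at the recording start
  expect_equal(tiled_time_fraction(spike_train(0.02, 60)), 0.07 / 60)
  # overlapping tiles merge: spikes at 1.00 and 1.04 -> [0.95, 1.09]
  expect_equal(tiled_time_fraction(spike_train(c(1.0, 1.04), 60)), 0.14 / 60)
  expect_equal(tiled_time_fraction(spike_train(numeric(0), 60)), 0)
})

test_that("tiled spike proportion matches hand evaluation", {
  expect_equal(tiled_spike_proportion(spike_train(1.0, 60), spike_train(1.02, 60)), 1.0)
  expect_equal(tiled_spike_proportion(spike_train(1.0, 60), spike_train(10, 60)), 0.0)
  expect_equal(tiled_spike_proportion(spike_train(c(1.0, 5.0), 60), spike_train(1.02, 60)), 0.5)
  expect_warning(p <- tiled_spike_proportion(spike_train(numeric(0), 60), spike_train(1, 60)),
                 "empty")
  expect_true(is.na(p))
})

test_that("STTC reproduces hand-evaluated pair values and the +1 self-correlation maximum", {
  a <- spike_train(c(1.0, 2.5, 7.3), 60)
  expect_identical(sttc(a, a), 1)
  expect_equal(sttc(spike_train(1.0, 60), spike_train(10.0, 60)), -1 / 600)
  expect_equal(sttc(spike_train(1.0, 60), spike_train(1.02, 60)), 1.0)
  # undefined cases
  expect_true(is.na(sttc(spike_train(numeric(0), 60), a)))
  expect_error(sttc(a, spike_train(1, 30)), "duration")
})

test_that("STTC is symmetric, bounded, and shift-invariant", {
  set.seed(42)
  for (k in 1:300) {
    a <- lattice_train(sample(1:25, 1))
    b <- lattice_train(sample(1:25, 1))
    v <- sttc(a, b)
    expect_identical(v, sttc(b, a))
    expect_true(is.na(v) || (v >= -1 - 1e-12 && v <= 1 + 1e-12))
  }
  # common time shift away from the boundaries leaves STTC unchanged
  a <- spike_train(c(5.1, 8.2, 20.7), 60)
  b <- spike_train(c(5.13, 9.0, 33.3), 60)
  for (shift in c(-3, 2, 10)) {
    as <- spike_train(a$times_s + shift, 60)
    bs <- spike_train(b$times_s + shift, 60)
    expect_equal(sttc(as, bs), sttc(a, b), tolerance = 1e-12)
  }
})

test_that("STTC of independent Poisson pairs at unequal rates centres on zero", {
  # the design rationale for the measure: independence of firing rate
  set.seed(7)
  vals <- vapply(1:200, function(i) {
    a <- spike_train(runif(rpois(1, 0.1 * 60) + 1, 0, 60), 60)
    b <- spike_train(runif(rpois(1, 1.0 * 60) + 1, 0, 60), 60)
    sttc(a, b)
  }, numeric(1))
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.01)
})

test_that("tiling-based STTC agrees with the brute-force/fine-grid oracle", {
  set.seed(99)
  for (k in 1:100) {
    a <- lattice_train(sample(2:15, 1))
    b <- lattice_train(sample(2:15, 1))
    expect_equal(sttc(a, b), oracle_sttc(a, b), tolerance = 1e-6)
  }
})

test_that("adjacency matrix is symmetric, handles empty trains, and matches per-pair oracle", {
  tr <- replicate(3, spike_train(c(1, 5, 9), 60), simplify = FALSE)
  m <- adjacency_matrix(tr)
  expect_true(all(m[upper.tri(m)] == 1))
  expect_true(all(is.na(diag(m))))

  tr2 <- c(tr, list(spike_train(numeric(0), 60)))
  m2 <- adjacency_matrix(tr2)
  expect_true(all(is.na(m2[4, ])) && all(is.na(m2[, 4])))

  set.seed(5)
  tr3 <- replicate(20, lattice_train(sample(2:12, 1)), simplify = FALSE)
  m3 <- adjacency_matrix(tr3)
  for (i in 1:19) for (j in (i + 1):20) {
    expect_equal(m3[i, j], oracle_sttc(tr3[[i]], tr3[[j]]), tolerance = 1e-6)
  }
})

test_that("total flow sums CI through each node", {
  m <- matrix(NA_real_, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.5
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.1
  expect_equal(unname(total_flow(m)), c(0.7, 0.6, 0.3))
  expect_equal(sum(total_flow(m)), 2 * sum(m[upper.tri(m)]))
  expect_equal(unname(total_flow(matrix(0, 4, 4))), rep(0, 4))
  h <- attr(total_flow(m, breaks = seq(0, 1, 0.25)), "histogram")
  expect_equal(sum(h$counts), 3)
})

test_that("group-wise mean CI reproduces hand-computed toy values and the 10 pair sets", {
  labels <- data.frame(roi_id = 1:4, neun_pos = TRUE,
                       arc_pos = c(TRUE, TRUE, FALSE, FALSE),
                       cfos_pos = c(TRUE, FALSE, TRUE, FALSE),
                       group = c("Arc+cFos+", "Arc+cFos-", "Arc-cFos+", "Arc-cFos-"))
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.8; m[1, 3] <- 0.4; m[1, 4] <- 0.3
  m[2, 3] <- 0.2; m[2, 4] <- 0.1; m[3, 4] <- 0.6
  m <- m + t(m)
  g <- group_mean_ci(m, labels, "neun_arc")
  expect_equal(g$mean_ci[g$set == "Arc-Arc"], 0.8)
  expect_equal(g$mean_ci[g$set == "Arc-NeuN"], mean(c(0.4, 0.3, 0.2, 0.1)))
  expect_equal(g$mean_ci[g$set == "NeuN-NeuN"], 0.6)
  expect_equal(g$n_pairs, c(1L, 4L, 1L))

  # each cell is its own group, so the four intra-group sets warn as empty
  g2 <- suppressWarnings(group_mean_ci(m, labels, "arc_cfos"))
  expect_equal(nrow(g2), 10L)
  expect_equal(g2$mean_ci[g2$set == "Arc+cFos+|Arc-cFos-"], 0.3)

  # all cells in one group: only the intra-group set is non-missing
  lab1 <- labels; lab1$arc_pos <- TRUE
  w <- capture_warnings(g3 <- group_mean_ci(m, lab1, "neun_arc"))
  expect_length(w, 2L)   # Arc-NeuN and NeuN-NeuN are both empty
  expect_match(w, "no defined pairs", all = TRUE)
  expect_true(is.na(g3$mean_ci[g3$set == "NeuN-NeuN"]))
  expect_false(is.na(g3$mean_ci[g3$set == "Arc-Arc"]))
})

test_that("correlation-change classification applies the band rule", {
  mb <- matrix(0, 2, 2); ma <- mb
  cls <- function(before, after) {
    mb[1, 2] <- mb[2, 1] <- before
    ma[1, 2] <- ma[2, 1] <- after
    classify_correlation_changes(mb, ma)$change_class
  }
  expect_equal(cls(0.2, 0.7), "positive")
  expect_equal(cls(0.7, 0.2), "negative")
  expect_equal(cls(0.3, 0.4), "none")
  expect_equal(cls(0.5, 0.5), "none")   # closed on the [0.5, 1] side
  expect_equal(cls(0.49, 0.5), "positive")
})

test_that("Arc-pair fraction curve follows the final/initial CI axis convention", {
  rec <- data.frame(
    i = 1:4, j = 5:8,
    ci_before = c(0.1, 0.2, 0.8, 0.9),
    ci_after  = c(0.6, 0.9, 0.2, 0.1),
    change_class = c("positive", "positive", "negative", "negative"),
    arc_arc = c(TRUE, FALSE, TRUE, TRUE))
  cur <- arc_pair_fraction_vs_threshold(rec, thresholds = c(0.5, 0.7, 0.85))
  pos <- cur[cur$change_class == "positive", ]
  expect_equal(pos$frac_arc_arc, c(0.5, 0, 0))        # by final CI
  neg <- cur[cur$change_class == "negative", ]
  expect_equal(neg$frac_arc_arc, c(1, 1, 1))          # by initial CI
  expect_equal(neg$n_pairs, c(2L, 2L, 1L))

  rec$arc_arc <- FALSE
  cur0 <- arc_pair_fraction_vs_threshold(rec, thresholds = 0.5)
  expect_true(all(cur0$frac_arc_arc == 0))
})

test_that("pair distances use the 0.8 um pixel scale", {
  d <- pair_distances(rbind(c(0, 0), c(3, 4)))
  expect_equal(d[1, 2], 4.0)
  expect_equal(pair_distances(rbind(c(5, 5), c(5, 5)))[1, 2], 0)
  cent <- rbind(c(0, 0), c(1, 0), c(0, 2))
  d3 <- pair_distances(cent, pixel_size_um = 1)
  expect_equal(d3[1, 2], 1); expect_equal(d3[1, 3], 2)
  expect_equal(d3[2, 3], sqrt(5))

  m <- matrix(c(NA, 0.6, 0.1, 0.6, NA, 0.8, 0.1, 0.8, NA), 3, 3)
  cur <- mean_distance_above_threshold(m, d3, thresholds = c(0, 0.5, 0.9))
  expect_equal(cur$mean_distance_um, c(mean(c(1, 2, sqrt(5))),
                                       mean(c(1, sqrt(5))), NA))
})

test_that("nonkernel density estimate integrates to one and handles constants", {
  d <- density_distribution(rep(3.3, 50))
  expect_equal(sum(d$density * d$width), 1)
  expect_equal(nrow(d[d$count > 0, ]), 1L)

  set.seed(3)
  u <- runif(5000)
  d2 <- density_distribution(u, breaks = seq(0, 1, 0.1))
  expect_equal(sum(d2$density * d2$width), 1)
  # approximately flat: chi-squared goodness of fit at alpha = 0.01
  expect_gt(chisq.test(d2$count)$p.value, 0.01)
  set.seed(4)
  d3 <- density_distribution(rnorm(200), breaks = 12)
  expect_equal(sum(d3$density * d3$width), 1, tolerance = 1e-12)
})
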