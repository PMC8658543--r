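test_that("burst generator honours its contract and degenerate limits", {
  tr <- generate_burst_spike_trains(50, 60, seed = 5)
  expect_length(tr, 50L)
  for (st in tr) {
    expect_true(all(st$times_s >= 0 & st$times_s <= 60))
    expect_true(!is.unsorted(st$times_s))
  }
  expect_error(generate_burst_spike_trains(0, 60), "invalid")
  expect_error(generate_burst_spike_trains(10, -1), "invalid")
  expect_error(generate_burst_spike_trains(10, 60, participation = 1.5), "participation")

  # full participation, no jitter, no background: identical trains, STTC 1
  tr1 <- generate_burst_spike_trains(5, 60, participation = 1, jitter_sd_s = 0,
                                     background_rate_hz = 0, seed = 9)
  expect_true(all(vapply(tr1, function(s)
    identical(s$times_s, tr1[[1]]$times_s), logical(1))))
  expect_identical(sttc(tr1[[1]], tr1[[2]]), 1)
})

test_that("zero participation gives independent trains with near-zero mean STTC", {
  vals <- unlist(lapply(1:100, function(seed) {
    tr <- generate_burst_spike_trains(4, 60, participation = 0,
                                      background_rate_hz = 0.5, seed = seed)
    m <- adjacency_matrix(tr)
    m[upper.tri(m)]
  }))
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.01)
})

test_that("generation is bit-reproducible from the master seed", {
  a <- generate_three_epoch_dataset(seed = 77, n_neurons = 30)
  b <- generate_three_epoch_dataset(seed = 77, n_neurons = 30)
  expect_identical(a, b)
  c <- generate_three_epoch_dataset(seed = 78, n_neurons = 30)
  expect_false(identical(a$spike_trains, c$spike_trains))
})

test_that("expected pairwise STTC is nondecreasing in participation", {
  mean_sttc <- function(p) {
    mean(unlist(lapply(1:50, function(seed) {
      tr <- generate_burst_spike_trains(4, 60, participation = p, seed = seed)
      m <- adjacency_matrix(tr)
      m[upper.tri(m)]
    })), na.rm = TRUE)
  }
  v <- vapply(c(0.2, 0.5, 0.8), mean_sttc, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("three-epoch dataset encodes refinement in the correlation structure", {
  cu <- generate_three_epoch_dataset(refinement = TRUE, seed = 13, n_neurons = 60)
  expect_length(cu$spike_trains, 3L)
  expect_true(all(vapply(cu$spike_trains, length, integer(1)) == 60))
  mb <- adjacency_matrix(cu$spike_trains$baseline)
  ma <- adjacency_matrix(cu$spike_trains$after)
  ref <- cu$true_labels$refined
  sub <- function(m, sel) { s <- m[sel, sel]; mean(s[upper.tri(s)], na.rm = TRUE) }
  expect_gt(sub(ma, ref), sub(mb, ref))                    # refined pairs rise
  expect_lt(mean(ma[upper.tri(ma)], na.rm = TRUE),
            mean(mb[upper.tri(mb)], na.rm = TRUE))         # network mean falls
  # refinement truth: Arc-positive set is exactly the refined set
  expect_identical(cu$true_labels$arc, cu$true_labels$refined)

  cu0 <- generate_three_epoch_dataset(refinement = FALSE, seed = 14, n_neurons = 60)
  mb0 <- adjacency_matrix(cu0$spike_trains$baseline)
  ma0 <- adjacency_matrix(cu0$spike_trains$after)
  arc0 <- cu0$true_labels$arc
  for (sel in list(arc0, !arc0, rep(TRUE, 60)))
    expect_lt(sub(ma0, sel), sub(mb0, sel))                # every group falls
})

test_that("Arc-positive cells cluster spatially and groups sum to the culture", {
  cu <- generate_three_epoch_dataset(seed = 19, n_neurons = 150)
  cent <- cu$roi_centroids
  arc <- cu$true_labels$arc
  darc <- as.matrix(dist(cent[arc, ]))
  expect_lte(max(darc), 2 * cu$params$cluster_radius_px)
  expect_true(all(cent >= 0 & cent <= cu$params$frame_px - 1))

  lab <- assign_labels(cu$marker_intensities,
                       list(neun = 130, arc = 130, cfos = 130))
  counts <- table(factor(lab$group, levels = c("Arc+cFos+", "Arc+cFos-",
                                               "Arc-cFos+", "Arc-cFos-")),
                  useNA = "always")
  expect_equal(sum(counts), 150L)
})

test_that("Arc within c-Fos overlap matches the 82.7% default", {
  fracs <- vapply(1:200, function(seed) {
    lab <- generate_three_epoch_dataset(seed = seed, n_neurons = 120)$true_labels
    mean(lab$cfos[lab$arc])
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.827), 0.02)
})

test_that("fluorescence synthesis follows the AR(1)-with-bleach forward model", {
  silent <- list(spike_train(numeric(0), 20))
  f0 <- spikes_to_fluorescence(silent, noise_sd = 0, baseline = 2)
  expect_true(all(f0 == 2))

  # single spike impulse response: amplitude * gamma^(t - k)
  st <- list(spike_train(2.05, 20))    # lands in frame 11 at 5 Hz
  f1 <- spikes_to_fluorescence(st, gamma = 0.9, amplitude = 1.5,
                               baseline = 0.5, noise_sd = 0)
  expect_true(all(f1[1, 1:10] == 0.5))
  expect_equal(f1[1, 11:100] - 0.5, 1.5 * 0.9^(0:89), tolerance = 1e-12)

  # bleach decays a silent cell's trace toward the baseline offset
  fb <- spikes_to_fluorescence(list(spike_train(0.05, 20)), noise_sd = 0,
                               baseline = 1, bleach_rate = 0.01)
  expect_true(all(diff(fb[1, ]) < 0))
  expect_identical(
    spikes_to_fluorescence(silent, seed = 4)[1, ],
    spikes_to_fluorescence(silent, seed = 4)[1, ])
})

test_that("rendered frames carry the ROI geometry and fluorescence values", {
  cu <- list(roi_centroids = data.frame(x = c(30, 90), y = c(40, 100)),
             marker_intensities = data.frame(roi_id = 1:2, neun = c(5, 9)))
  fl <- fluorescence_matrix(matrix(c(1, 2, 3, 4), 2, 2), 5)
  r <- render_synthetic_frames(cu, fl, frame_px = 128L, radius_px = 6)
  comp <- EBImage::bwlabel(EBImage::Image(r$nuclear > 0.5))
  expect_equal(max(comp), 2)
  rois <- roi_set(r$label_image)
  expect_equal(quantify_roi_intensity(r$movie[, , 1], rois), c(1, 2))
  expect_equal(quantify_roi_intensity(r$movie[, , 2], rois), c(3, 4))
  expect_equal(quantify_roi_intensity(r$markers$neun, rois), c(5, 9))

  # default geometry is the 1007 x 1007 px imaging field
  r2 <- render_synthetic_frames(cu)
  expect_equal(dim(r2$nuclear), c(1007, 1007))

  ov <- list(roi_centroids = data.frame(x = c(50, 54), y = c(50, 50)),
             marker_intensities = NULL)
  expect_warning(render_synthetic_frames(ov, frame_px = 128L), "overlapping")
})
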