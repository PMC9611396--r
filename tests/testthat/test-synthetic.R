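test_that("populations are deterministic, distinct and anti-phase constrained", {
  p1 <- sample_population(100, seed = 21)
  p2 <- sample_population(100, seed = 21)
  expect_length(p1, 100L)
  expect_identical(p1, p2)
  sids <- vapply(p1, function(s) s$sid, "")
  expect_equal(anyDuplicated(sids), 0L)
  # signatures are pairwise distinct in their parameters
  amps <- vapply(p1, function(s) s$joint_params$Knee$amplitude, 0)
  expect_equal(anyDuplicated(amps), 0L)
  # single subject: left and right hip phases differ by pi
  solo <- sample_population(1, seed = 4)[[1]]
  hl <- signature_joint_params(solo, "HipLeft")
  hr <- signature_joint_params(solo, "HipRight")
  expect_equal(hr$phase - hl$phase, pi)
  expect_equal(hl$amplitude, hr$amplitude)
  # cadence range
  cad <- vapply(p1, function(s) s$cadence, 0)
  expect_true(all(cad >= 0.6 & cad <= 1.4))
  amp_all <- unlist(lapply(p1, function(s) {
    vapply(s$joint_params, function(p) p$amplitude, 0)
  }))
  expect_true(all(amp_all >= 0 & amp_all <= pi / 2))
})

# recover the signed joint angle from a recording's quaternion stream
joint_angle_track <- function(rec, joint, axis) {
  qn <- normalize_quaternion(rec$quaternions[, joint, ])
  aa <- quaternion_to_axis_angle(qn)
  aa$theta * sign(aa$axis %*% axis)
}

test_that("zero-jitter recordings are deterministic, sinusoidal at the cadence, and anti-phase", {
  sig <- sample_population(1, seed = 11)[[1]]
  sig$cadence <- 1.0
  sig$amplitude_jitter <- 0
  nm <- noise_model(jitter_sd = 0, tempo_range = c(1, 1),
                    t_range = c(90L, 90L))
  r1 <- simulate_recording(sig, nm, T = 90, seed = 5)
  r2 <- simulate_recording(sig, nm, T = 90, seed = 5)
  expect_identical(r1$quaternions, r2$quaternions)

  # spectral peak at the cadence within one DFT bin (alpha = 1 gives the
  # lagged raw stream, still a pure sinusoid)
  b <- sequence_to_node_inputs(r1, cfg = smoothing_config(1))
  ch <- b$leg_left[-1, 1, ] # drop the lag frame
  for (k in 1:3) {
    x <- ch[, k] - mean(ch[, k])
    if (max(abs(x)) < 1e-8) next
    spec <- Mod(fft(x))[2:(length(x) %/% 2)]
    peak_hz <- which.max(spec) * 30 / length(x)
    expect_lt(abs(peak_hz - 1.0), 30 / length(x) + 1e-9)
  }

  # left knee equals right knee shifted by half a cycle (15 frames at 1 Hz)
  ax <- signature_joint_params(sig, "KneeLeft")$axis
  left <- joint_angle_track(r1, "KneeLeft", ax)
  right <- joint_angle_track(r1, "KneeRight", ax)
  expect_equal(left[16:90], right[1:75], tolerance = 1e-8)
})

test_that("simulated datasets have the advertised size, frame range and round-trip", {
  dir <- file.path(tempdir(), "sim_count")
  man <- simulate_dataset(8, 30, noise_model(), seed = 2, dir = dir)
  expect_equal(nrow(man), 240L)
  expect_length(unique(man$sid), 8L)
  expect_true(all(man$T >= 20 & man$T <= 185))
  rec <- read_recording(file.path(dir, man$path[1]))
  expect_equal(rec$T, man$T[1])
  expect_equal(rec$sid, man$sid[1])
  # regenerating under the same seed reproduces identical values
  dir2 <- file.path(tempdir(), "sim_count2")
  man2 <- simulate_dataset(8, 30, noise_model(), seed = 2, dir = dir2)
  rec2 <- read_recording(file.path(dir2, man2$path[1]))
  expect_equal(rec$quaternions, rec2$quaternions)
})

test_that("zero-jitter signatures are separable by nearest neighbor on amplitude estimates", {
  pop <- sample_population(4, seed = 31)
  nm <- noise_model(jitter_sd = 0, t_range = c(80L, 80L))
  feats <- list(); labs <- character(0)
  for (s in seq_along(pop)) {
    for (r in 1:4) {
      rec <- simulate_recording(pop[[s]], nm, T = 80,
                                seed = 100 * s + r)
      b <- sequence_to_node_inputs(rec, cfg = smoothing_config(1))
      # amplitude estimate per channel: half the range
      f <- unlist(lapply(gait_vertices(), function(v) {
        apply(b[[v]], c(2, 3), function(x) (max(x) - min(x)) / 2)
      }))
      feats[[length(feats) + 1L]] <- f
      labs <- c(labs, pop[[s]]$sid)
    }
  }
  X <- do.call(rbind, feats)
  # leave-one-out 1-NN is perfect
  d <- as.matrix(dist(X))
  diag(d) <- Inf
  pred <- labs[apply(d, 1, which.min)]
  expect_equal(pred, labs)
})

test_that("heavier sensor jitter degrades trained-model kNN accuracy in expectation", {
  acc_at <- function(jitter, seed) {
    dir <- file.path(tempdir(), sprintf("jit_%s_%d", jitter, seed))
    man <- simulate_dataset(6, 8,
                            noise_model(jitter_sd = jitter,
                                        t_range = c(25L, 35L)),
                            seed = seed, dir = dir)
    bundles <- prepare_bundles(man, man$sample_id)
    sids <- attr(bundles, "sids")
    sp <- stratified_split(man, 0.25, seed = seed)
    labels <- sort(unique(sids))
    m <- build_model(build_gait_st_graph(),
                     model_config(n_classes = 6,
                                  width_multiplier = 0.125),
                     seed = seed, labels = labels)
    fit <- train_model(m, bundles[sp$train], sids[sp$train],
                       train_config(epochs = 8L, seed = seed))
    gal <- embed_dataset(fit$model, bundles[sp$train], sids[sp$train])
    prb <- embed_dataset(fit$model, bundles[sp$test], sids[sp$test])
    mean(knn_classify(gal, prb, k = 3) == sids[sp$test])
  }
  lvls <- c(0.05, 1.0, 3.0)
  acc <- sapply(lvls, function(j) mean(sapply(1:3, function(s) {
    acc_at(j, s)
  })))
  # monotone trend in expectation over seeds, not strictly per seed
  expect_gte(acc[1], acc[2] - 0.05)
  expect_gte(acc[2], acc[3] - 0.05)
  expect_gt(acc[1], acc[3])
})
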