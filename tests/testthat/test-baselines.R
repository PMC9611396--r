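# Small shared dataset for baseline comparisons: low jitter so every
# method has a fair shot, distinct limb lengths so the handcrafted
# features separate subjects too.
baseline_ds <- function(seed) {
  cached(paste0("baseline_ds_", seed), {
    dir <- file.path(tempdir(), paste0("baseline_ds_", seed))
    man <- simulate_dataset(5, 10,
                            noise_model(jitter_sd = 0.01,
                                        t_range = c(40L, 60L)),
                            seed = seed + 40L, dir = dir)
    bundles <- prepare_bundles(man, man$sample_id)
    split <- stratified_split(man, 0.2, seed = seed)
    list(man = man, bundles = bundles, sids = attr(bundles, "sids"),
         split = split)
  })
}

test_that("time interpolation is the identity at length 100 and exact on ramps and sinusoids", {
  x100 <- matrix(rnorm(300), 100, 3)
  expect_identical(interpolate_time(x100), x100)
  # a linear ramp stays a linear ramp with preserved endpoints
  ramp <- matrix(seq(2, 7, length.out = 57), ncol = 1)
  out <- interpolate_time(ramp)
  expect_equal(out[1, 1], 2)
  expect_equal(out[100, 1], 7)
  expect_equal(out[, 1], seq(2, 7, length.out = 100), tolerance = 1e-9)
  # closed-form linear interpolation oracle on a sinusoid
  tt <- 50L
  y <- sin(2 * pi * (1:tt) / 17)
  out2 <- interpolate_time(matrix(y, ncol = 1))
  grid <- seq(1, tt, length.out = 100)
  lo <- pmin(floor(grid), tt - 1); w <- grid - lo
  oracle <- (1 - w) * y[lo] + w * y[lo + 1]
  expect_equal(out2[, 1], oracle, tolerance = 1e-9)
  expect_error(interpolate_time(matrix(1, 1, 3)), "T >= 2")
})

test_that("the LSTM baseline consumes 15 features, normalizes its softmax and counts parameters in closed form", {
  ds <- baseline_ds(1)
  expect_equal(ncol(baseline_frame_features(ds$bundles[[1]])), 15L)
  clf <- cached("lstm_base_tiny", {
    train_lstm_baseline(ds$bundles[ds$split$train][1:10],
                        ds$sids[ds$split$train][1:10],
                        labels = sort(unique(ds$sids)),
                        epochs = 1L, seed = 1)
  })
  pred <- baseline_predict(clf, ds$bundles[ds$split$test][1:5])
  expect_equal(unname(rowSums(pred$probs)), rep(1, 5), tolerance = 1e-9)
  # 4 * ((15 + 128) * 128 + 128) for the fused-gate cell
  expect_equal(lstm_cell_n_params(clf), 4L * ((15L + 128L) * 128L + 128L))
})

test_that("the LSTM baseline reaches 0.95 training accuracy on separable low-noise data", {
  ds <- baseline_ds(1)
  clf <- cached("lstm_base_trained_1", {
    train_lstm_baseline(ds$bundles[ds$split$train],
                        ds$sids[ds$split$train],
                        labels = sort(unique(ds$sids)),
                        epochs = 30L, seed = 1)
  })
  pred <- baseline_predict(clf, ds$bundles[ds$split$train])
  expect_gte(mean(pred$labels == ds$sids[ds$split$train]), 0.95)
})

test_that("convolutional layer shapes follow the kernel arithmetic", {
  plan <- cnn_plan(5)
  expect_equal(plan$p1$oh, 100L - 30L + 1L) # 71
  expect_equal(plan$p1$ow, 7L)
  expect_equal(plan$nh1, 35L)
  expect_equal(plan$p2$oh, 35L - 15L + 1L) # 21
  expect_equal(plan$p2$ow, 7L * 25L - 17L + 1L) # 159
  expect_equal(plan$nh2, 10L)
  expect_equal(plan$flat, 10L * 159L * 20L)
  # forward map of one sample matches the plan
  ds <- baseline_ds(1)
  clf <- cached("cnn_base_tiny", {
    train_cnn_baseline(ds$bundles[ds$split$train][1:10],
                       ds$sids[ds$split$train][1:10],
                       labels = sort(unique(ds$sids)),
                       epochs = 1L, seed = 2)
  })
  pred <- baseline_predict(clf, ds$bundles[ds$split$test][1:4])
  expect_equal(dim(pred$probs), c(4L, 5L))
  expect_equal(unname(rowSums(pred$probs)), rep(1, 4), tolerance = 1e-9)
})

test_that("the convolutional autoencoder exposes a 128-d latent code", {
  ds <- baseline_ds(1)
  cae <- cached("cae_tiny", {
    train_cae(ds$bundles[ds$split$train][1:8],
              ds$sids[ds$split$train][1:8], epochs = 20L, seed = 3)
  })
  emb <- cae_embed(cae, ds$bundles[ds$split$test][1:3])
  expect_equal(dim(emb), c(3L, 128L))
  expect_true(all(is.finite(emb)))
  # reconstruction loss decreases over the training run
  expect_lt(tail(cae$history, 1), cae$history[1])
})

test_that("handcrafted features are zero-motion-consistent and hand-countable", {
  # motionless skeleton with both ankles at the same point
  pos <- array(0, c(5, 20, 3))
  joints <- kinect_joints$joint
  pos[, match("Head", joints), 2] <- 1.7
  pos[, match("KneeLeft", joints), 2] <- 0.45
  pos[, match("KneeRight", joints), 2] <- 0.45
  qt <- array(0, c(5, 20, 4)); qt[, , 4] <- 1
  rec <- gait_sequence("still", "S1", pos, qt)
  f <- handcrafted_features(rec)
  expect_equal(unname(f["step_mean"]), 0)
  expect_equal(unname(f["step_sd"]), 0)
  expect_equal(unname(f["height_sd"]), 0)
  expect_equal(unname(f["KneeLeft_mean"]), 0.45)
  expect_equal(unname(f["KneeLeft_sd"]), 0)

  # outlier filter drops exactly the rows beyond 2 SD
  X <- cbind(c(rep(0, 9), 100), rep(1, 10))
  keep <- feature_outlier_filter(X)
  expect_equal(which(!keep), 10L)
  expect_equal(sum(keep), 9L)
})

test_that("random-subspace kNN on handcrafted features separates subjects with distinct skeletons", {
  ds <- baseline_ds(1)
  seqs <- load_recordings(ds$man, ds$man$sample_id)
  res <- handcrafted_pipeline(seqs[ds$split$train], seqs[ds$split$test],
                              draws = 20L, k = 3L, seed = 4)
  expect_equal(nrow(res), 20L)
  expect_gte(stats::median(res$accuracy), 0.9)
})

test_that("the structured model is at least as accurate as every baseline on shared splits", {
  accs <- lapply(1:3, function(seed) {
    ds <- baseline_ds(seed)
    labels <- sort(unique(ds$sids))
    tr <- ds$split$train; te <- ds$split$test
    st <- cached(paste0("trend_st_", seed), {
      m <- build_model(build_gait_st_graph(),
                       model_config(length(labels),
                                    width_multiplier = 0.125),
                       seed = seed, labels = labels)
      train_model(m, ds$bundles[tr], ds$sids[tr],
                  train_config(epochs = 15L, seed = seed))$model
    })
    st_acc <- mean(vapply(ds$bundles[te], function(b) {
      predict(st, b)$label
    }, "") == ds$sids[te])
    lstm <- cached(paste0("trend_lstm_", seed), {
      train_lstm_baseline(ds$bundles[tr], ds$sids[tr], labels = labels,
                          epochs = 30L, seed = seed)
    })
    lstm_acc <- mean(baseline_predict(lstm, ds$bundles[te])$labels ==
                       ds$sids[te])
    cnn <- cached(paste0("trend_cnn_", seed), {
      train_cnn_baseline(ds$bundles[tr], ds$sids[tr], labels = labels,
                         epochs = 8L, seed = seed)
    })
    cnn_acc <- mean(baseline_predict(cnn, ds$bundles[te])$labels ==
                      ds$sids[te])
    seqs <- load_recordings(ds$man, ds$man$sample_id)
    hand <- handcrafted_pipeline(seqs[tr], seqs[te], draws = 10L,
                                 k = 3L, seed = seed)
    c(st = st_acc, lstm = lstm_acc, cnn = cnn_acc,
      hand = stats::median(hand$accuracy))
  })
  m <- colMeans(do.call(rbind, accs))
  expect_gte(m[["st"]], m[["lstm"]] - 0.05)
  expect_gte(m[["st"]], m[["cnn"]] - 0.05)
  expect_gte(m[["st"]], m[["hand"]] - 0.05)
})
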