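small_cfg <- function(C = 3) {
  model_config(n_classes = C, width_multiplier = 0.125,
               embedding_dim = 16L)
}

test_that("the factor inventory matches the graph: 7 shared recurrent edge factors", {
  m <- build_model(build_gait_st_graph(), small_cfg(), seed = 1)
  edge_rnn <- grep("^(temporal|adjacency|symmetry)_", names(m$factors),
                   value = TRUE)
  expect_length(edge_rnn, 7L) # 3 temporal + 2 adjacency + 2 symmetry
  expect_length(grep("^node_lstm_", names(m$factors)), 3L)
  expect_length(grep("^mlp_", names(m$factors)), 3L)
})

test_that("model builds are deterministic under seed", {
  m1 <- build_model(build_gait_st_graph(), small_cfg(), seed = 7)
  m2 <- build_model(build_gait_st_graph(), small_cfg(), seed = 7)
  m3 <- build_model(build_gait_st_graph(), small_cfg(), seed = 8)
  for (nm in names(m1$factors)) {
    expect_identical(m1$factors[[nm]]$params, m2$factors[[nm]]$params)
  }
  expect_false(identical(m1$factors$final_lstm$params,
                         m3$factors$final_lstm$params))
})

test_that("mutating a shared limb factor through one side is visible through the other", {
  m <- build_model(build_gait_st_graph(), small_cfg(), seed = 2)
  fl <- vertex_factors(m, "arm_left")$mlp
  fr <- vertex_factors(m, "arm_right")$mlp
  fl$params$W[1, 1] <- 123.5
  expect_equal(fr$params$W[1, 1], 123.5)
})

test_that("the shortest admissible sequence (T = 2) produces finite logits", {
  b <- tiny_bundle(T = 2L)
  m <- build_model(build_gait_st_graph(), small_cfg(4), seed = 3)
  fw <- forward(m, b)
  expect_length(fw$logits, 4L)
  expect_true(all(is.finite(fw$logits)))
  expect_error(forward(m, structure(list(), T = 1,
                                    class = "node_input_bundle")),
               "T >= 2")
})

test_that("swapping left and right inputs leaves side-summed layer-1 features unchanged", {
  m <- build_model(build_gait_st_graph(), small_cfg(), seed = 4)
  b <- tiny_bundle(T = 9L)
  swapped <- b
  swapped$leg_left <- b$leg_right; swapped$leg_right <- b$leg_left
  swapped$arm_left <- b$arm_right; swapped$arm_right <- b$arm_left
  attr(swapped, "static") <- NULL
  f0 <- forward(m, b, keep_cache = TRUE)
  f1 <- forward(m, swapped, keep_cache = TRUE)
  expect_equal(f0$cache$mlp_ll$Y + f0$cache$mlp_lr$Y,
               f1$cache$mlp_ll$Y + f1$cache$mlp_lr$Y)
  expect_equal(f0$cache$tmp_al$Z + f0$cache$tmp_ar$Z,
               f1$cache$tmp_al$Z + f1$cache$tmp_ar$Z)
  expect_equal(f0$cache$adj_ll$Z + f0$cache$adj_lr$Z,
               f1$cache$adj_ll$Z + f1$cache$adj_lr$Z)
  # the symmetry factor sees its input halves swapped
  n_leg <- ncol(f0$cache$sym_leg$X) / 2
  expect_equal(f0$cache$sym_leg$X[, 1:n_leg],
               f1$cache$sym_leg$X[, n_leg + 1:n_leg])
})

test_that("padded-then-masked sequences give identical logits to the unpadded ones", {
  m <- build_model(build_gait_st_graph(), small_cfg(), seed = 5)
  b <- tiny_bundle(T = 10L)
  padded <- b
  for (v in gait_vertices()) {
    pad <- array(rnorm(4 * dim(b[[v]])[2] * 3), c(4, dim(b[[v]])[2], 3))
    padded[[v]] <- abind_rows(b[[v]], pad)
  }
  attr(padded, "T") <- 14L
  attr(padded, "static") <- NULL
  f0 <- forward(m, b)
  f1 <- forward(m, padded, t_last = 10L)
  expect_equal(f0$logits, f1$logits, tolerance = 1e-12)
  expect_equal(f0$embedding, f1$embedding, tolerance = 1e-12)
})

test_that("shuffling the frames of a periodic input changes the logits", {
  m <- build_model(build_gait_st_graph(), small_cfg(), seed = 6)
  b <- tiny_bundle(T = 40L)
  shuffled <- b
  set.seed(1)
  perm <- sample(40)
  for (v in gait_vertices()) shuffled[[v]] <- b[[v]][perm, , ]
  attr(shuffled, "static") <- NULL
  f0 <- forward(m, b)
  f1 <- forward(m, shuffled)
  expect_gt(max(abs(f0$logits - f1$logits)), 1e-8)
})

test_that("analytic gradients match central finite differences on random parameters", {
  b <- tiny_bundle(T = 12L)
  m <- build_model(build_gait_st_graph(), small_cfg(), seed = 2)
  loss_fn <- function() cross_entropy(2, forward(m, b)$probs,
                                      is_index = TRUE)
  stgait:::zero_grads(m$factors)
  fw <- forward(m, b, keep_cache = TRUE)
  dl <- fw$probs; dl[2] <- dl[2] - 1
  stgait:::backward(m, fw, dl)
  set.seed(99)
  eps <- 1e-5
  for (trial in 1:20) {
    fn <- sample(names(m$factors), 1)
    f <- m$factors[[fn]]
    pn <- sample(names(f$params), 1)
    ix <- sample(length(f$params[[pn]]), 1)
    orig <- f$params[[pn]][ix]
    f$params[[pn]][ix] <- orig + eps; lp <- loss_fn()
    f$params[[pn]][ix] <- orig - eps; lm <- loss_fn()
    f$params[[pn]][ix] <- orig
    num <- (lp - lm) / (2 * eps)
    ana <- f$grads[[pn]][ix]
    if (abs(num) + abs(ana) > 1e-8) {
      expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("class posteriors are normalized and argmax-consistent; zeroed head gives uniform", {
  m <- build_model(build_gait_st_graph(), small_cfg(4), seed = 8)
  for (i in 1:10) {
    b <- tiny_bundle(T = 8L, seed = i, n_subject_seed = i)
    p <- predict(m, b)
    expect_equal(sum(p$probs), 1, tolerance = 1e-6)
    expect_true(all(p$probs >= 0))
    expect_equal(p$label, names(p$probs)[which.max(p$probs)])
  }
  m$factors$logit_head$params$W[] <- 0
  m$factors$logit_head$params$b[] <- 0
  p <- predict(m, tiny_bundle(T = 8L))
  expect_equal(unname(p$probs), rep(0.25, 4))
  # argmax ties break to the lowest class index
  expect_equal(p$label, m$labels[1])
})

test_that("the embedding is the pre-tanh code feeding the logits head", {
  m <- build_model(build_gait_st_graph(),
                   model_config(n_classes = 5, width_multiplier = 0.25),
                   seed = 9)
  b <- tiny_bundle(T = 8L)
  e <- embed(m, b)
  expect_length(e, 128L)
  expect_identical(e, embed(m, b))
  fw <- forward(m, b)
  relogits <- drop(tanh(e) %*% m$factors$logit_head$params$W +
                     m$factors$logit_head$params$b)
  expect_equal(relogits, fw$logits, tolerance = 1e-6)
})

test_that("feature maps export one CSV per layer map with T rows", {
  m <- build_model(build_gait_st_graph(), small_cfg(), seed = 11)
  b <- tiny_bundle(T = 7L)
  dir <- file.path(tempdir(), "fmaps")
  paths <- write_feature_maps(m, b, dir)
  expect_length(paths, 11L + 3L + 1L)
  one <- read.csv(file.path(dir, "layer3_fusion.csv"))
  expect_equal(dim(one), c(7L, m$config$fusion_width))
})

test_that("checkpoints restore to bit-identical parameters and logits", {
  m <- build_model(build_gait_st_graph(), small_cfg(), seed = 10)
  b <- tiny_bundle(T = 8L)
  fit <- train_model(m, list(a = b, b2 = tiny_bundle(T = 8L, seed = 2)),
                     c("C001", "C002"),
                     train_config(epochs = 2L, seed = 1))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  back <- load_checkpoint(path)
  for (nm in names(fit$model$factors)) {
    expect_identical(back$factors[[nm]]$params,
                     fit$model$factors[[nm]]$params)
  }
  expect_identical(forward(back, b)$logits,
                   forward(fit$model, b)$logits)
})
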