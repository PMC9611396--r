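# Comparison baselines: a single-layer LSTM over per-part mean rotations, a
# 3-channel time-convolutional classifier (with an autoencoder variant
# exposing a 128-d latent code), and handcrafted anthropometric/dynamic
# features with random-subspace kNN.

#' Per-frame 15-dimensional feature vector for the LSTM baseline
#'
#' Mean exponential-map vector over the joints of each of the five body
#' parts, concatenated in the fixed vertex order (5 parts x 3 channels).
#'
#' @param bundle A [sequence_to_node_inputs()] bundle.
#' @return Matrix `T x 15`.
#' @export
baseline_frame_features <- function(bundle) {
  do.call(cbind, lapply(gait_vertices(), function(v) {
    arr <- bundle[[v]]
    t(apply(arr, 1, function(m) colMeans(matrix(m, ncol = 3))))
  }))
}

#' Linear time interpolation to a fixed length of 100 frames
#'
#' Channelwise linear interpolation on a uniform grid of 100 points
#' spanning the original frame range; first and last frames are preserved.
#'
#' @param x Matrix `T x p` (or 3-d array `T x J x 3`), `T >= 2`.
#' @param length_out Target length (default 100).
#' @return Same structure with first dimension `length_out`.
#' @export
interpolate_time <- function(x, length_out = 100L) {
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    out <- array(0, c(length_out, d[2], d[3]))
    for (j in seq_len(d[2])) {
      out[, j, ] <- interpolate_time(x[, j, , drop = TRUE], length_out)
    }
    return(out)
  }
  x <- as.matrix(x)
  tt <- nrow(x)
  if (tt < 2) stop("interpolation needs T >= 2, got ", tt)
  if (tt == length_out) return(x)
  grid <- seq(1, tt, length.out = length_out)
  apply(x, 2, function(col) stats::approx(seq_len(tt), col, xout = grid)$y)
}

# 7-joint lower-limb channel selection for the convolutional baselines:
# hip center plus both hips, knees and ankles
.cnn_joint_tensor <- function(bundle) {
  arr <- array(0, c(attr(bundle, "T"), 7, 3))
  arr[, 1, ] <- bundle$spine[, "HipCenter", ]
  arr[, 2, ] <- bundle$leg_left[, "HipLeft", ]
  arr[, 3, ] <- bundle$leg_right[, "HipRight", ]
  arr[, 4, ] <- bundle$leg_left[, "KneeLeft", ]
  arr[, 5, ] <- bundle$leg_right[, "KneeRight", ]
  arr[, 6, ] <- bundle$leg_left[, "AnkleLeft", ]
  arr[, 7, ] <- bundle$leg_right[, "AnkleRight", ]
  arr
}

# ---- single-layer LSTM baseline ------------------------------------------

#' Build and train the single-layer LSTM baseline
#'
#' Architecture: Input(T x 15) - LSTM(128) - tanh - Dense(C) - tanh -
#' Softmax, reading the last hidden state. Trained with per-sequence Adam
#' updates and cross-entropy, shuffled every epoch. The default learning
#' rate is conservative (3e-4): the tanh squashing both sides of the dense
#' head saturates and stalls at aggressive rates.
#'
#' @param bundles Named list of bundles.
#' @param sids Labels parallel to `bundles`.
#' @param labels Class label universe.
#' @param hidden LSTM width (reference 128).
#' @param epochs,learning_rate,seed Training settings.
#' @return Object of class `lstm_baseline` with `predict_label()` support
#'   via [baseline_predict()].
#' @export
train_lstm_baseline <- function(bundles, sids, labels = sort(unique(sids)),
                                hidden = 128L, epochs = 30L,
                                learning_rate = 3e-4, seed = 1L) {
  sids <- as.character(sids)
  rng <- .local_rng(seed)
  feats <- lapply(bundles, baseline_frame_features)
  n_in <- ncol(feats[[1]])
  if (n_in != 15L) stop("per-frame feature length must be 15, got ", n_in)
  C <- length(labels)
  lstm <- new_lstm_factor(n_in, hidden, NULL, rng)
  head <- new_dense_factor(hidden, C, rng, "none")
  class_ix <- match(sids, labels)
  factors <- list(lstm, head)
  t_adam <- 0L
  n <- length(feats)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- rng$sample(seq_len(n))
    tot <- 0
    for (i in ord) {
      zero_grads(factors)
      fwd <- lstm_forward(lstm, feats[[i]])
      hT <- fwd$Z[nrow(fwd$Z), , drop = FALSE]
      th <- tanh(hT)
      dn <- dense_forward(head, th)
      logits <- tanh(drop(dn$Y))
      p <- .softmax(logits)
      loss <- cross_entropy(class_ix[i], p, is_index = TRUE)
      dlog <- p; dlog[class_ix[i]] <- dlog[class_ix[i]] - 1
      dpre <- dlog * (1 - logits^2)
      dth <- dense_backward(head, dn, matrix(dpre, 1))
      dhT <- dth * (1 - th^2)
      dZ <- matrix(0, nrow(fwd$Z), hidden)
      dZ[nrow(dZ), ] <- dhT
      lstm_backward(lstm, fwd, dZ)
      t_adam <- t_adam + 1L
      adam_step(factors, learning_rate, t_adam)
      tot <- tot + loss
    }
    history[ep] <- tot / n
  }
  structure(list(kind = "lstm", lstm = lstm, head = head, labels = labels,
                 hidden = hidden, history = history),
            class = "lstm_baseline")
}

#' Class probabilities and predicted labels from a trained baseline
#'
#' @param clf A trained baseline classifier.
#' @param bundles Bundle list to classify.
#' @return List with `labels` (predicted) and `probs` (matrix n x C).
#' @export
baseline_predict <- function(clf, bundles) {
  UseMethod("baseline_predict")
}

#' @export
baseline_predict.lstm_baseline <- function(clf, bundles) {
  probs <- t(vapply(bundles, function(b) {
    x <- baseline_frame_features(b)
    fwd <- lstm_forward(clf$lstm, x)
    th <- tanh(fwd$Z[nrow(fwd$Z), , drop = FALSE])
    logits <- tanh(drop(dense_forward(clf$head, th)$Y))
    .softmax(logits)
  }, numeric(length(clf$labels))))
  list(labels = clf$labels[max.col(probs, ties.method = "first")],
       probs = probs)
}

#' Closed-form LSTM parameter count
#'
#' `4 * ((n_in + hidden) * hidden + hidden)` for the fused gate weights and
#' biases, excluding any output projection.
#'
#' @param clf An `lstm_baseline` (or any LSTM factor).
#' @return Integer parameter count of the recurrent cell.
#' @export
lstm_cell_n_params <- function(clf) {
  f <- if (inherits(clf, "lstm_baseline")) clf$lstm else clf
  length(f$params$Wx) + length(f$params$Wh) + length(f$params$b)
}

# ---- convolutional baseline ----------------------------------------------

# valid 2-d convolution via precomputed im2col indices; input (h x w x cin)
# flattened column-major, kernel (kh x kw), cout filters
.conv_plan <- function(h, w, cin, kh, kw) {
  oh <- h - kh + 1L
  ow <- w - kw + 1L
  # rows: output positions (oh*ow), cols: kh*kw*cin receptive entries
  idx <- matrix(0L, oh * ow, kh * kw * cin)
  col <- 1L
  for (c in seq_len(cin)) {
    for (j in seq_len(kw)) {
      for (i in seq_len(kh)) {
        base <- (c - 1L) * h * w
        offs <- outer(seq_len(oh) + i - 2L,
                      (seq_len(ow) + j - 2L) * h, "+") + 1L
        idx[, col] <- base + as.integer(offs)
        col <- col + 1L
      }
    }
  }
  list(idx = idx, oh = oh, ow = ow, cin = cin, kh = kh, kw = kw,
       in_len = h * w * cin)
}

.conv_forward <- function(plan, xvec, W, b) {
  xcol <- matrix(xvec[plan$idx], nrow(plan$idx), ncol(plan$idx))
  Y <- sweep(xcol %*% W, 2, b, "+")
  list(Y = Y, xcol = xcol) # Y: (oh*ow) x filters
}

.conv_backward <- function(plan, cache, W, dY) {
  dW <- crossprod(cache$xcol, dY)
  db <- colSums(dY)
  dxcol <- dY %*% t(W)
  dx <- numeric(plan$in_len)
  acc <- rowsum(as.numeric(dxcol), group = as.integer(plan$idx))
  dx[as.integer(rownames(acc))] <- acc[, 1]
  list(dW = dW, db = db, dx = dx)
}

# 2x1 average pooling over the time axis of an (ot x ow x f) map held as an
# (ot*ow) x f matrix; truncates an odd trailing row
.pool_forward <- function(Y, oh, ow) {
  nh <- oh %/% 2L
  arr <- array(Y, c(oh, ow, ncol(Y)))
  pooled <- (arr[seq(1, 2 * nh, 2), , , drop = FALSE] +
               arr[seq(2, 2 * nh, 2), , , drop = FALSE]) / 2
  list(Y = matrix(pooled, nh * ow, ncol(Y)), nh = nh)
}

.pool_backward <- function(dP, oh, ow, nf) {
  nh <- nrow(dP) / ow
  darr <- array(0, c(oh, ow, nf))
  dp <- array(dP, c(nh, ow, nf))
  darr[seq(1, 2 * nh, 2), , ] <- dp / 2
  darr[seq(2, 2 * nh, 2), , ] <- dp / 2
  matrix(darr, oh * ow, nf)
}

# batch normalization per filter channel, computed over batch x positions
.bn_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- colMeans(X)
  v <- colMeans(sweep(X, 2, mu)^2)
  xhat <- sweep(sweep(X, 2, mu), 2, sqrt(v + eps), "/")
  list(Y = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"),
       xhat = xhat, var = v, eps = eps)
}

.bn_backward <- function(cache, gamma, dY) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  istd <- 1 / sqrt(cache$var + cache$eps)
  dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dY), byrow = TRUE) -
                sweep(cache$xhat, 2,
                      colMeans(dxhat * cache$xhat), "*"),
              2, istd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Convolutional baseline architecture shapes
#'
#' Returns the layer plan of the 3-channel convolutional network:
#' Input(100 x 7 x 3) - Conv(30 x 1 @ 25) - tanh - AvgPool(2 x 1) -
#' BatchNorm - Conv(15 x 17 @ 20, over the time x feature map) - tanh -
#' AvgPool(2 x 1) - BatchNorm - Dense(C) - Softmax. The second kernel runs
#' over the time axis crossed with the (joint, filter) feature axis.
#'
#' @param n_classes Class count for the dense head.
#' @return List of conv plans and dimensions.
#' @export
cnn_plan <- function(n_classes) {
  p1 <- .conv_plan(100L, 7L, 3L, 30L, 1L)     # -> 71 x 7 x 25
  nh1 <- p1$oh %/% 2L                          # -> 35 x 7 x 25
  p2 <- .conv_plan(nh1, 7L * 25L, 1L, 15L, 17L) # -> 21 x 159 x 20
  nh2 <- p2$oh %/% 2L                          # -> 10 x 159 x 20
  list(p1 = p1, nh1 = nh1, p2 = p2, nh2 = nh2,
       f1 = 25L, f2 = 20L,
       flat = nh2 * p2$ow * 20L, n_classes = n_classes)
}

.cnn_init <- function(plan, rng, n_out, latent = NULL) {
  list(
    W1 = .glorot(ncol(plan$p1$idx), plan$f1, rng), b1 = rep(0, plan$f1),
    g1 = rep(1, plan$f1), be1 = rep(0, plan$f1),
    W2 = .glorot(ncol(plan$p2$idx), plan$f2, rng), b2 = rep(0, plan$f2),
    g2 = rep(1, plan$f2), be2 = rep(0, plan$f2),
    W3 = .glorot(plan$flat, n_out, rng), b3 = rep(0, n_out)
  )
}

# forward to the flattened representation; X: matrix n x (100*7*3)
.cnn_trunk_forward <- function(plan, par, X, train = TRUE) {
  n <- nrow(X)
  c1 <- lapply(seq_len(n), function(i) .conv_forward(plan$p1, X[i, ],
                                                     par$W1, par$b1))
  A1 <- lapply(c1, function(z) tanh(z$Y))
  P1 <- lapply(A1, function(a) .pool_forward(a, plan$p1$oh, plan$p1$ow))
  S1 <- do.call(rbind, lapply(P1, function(p) p$Y)) # (n*35*7) x 25
  B1 <- .bn_forward(S1, par$g1, par$be1)
  rows1 <- nrow(P1[[1]]$Y)
  c2 <- lapply(seq_len(n), function(i) {
    xin <- B1$Y[(i - 1) * rows1 + seq_len(rows1), , drop = FALSE]
    # (35 x 7 x 25) -> single-channel (35 x 175) map, channel-last columns
    xmap <- matrix(aperm(array(xin, c(plan$nh1, plan$p1$ow, plan$f1)),
                         c(1, 3, 2)), plan$nh1, plan$p1$ow * plan$f1)
    .conv_forward(plan$p2, as.numeric(xmap), par$W2, par$b2)
  })
  A2 <- lapply(c2, function(z) tanh(z$Y))
  P2 <- lapply(A2, function(a) .pool_forward(a, plan$p2$oh, plan$p2$ow))
  S2 <- do.call(rbind, lapply(P2, function(p) p$Y))
  B2 <- .bn_forward(S2, par$g2, par$be2)
  rows2 <- nrow(P2[[1]]$Y)
  flat <- t(vapply(seq_len(n), function(i) {
    as.numeric(B2$Y[(i - 1) * rows2 + seq_len(rows2), , drop = FALSE])
  }, numeric(plan$flat)))
  list(c1 = c1, A1 = A1, B1 = B1, c2 = c2, A2 = A2, B2 = B2,
       flat = flat, rows1 = rows1, rows2 = rows2, n = n)
}

.cnn_trunk_backward <- function(plan, par, X, cc, dflat) {
  n <- cc$n
  grads <- list(W1 = 0 * par$W1, b1 = 0 * par$b1, g1 = 0 * par$g1,
                be1 = 0 * par$be1, W2 = 0 * par$W2, b2 = 0 * par$b2,
                g2 = 0 * par$g2, be2 = 0 * par$be2)
  dS2 <- do.call(rbind, lapply(seq_len(n), function(i) {
    matrix(dflat[i, ], cc$rows2, plan$f2)
  }))
  bn2 <- .bn_backward(cc$B2, par$g2, dS2)
  grads$g2 <- bn2$dgamma; grads$be2 <- bn2$dbeta
  dS1_list <- vector("list", n)
  for (i in seq_len(n)) {
    dP2 <- bn2$dx[(i - 1) * cc$rows2 + seq_len(cc$rows2), , drop = FALSE]
    dA2 <- .pool_backward(dP2, plan$p2$oh, plan$p2$ow, plan$f2)
    dY2 <- dA2 * (1 - cc$A2[[i]]^2)
    cb2 <- .conv_backward(plan$p2, cc$c2[[i]], par$W2, dY2)
    grads$W2 <- grads$W2 + cb2$dW; grads$b2 <- grads$b2 + cb2$db
    # back from (35 x 175) map to (35*7) x 25 layout
    dmap <- matrix(cb2$dx, plan$nh1, plan$p1$ow * plan$f1)
    dS1_list[[i]] <- matrix(aperm(array(dmap, c(plan$nh1, plan$f1,
                                                plan$p1$ow)),
                                  c(1, 3, 2)), cc$rows1, plan$f1)
  }
  bn1 <- .bn_backward(cc$B1, par$g1, do.call(rbind, dS1_list))
  grads$g1 <- bn1$dgamma; grads$be1 <- bn1$dbeta
  for (i in seq_len(n)) {
    dP1 <- bn1$dx[(i - 1) * cc$rows1 + seq_len(cc$rows1), , drop = FALSE]
    dA1 <- .pool_backward(dP1, plan$p1$oh, plan$p1$ow, plan$f1)
    dY1 <- dA1 * (1 - cc$A1[[i]]^2)
    cb1 <- .conv_backward(plan$p1, cc$c1[[i]], par$W1, dY1)
    grads$W1 <- grads$W1 + cb1$dW; grads$b1 <- grads$b1 + cb1$db
  }
  grads
}

# shared Adam over a flat named list of arrays
.flat_adam <- function(par, grads, state, lr, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / (1 - beta1^t)) /
      (sqrt(state$v[[nm]] / (1 - beta2^t)) + eps)
  }
  list(par = par, state = state)
}

#' Train the 3-channel convolutional baseline classifier
#'
#' Inputs are the 7-joint lower-limb exponential-map tensors, linearly
#' time-scaled to 100 frames. Trained full-batch with Adam.
#'
#' @param bundles Named bundle list.
#' @param sids Labels parallel to `bundles`.
#' @param labels Class universe.
#' @param epochs,learning_rate,seed Training settings.
#' @return Object of class `cnn_baseline`.
#' @export
train_cnn_baseline <- function(bundles, sids, labels = sort(unique(sids)),
                               epochs = 30L, learning_rate = 1e-3,
                               seed = 1L) {
  sids <- as.character(sids)
  rng <- .local_rng(seed)
  plan <- cnn_plan(length(labels))
  X <- t(vapply(bundles, function(b) {
    as.numeric(interpolate_time(.cnn_joint_tensor(b)))
  }, numeric(100L * 7L * 3L)))
  class_ix <- match(sids, labels)
  par <- .cnn_init(plan, rng, length(labels))
  state <- list(m = lapply(par, function(p) 0 * p),
                v = lapply(par, function(p) 0 * p))
  n <- nrow(X)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    cc <- .cnn_trunk_forward(plan, par, X)
    logits <- sweep(cc$flat %*% par$W3, 2, par$b3, "+")
    P <- t(apply(logits, 1, .softmax))
    loss <- mean(vapply(seq_len(n), function(i) {
      cross_entropy(class_ix[i], P[i, ], is_index = TRUE)
    }, 0))
    history[ep] <- loss
    dlog <- P
    dlog[cbind(seq_len(n), class_ix)] <-
      dlog[cbind(seq_len(n), class_ix)] - 1
    dlog <- dlog / n
    grads <- .cnn_trunk_backward(plan, par, X, cc,
                                 dlog %*% t(par$W3))
    grads$W3 <- crossprod(cc$flat, dlog)
    grads$b3 <- colSums(dlog)
    upd <- .flat_adam(par, grads, state, learning_rate, ep)
    par <- upd$par
    state <- upd$state
  }
  structure(list(kind = "cnn", plan = plan, par = par, labels = labels,
                 history = history),
            class = "cnn_baseline")
}

#' @export
baseline_predict.cnn_baseline <- function(clf, bundles) {
  X <- t(vapply(bundles, function(b) {
    as.numeric(interpolate_time(.cnn_joint_tensor(b)))
  }, numeric(100L * 7L * 3L)))
  cc <- .cnn_trunk_forward(clf$plan, clf$par, X, train = FALSE)
  logits <- sweep(cc$flat %*% clf$par$W3, 2, clf$par$b3, "+")
  probs <- t(apply(logits, 1, .softmax))
  list(labels = clf$labels[max.col(probs, ties.method = "first")],
       probs = probs)
}

#' Train the convolutional autoencoder and return its 128-d embeddings
#'
#' Same convolutional trunk as [train_cnn_baseline()]; the flattened code is
#' mapped to a 128-dimensional latent vector, and a dense decoder
#' reconstructs the interpolated input under mean-squared-error loss. The
#' latent layer plays the role of the class embedding at evaluation time.
#'
#' @inheritParams train_cnn_baseline
#' @param latent_dim Latent width (reference 128).
#' @return Object of class `cae_baseline`; `cae_embed()` returns latent
#'   codes.
#' @export
train_cae <- function(bundles, sids, labels = sort(unique(sids)),
                      latent_dim = 128L, epochs = 30L,
                      learning_rate = 3e-4, seed = 1L) {
  rng <- .local_rng(seed)
  plan <- cnn_plan(2L)
  X <- t(vapply(bundles, function(b) {
    as.numeric(interpolate_time(.cnn_joint_tensor(b)))
  }, numeric(100L * 7L * 3L)))
  par <- .cnn_init(plan, rng, 2L)
  par$W3 <- NULL; par$b3 <- NULL
  par$Wl <- .glorot(plan$flat, latent_dim, rng)
  par$bl <- rep(0, latent_dim)
  par$Wd <- .glorot(latent_dim, ncol(X), rng)
  par$bd <- rep(0, ncol(X))
  state <- list(m = lapply(par, function(p) 0 * p),
                v = lapply(par, function(p) 0 * p))
  n <- nrow(X)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    cc <- .cnn_trunk_forward(plan, par, X)
    Z <- sweep(cc$flat %*% par$Wl, 2, par$bl, "+")
    R <- sweep(Z %*% par$Wd, 2, par$bd, "+")
    err <- R - X
    history[ep] <- mean(err^2)
    dR <- 2 * err / length(err)
    grads <- list(Wd = crossprod(Z, dR), bd = colSums(dR))
    dZ <- dR %*% t(par$Wd)
    grads$Wl <- crossprod(cc$flat, dZ)
    grads$bl <- colSums(dZ)
    dflat <- dZ %*% t(par$Wl)
    tg <- .cnn_trunk_backward(plan, par, X, cc, dflat)
    grads <- c(grads, tg)
    upd <- .flat_adam(par, grads, state, learning_rate, ep)
    par <- upd$par
    state <- upd$state
  }
  structure(list(kind = "cae", plan = plan, par = par,
                 latent_dim = latent_dim, labels = labels,
                 history = history),
            class = "cae_baseline")
}

#' Latent codes from a trained convolutional autoencoder
#' @param clf A `cae_baseline`.
#' @param bundles Bundle list.
#' @return Matrix n x latent_dim.
#' @export
cae_embed <- function(clf, bundles) {
  X <- t(vapply(bundles, function(b) {
    as.numeric(interpolate_time(.cnn_joint_tensor(b)))
  }, numeric(100L * 7L * 3L)))
  cc <- .cnn_trunk_forward(clf$plan, clf$par, X, train = FALSE)
  sweep(cc$flat %*% clf$par$Wl, 2, clf$par$bl, "+")
}

# ---- handcrafted features ------------------------------------------------

.bone_pairs <- function() {
  k <- kinect_joints[!is.na(kinect_joints$parent), ]
  cbind(k$joint, k$parent)
}

#' Handcrafted anthropometric and dynamic gait features
#'
#' Per sample: mean and standard deviation across the recording of the
#' ankle-ankle step length (per-cycle maxima of the per-frame ankle
#' distance), the stride length (sum of two consecutive steps), every bone
#' length along the kinematic tree, and the height (sum of bone lengths
#' from head to foot). All computed from the absolute positional data.
#'
#' @param seq A [gait_sequence()].
#' @return Named numeric feature vector of fixed length (6 + 2 x 19 bones).
#' @export
handcrafted_features <- function(seq) {
  pos <- seq$positions
  al <- pos[, "AnkleLeft", ]
  ar <- pos[, "AnkleRight", ]
  ankle_d <- sqrt(rowSums((al - ar)^2))
  # local maxima of the ankle-distance series = step instants
  n <- length(ankle_d)
  peaks <- which(diff(sign(diff(ankle_d))) < 0) + 1L
  steps <- if (length(peaks)) ankle_d[peaks] else max(ankle_d)
  strides <- if (length(steps) >= 2) {
    steps[-length(steps)] + steps[-1]
  } else 2 * steps
  bone_len <- apply(.bone_pairs(), 1, function(bp) {
    sqrt(rowSums((pos[, bp[1], , drop = TRUE] -
                    pos[, bp[2], , drop = TRUE])^2))
  })
  if (is.null(dim(bone_len))) bone_len <- matrix(bone_len, nrow = 1)
  colnames(bone_len) <- .bone_pairs()[, 1]
  height_chain <- c("Head", "ShoulderCenter", "Spine", "HipLeft",
                    "KneeLeft", "AnkleLeft", "FootLeft")
  height <- rowSums(bone_len[, height_chain, drop = FALSE])
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  bone_feats <- as.numeric(rbind(colMeans(bone_len),
                                 apply(bone_len, 2, sd0)))
  names(bone_feats) <- paste0(rep(colnames(bone_len), each = 2),
                              c("_mean", "_sd"))
  c(step_mean = mean(steps), step_sd = sd0(steps),
    stride_mean = mean(strides), stride_sd = sd0(strides),
    height_mean = mean(height), height_sd = sd0(height),
    bone_feats)
}

#' Remove per-feature 2-standard-deviation outliers
#'
#' A sample is dropped when any of its features lies more than `z_max`
#' standard deviations from that feature's mean (constant features are
#' ignored).
#'
#' @param X Feature matrix, samples in rows.
#' @param z_max Threshold in standard deviations (default 2).
#' @return Logical vector of samples to keep.
#' @export
feature_outlier_filter <- function(X, z_max = 2) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- rep(TRUE, nrow(X))
  for (j in which(sdv > 0)) {
    keep <- keep & abs(X[, j] - mu[j]) <= z_max * sdv[j]
  }
  keep
}

#' Handcrafted-feature random-subspace kNN pipeline
#'
#' Extracts handcrafted features for train and test samples, removes
#' training outliers beyond 2 SD per feature, standardizes, then runs
#' `draws` random feature-subspace kNN classifications and returns the
#' distribution of accuracy and macro-F1 scores. Deterministic under
#' `seed`.
#'
#' @param train_seqs,test_seqs Lists of [gait_sequence()] objects.
#' @param draws Number of random subspace draws (reference 50).
#' @param subspace_size Features per draw (default: half, at least 2).
#' @param k kNN neighborhood size.
#' @param seed Integer seed.
#' @return Data frame with one row per draw (`draw`, `accuracy`, `f1`).
#' @export
handcrafted_pipeline <- function(train_seqs, test_seqs, draws = 50L,
                                 subspace_size = NULL, k = 5L, seed = 1L) {
  Xtr <- t(vapply(train_seqs, handcrafted_features,
                  handcrafted_features(train_seqs[[1]])))
  Xte <- t(vapply(test_seqs, handcrafted_features,
                  handcrafted_features(test_seqs[[1]])))
  ytr <- vapply(train_seqs, function(s) s$sid, "")
  yte <- vapply(test_seqs, function(s) s$sid, "")
  keep <- feature_outlier_filter(Xtr)
  Xtr <- Xtr[keep, , drop = FALSE]
  ytr <- ytr[keep]
  mu <- colMeans(Xtr)
  sdv <- pmax(apply(Xtr, 2, stats::sd), 1e-12)
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  p <- ncol(Xtr)
  if (is.null(subspace_size)) subspace_size <- max(2L, p %/% 2L)
  if (subspace_size < 2) stop("subspace_size must be at least 2")
  rng <- .local_rng(seed)
  labels <- sort(unique(c(ytr, yte)))
  out <- lapply(seq_len(draws), function(d) {
    coords <- rng$sample(seq_len(p), subspace_size)
    pred <- knn_classify(embedding_set(Xtr[, coords, drop = FALSE], ytr),
                         embedding_set(Xte[, coords, drop = FALSE], yte),
                         k = min(k, nrow(Xtr)))
    rp <- classification_report(yte, pred, labels)
    data.frame(draw = d, accuracy = rp$accuracy, f1 = rp$f1)
  })
  do.call(rbind, out)
}
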