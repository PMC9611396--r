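#' Cross-entropy loss
#'
#' `L = -sum_c y_c log(yhat_c)` for a one-hot target. Predicted
#' probabilities are clamped at 1e-12 for numerical safety.
#'
#' @param y One-hot target vector (or a class index if `is_index = TRUE`).
#' @param yhat Predicted probability vector (nonnegative, sums to 1).
#' @param is_index Interpret `y` as a 1-based class index.
#' @return Nonnegative scalar; zero iff `yhat` puts mass 1 on the true
#'   class.
#' @export
cross_entropy <- function(y, yhat, is_index = FALSE) {
  if (is_index) {
    idx <- as.integer(y)
    stopifnot(idx >= 1, idx <= length(yhat))
    return(-log(max(yhat[idx], 1e-12)))
  }
  if (length(y) != length(yhat)) {
    stop("length mismatch: target has ", length(y), " entries, prediction ",
         length(yhat))
  }
  -sum(y * log(pmax(yhat, 1e-12)))
}

#' Training configuration
#'
#' Two documented profiles: `"reference"` mirrors the published regime
#' (Adam, learning rate 3e-5, 30 epochs, per-sequence updates) sized for
#' ~2500-sample, 100-class training; `"reduced"` keeps the same loop at a
#' 3e-4 rate, appropriate for the desk-scale synthetic runs that make
#' ~100x fewer optimizer updates. (Aggressive rates are unstable late in
#' training under per-sequence Adam: once the loss is tiny, the
#' second-moment normalizer amplifies noise gradients.)
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed controlling shuffling.
#' @param clip_norm Clip each factor's gradient to this global L2 norm
#'   before the update (`Inf` disables clipping). Defaults by profile:
#'   `Inf` for `"reference"`, 5 for `"reduced"` — per-sequence Adam at the
#'   reduced scale occasionally spikes after convergence, and a mild clip
#'   suppresses the excursion without touching ordinary updates.
#' @param checkpoint_every Save a checkpoint every this many epochs (0 =
#'   never); requires `checkpoint_dir`.
#' @param checkpoint_dir Directory for checkpoints.
#' @param profile Convenience preset, `"reference"` or `"reduced"`;
#'   explicit arguments win.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = NULL, epochs = 30L, seed = 1L,
                         clip_norm = NULL,
                         checkpoint_every = 0L, checkpoint_dir = NULL,
                         profile = c("reduced", "reference")) {
  profile <- match.arg(profile)
  if (is.null(learning_rate)) {
    learning_rate <- if (profile == "reference") 3e-5 else 3e-4
  }
  if (is.null(clip_norm)) {
    clip_norm <- if (profile == "reference") Inf else 5
  }
  stopifnot(learning_rate > 0, epochs >= 1, clip_norm > 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), clip_norm = clip_norm,
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir, profile = profile),
            class = "train_config")
}

# loss + gradient accumulation for a single (bundle, label index) pair
.loss_and_grads <- function(model, bundle, class_ix) {
  fw <- forward(model, bundle, keep_cache = TRUE)
  loss <- cross_entropy(class_ix, fw$probs, is_index = TRUE)
  dlogits <- fw$probs
  dlogits[class_ix] <- dlogits[class_ix] - 1
  backward(model, fw, dlogits)
  list(loss = loss, probs = fw$probs)
}

#' Train the gait model by per-sequence stochastic gradient descent
#'
#' Sequences are visited one at a time (batch size 1; sequences have
#' variable length so no padding is needed), the order reshuffled every
#' epoch under the config seed, with an Adam update after each sequence.
#' Gradients flow through the full unrolled sequence — no truncation.
#'
#' @param model An [build_model()] model whose `labels` cover the training
#'   sids.
#' @param bundles Named list of [sequence_to_node_inputs()] bundles.
#' @param sids Character vector of subject labels, parallel to `bundles`.
#' @param cfg A [train_config()].
#' @param quiet Suppress per-epoch progress messages.
#' @return List with `model` (trained, parameters frozen for inference) and
#'   `history` (data frame of per-epoch mean loss and training accuracy).
#' @export
train_model <- function(model, bundles, sids, cfg = train_config(),
                        quiet = TRUE) {
  stopifnot(length(bundles) == length(sids), length(bundles) >= 1)
  sids <- as.character(sids)
  if (length(unique(sids)) < 2) {
    stop("training needs at least 2 classes, got ", length(unique(sids)))
  }
  class_ix <- match(sids, model$labels)
  if (anyNA(class_ix)) {
    stop("sid absent from the model's label vocabulary: ",
         sids[which(is.na(class_ix))[1]])
  }
  rng <- .local_rng(cfg$seed)
  n <- length(bundles)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  factors <- model$factors
  orders <- vector("list", cfg$epochs)
  first_loss <- NA_real_
  for (epoch in seq_len(cfg$epochs)) {
    ord <- rng$sample(seq_len(n))
    orders[[epoch]] <- ord
    tot_loss <- 0
    correct <- 0L
    for (i in ord) {
      zero_grads(factors)
      res <- .loss_and_grads(model, bundles[[i]], class_ix[i])
      if (is.na(first_loss)) first_loss <- res$loss
      if (is.finite(cfg$clip_norm)) clip_grads(factors, cfg$clip_norm)
      model$adam_t <- model$adam_t + 1L
      adam_step(factors, cfg$learning_rate, model$adam_t)
      tot_loss <- tot_loss + res$loss
      if (which.max(res$probs) == class_ix[i]) correct <- correct + 1L
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = tot_loss / n, accuracy = correct / n))
    if (!quiet) {
      message(sprintf("epoch %3d | loss %.4f | train acc %.3f",
                      epoch, tot_loss / n, correct / n))
    }
    if (cfg$checkpoint_every > 0 && !is.null(cfg$checkpoint_dir) &&
        epoch %% cfg$checkpoint_every == 0) {
      save_checkpoint(model, file.path(
        cfg$checkpoint_dir, sprintf("checkpoint_epoch%03d.rds", epoch)))
    }
  }
  attr(history, "orders") <- orders
  attr(history, "first_loss") <- first_loss
  list(model = model, history = history)
}

#' Preprocess and cache bundles for a set of manifest samples
#'
#' @param manifest Manifest from [read_manifest()] or [simulate_dataset()].
#' @param sample_ids Samples to preprocess.
#' @param cfg A [smoothing_config()].
#' @param graph The gait graph.
#' @return Named list of bundles, plus attribute `sids`.
#' @export
prepare_bundles <- function(manifest, sample_ids,
                            cfg = smoothing_config(),
                            graph = build_gait_st_graph()) {
  recs <- load_recordings(manifest, sample_ids)
  bundles <- lapply(recs, function(r) {
    cache_static_inputs(sequence_to_node_inputs(r, graph = graph,
                                                cfg = cfg))
  })
  attr(bundles, "sids") <- vapply(recs, function(r) r$sid, "")
  bundles
}
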