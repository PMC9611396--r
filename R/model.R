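#' Model configuration
#'
#' Widths follow the reference architecture: every base-layer edge factor
#' (MLP and edge LSTMs) has 128 hidden units, each body-part node LSTM and
#' its fully-connected layer 256, the final fusion LSTM 512, and the class
#' embedding is 128-dimensional. `width_multiplier` scales the three
#' feature-map widths (not the embedding) for reduced-scale runs.
#'
#' @param n_classes Number of subject labels C.
#' @param base_width Edge-factor width (reference 128).
#' @param node_width Node-factor width (reference 256).
#' @param fusion_width Final LSTM width (reference 512).
#' @param embedding_dim Embedding dimensionality d (reference 128).
#' @param width_multiplier Scales base/node/fusion widths; 1 reproduces the
#'   reference layout exactly.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_classes, base_width = 128L, node_width = 256L,
                         fusion_width = 512L, embedding_dim = 128L,
                         width_multiplier = 1) {
  stopifnot(n_classes >= 2, base_width > 0, node_width > 0,
            fusion_width > 0, embedding_dim > 0, width_multiplier > 0)
  structure(list(
    n_classes = as.integer(n_classes),
    base_width = as.integer(round(base_width * width_multiplier)),
    node_width = as.integer(round(node_width * width_multiplier)),
    fusion_width = as.integer(round(fusion_width * width_multiplier)),
    embedding_dim = as.integer(embedding_dim),
    width_multiplier = width_multiplier
  ), class = "model_config")
}

#' Build the graph-factorized recurrent gait model
#'
#' Instantiates one shared factor per graph partition: per limb pair and for
#' the spine an input MLP and a temporal edge LSTM; per limb pair a
#' spine-limb adjacency edge LSTM and a left-right symmetry edge LSTM
#' (7 recurrent edge factors in total); three body-part node factors
#' (LSTM + fully-connected), one final fusion LSTM, an embedding head and a
#' logits head. Left and right limbs of a pair resolve to the *same* factor
#' environments — shared storage, not copies.
#'
#' @param graph The [build_gait_st_graph()] graph.
#' @param cfg A [model_config()].
#' @param seed Integer seed for deterministic initialization (orthogonal
#'   recurrent kernels, Glorot-uniform input kernels, zero biases).
#' @param labels Optional character vector of class labels (length
#'   `cfg$n_classes`).
#' @return An object of class `st_gait_model`.
#' @export
build_model <- function(graph = build_gait_st_graph(), cfg, seed = 1L,
                        labels = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  rng <- .local_rng(seed)
  bw <- cfg$base_width; nw <- cfg$node_width; fw <- cfg$fusion_width
  in_spine <- 3L * 3L; in_leg <- 3L * 3L; in_arm <- 4L * 3L

  factors <- list(
    mlp_spine = new_mlp_factor(in_spine, bw, rng),
    mlp_legs = new_mlp_factor(in_leg, bw, rng),
    mlp_arms = new_mlp_factor(in_arm, bw, rng),
    temporal_spine = new_lstm_factor(2L * in_spine, bw, bw, rng, "relu"),
    temporal_legs = new_lstm_factor(2L * in_leg, bw, bw, rng, "relu"),
    temporal_arms = new_lstm_factor(2L * in_arm, bw, bw, rng, "relu"),
    adjacency_legs = new_lstm_factor(in_leg + in_spine, bw, bw, rng, "relu"),
    adjacency_arms = new_lstm_factor(in_arm + in_spine, bw, bw, rng, "relu"),
    symmetry_legs = new_lstm_factor(2L * in_leg, bw, bw, rng, "relu"),
    symmetry_arms = new_lstm_factor(2L * in_arm, bw, bw, rng, "relu"),
    node_lstm_spine = new_lstm_factor(4L * bw, nw, NULL, rng),
    node_lstm_legs = new_lstm_factor(4L * bw, nw, NULL, rng),
    node_lstm_arms = new_lstm_factor(4L * bw, nw, NULL, rng),
    node_fc_spine = new_dense_factor(nw, nw, rng, "relu"),
    node_fc_legs = new_dense_factor(nw, nw, rng, "relu"),
    node_fc_arms = new_dense_factor(nw, nw, rng, "relu"),
    final_lstm = new_lstm_factor(3L * nw, fw, fw, rng, "none"),
    embed_head = new_dense_factor(fw, cfg$embedding_dim, rng, "none"),
    logit_head = new_dense_factor(cfg$embedding_dim, cfg$n_classes, rng,
                                  "none")
  )
  if (is.null(labels)) labels <- sprintf("C%03d", seq_len(cfg$n_classes))
  stopifnot(length(labels) == cfg$n_classes)
  structure(list(graph = graph, config = cfg, factors = factors,
                 labels = as.character(labels), adam_t = 0L),
            class = "st_gait_model")
}

#' Shared factor environments serving a vertex
#'
#' Resolves a body-part vertex to the factor environments that process it.
#' Bilateral limbs return identical environments for both sides.
#'
#' @param model An [build_model()] model.
#' @param vertex One of [gait_vertices()].
#' @return Named list of factor environments (`mlp`, `temporal`,
#'   `adjacency` (limbs only), `symmetry` (limbs only), `node_lstm`,
#'   `node_fc`).
#' @export
vertex_factors <- function(model, vertex) {
  part <- model$graph$vertex_partition[[vertex]]
  f <- model$factors
  out <- list(mlp = f[[paste0("mlp_", part)]],
              temporal = f[[paste0("temporal_", part)]],
              node_lstm = f[[paste0("node_lstm_", part)]],
              node_fc = f[[paste0("node_fc_", part)]])
  if (part != "spine") {
    out$adjacency <- f[[paste0("adjacency_", part)]]
    out$symmetry <- f[[paste0("symmetry_", part)]]
  }
  out
}

# Static per-sequence network inputs: flattened part matrices plus the
# temporal, adjacency and symmetry edge features. Independent of the
# parameters, so they are computed once per sequence and cached on the
# bundle across epochs.
.static_inputs <- function(bundle) {
  xs <- .flatten_vertex(bundle, "spine")
  xl_leg <- .flatten_vertex(bundle, "leg_left")
  xr_leg <- .flatten_vertex(bundle, "leg_right")
  xl_arm <- .flatten_vertex(bundle, "arm_left")
  xr_arm <- .flatten_vertex(bundle, "arm_right")
  if (!all(is.finite(xs)) || !all(is.finite(xl_leg)) ||
      !all(is.finite(xr_leg)) || !all(is.finite(xl_arm)) ||
      !all(is.finite(xr_arm))) {
    stop("non-finite values in node inputs")
  }
  list(
    xs = xs, xl_leg = xl_leg, xr_leg = xr_leg,
    xl_arm = xl_arm, xr_arm = xr_arm,
    tf_s = .temporal_feature(xs),
    tf_ll = .temporal_feature(xl_leg), tf_lr = .temporal_feature(xr_leg),
    tf_al = .temporal_feature(xl_arm), tf_ar = .temporal_feature(xr_arm),
    adj_ll = cbind(xl_leg, xs), adj_lr = cbind(xr_leg, xs),
    adj_al = cbind(xl_arm, xs), adj_ar = cbind(xr_arm, xs),
    sym_leg = cbind(xl_leg, xr_leg), sym_arm = cbind(xl_arm, xr_arm)
  )
}

#' Attach cached network inputs to a bundle
#'
#' Precomputes the parameter-independent edge features so repeated forward
#' passes (training epochs) skip re-assembly.
#'
#' @param bundle A [sequence_to_node_inputs()] bundle.
#' @return The bundle with a `static` attribute.
#' @export
cache_static_inputs <- function(bundle) {
  if (is.null(attr(bundle, "static"))) {
    attr(bundle, "static") <- .static_inputs(bundle)
  }
  bundle
}

# temporal edge feature: [x_t || x_t - x_(t-1)] with zero difference at t=1
.temporal_feature <- function(X) {
  D <- rbind(matrix(0, 1, ncol(X)), diff(X))
  cbind(X, D)
}


#' Forward pass through the factorized network
#'
#' Layer 1 applies, per side, the shared input MLP, the shared temporal edge
#' LSTM on `[x_t || x_t - x_(t-1)]`, and the shared spine-limb adjacency
#' LSTM on `[limb || spine]`; the symmetry LSTM sees `[left || right]`.
#' Layer 2 feeds each body-part node LSTM the concatenation of the
#' side-summed MLP, temporal and adjacency outputs plus the symmetry output
#' (the spine node reuses the side-summed leg and arm adjacency outputs).
#' Layer 3 concatenates the three node output sequences into the fusion
#' LSTM; the embedding is a linear map of its last output `z_T`, and the
#' logits are a linear map of `tanh(embedding)`.
#'
#' @param model An `st_gait_model`.
#' @param bundle A [sequence_to_node_inputs()] bundle.
#' @param t_last Read the sequence state at this frame (default: the full
#'   length). Lets padded sequences be masked: frames after `t_last` cannot
#'   influence the output because every layer is causal.
#' @param keep_cache Retain intermediate activations for backpropagation.
#' @return A list with `logits`, `probs`, `embedding`, and per-layer feature
#'   maps `layer1` (T x base width each), `layer2` (T x node width), and
#'   `layer3` (T x fusion width).
#' @export
forward <- function(model, bundle, t_last = NULL, keep_cache = FALSE) {
  stopifnot(inherits(bundle, "node_input_bundle"))
  tt <- attr(bundle, "T")
  if (tt < 2) stop("forward pass needs T >= 2, got ", tt)
  if (is.null(t_last)) t_last <- tt
  stopifnot(t_last >= 2, t_last <= tt)
  f <- model$factors

  st <- attr(bundle, "static")
  if (is.null(st)) st <- .static_inputs(bundle)

  cc <- list() # caches
  # ---- layer 1 ----
  cc$mlp_s <- mlp_forward(f$mlp_spine, st$xs)
  cc$mlp_ll <- mlp_forward(f$mlp_legs, st$xl_leg)
  cc$mlp_lr <- mlp_forward(f$mlp_legs, st$xr_leg)
  cc$mlp_al <- mlp_forward(f$mlp_arms, st$xl_arm)
  cc$mlp_ar <- mlp_forward(f$mlp_arms, st$xr_arm)

  cc$tmp_s <- lstm_forward(f$temporal_spine, st$tf_s)
  cc$tmp_ll <- lstm_forward(f$temporal_legs, st$tf_ll)
  cc$tmp_lr <- lstm_forward(f$temporal_legs, st$tf_lr)
  cc$tmp_al <- lstm_forward(f$temporal_arms, st$tf_al)
  cc$tmp_ar <- lstm_forward(f$temporal_arms, st$tf_ar)

  cc$adj_ll <- lstm_forward(f$adjacency_legs, st$adj_ll)
  cc$adj_lr <- lstm_forward(f$adjacency_legs, st$adj_lr)
  cc$adj_al <- lstm_forward(f$adjacency_arms, st$adj_al)
  cc$adj_ar <- lstm_forward(f$adjacency_arms, st$adj_ar)

  cc$sym_leg <- lstm_forward(f$symmetry_legs, st$sym_leg)
  cc$sym_arm <- lstm_forward(f$symmetry_arms, st$sym_arm)

  # ---- layer 2 ----
  in_legs <- cbind(cc$mlp_ll$Y + cc$mlp_lr$Y, cc$tmp_ll$Z + cc$tmp_lr$Z,
                   cc$adj_ll$Z + cc$adj_lr$Z, cc$sym_leg$Z)
  in_arms <- cbind(cc$mlp_al$Y + cc$mlp_ar$Y, cc$tmp_al$Z + cc$tmp_ar$Z,
                   cc$adj_al$Z + cc$adj_ar$Z, cc$sym_arm$Z)
  in_spine <- cbind(cc$mlp_s$Y, cc$tmp_s$Z,
                    cc$adj_ll$Z + cc$adj_lr$Z, cc$adj_al$Z + cc$adj_ar$Z)
  cc$node_lstm_legs <- lstm_forward(f$node_lstm_legs, in_legs)
  cc$node_lstm_arms <- lstm_forward(f$node_lstm_arms, in_arms)
  cc$node_lstm_spine <- lstm_forward(f$node_lstm_spine, in_spine)
  cc$node_fc_legs <- dense_forward(f$node_fc_legs, cc$node_lstm_legs$Z)
  cc$node_fc_arms <- dense_forward(f$node_fc_arms, cc$node_lstm_arms$Z)
  cc$node_fc_spine <- dense_forward(f$node_fc_spine, cc$node_lstm_spine$Z)

  # ---- layer 3 ----
  in_final <- cbind(cc$node_fc_spine$Y, cc$node_fc_legs$Y,
                    cc$node_fc_arms$Y)
  cc$final <- lstm_forward(f$final_lstm, in_final)
  zT <- cc$final$Z[t_last, , drop = FALSE]
  cc$embed <- dense_forward(f$embed_head, zT)
  embedding <- cc$embed$Y
  cc$tanh_e <- tanh(embedding)
  cc$logit <- dense_forward(f$logit_head, cc$tanh_e)
  logits <- drop(cc$logit$Y)
  probs <- .softmax(logits)

  out <- list(
    logits = logits, probs = probs, embedding = drop(embedding),
    layer1 = list(temporal_spine = cc$tmp_s$Z,
                  temporal_leg_left = cc$tmp_ll$Z,
                  temporal_leg_right = cc$tmp_lr$Z,
                  temporal_arm_left = cc$tmp_al$Z,
                  temporal_arm_right = cc$tmp_ar$Z,
                  adjacency_leg_left = cc$adj_ll$Z,
                  adjacency_leg_right = cc$adj_lr$Z,
                  adjacency_arm_left = cc$adj_al$Z,
                  adjacency_arm_right = cc$adj_ar$Z,
                  symmetry_legs = cc$sym_leg$Z,
                  symmetry_arms = cc$sym_arm$Z),
    layer2 = list(spine = cc$node_fc_spine$Y, legs = cc$node_fc_legs$Y,
                  arms = cc$node_fc_arms$Y),
    layer3 = cc$final$Z,
    t_last = t_last
  )
  if (keep_cache) out$cache <- cc
  out
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Backward pass: given the forward cache and d(loss)/d(logits), accumulate
# parameter gradients into the shared factor environments.
backward <- function(model, fw, dlogits) {
  f <- model$factors
  cc <- fw$cache
  if (is.null(cc)) stop("forward pass was run without keep_cache = TRUE")
  tt <- nrow(cc$final$Z)

  dtanh_e <- dense_backward(f$logit_head, cc$logit,
                            matrix(dlogits, nrow = 1))
  demb <- dtanh_e * (1 - cc$tanh_e^2)
  dzT <- dense_backward(f$embed_head, cc$embed, demb)
  dZf <- matrix(0, tt, ncol(cc$final$Z))
  dZf[fw$t_last, ] <- dzT
  dIn3 <- lstm_backward(f$final_lstm, cc$final, dZf)

  nw <- model$config$node_width
  dns <- dIn3[, 1:nw, drop = FALSE]
  dnl <- dIn3[, nw + 1:nw, drop = FALSE]
  dna <- dIn3[, 2 * nw + 1:nw, drop = FALSE]

  dnode_s <- dense_backward(f$node_fc_spine, cc$node_fc_spine, dns)
  dnode_l <- dense_backward(f$node_fc_legs, cc$node_fc_legs, dnl)
  dnode_a <- dense_backward(f$node_fc_arms, cc$node_fc_arms, dna)
  dIn_s <- lstm_backward(f$node_lstm_spine, cc$node_lstm_spine, dnode_s)
  dIn_l <- lstm_backward(f$node_lstm_legs, cc$node_lstm_legs, dnode_l)
  dIn_a <- lstm_backward(f$node_lstm_arms, cc$node_lstm_arms, dnode_a)

  bw <- model$config$base_width
  blk <- function(d, k) d[, (k - 1) * bw + 1:bw, drop = FALSE]

  # layer-2 -> layer-1 gradient routing (sums broadcast to both sides)
  dmlp_legs <- blk(dIn_l, 1); dtmp_legs <- blk(dIn_l, 2)
  dadj_legs <- blk(dIn_l, 3); dsym_legs <- blk(dIn_l, 4)
  dmlp_arms <- blk(dIn_a, 1); dtmp_arms <- blk(dIn_a, 2)
  dadj_arms <- blk(dIn_a, 3); dsym_arms <- blk(dIn_a, 4)
  dmlp_s <- blk(dIn_s, 1); dtmp_s <- blk(dIn_s, 2)
  dadj_legs_s <- blk(dIn_s, 3); dadj_arms_s <- blk(dIn_s, 4)

  dadj_legs_tot <- dadj_legs + dadj_legs_s
  dadj_arms_tot <- dadj_arms + dadj_arms_s

  mlp_backward(f$mlp_spine, cc$mlp_s, dmlp_s)
  mlp_backward(f$mlp_legs, cc$mlp_ll, dmlp_legs)
  mlp_backward(f$mlp_legs, cc$mlp_lr, dmlp_legs)
  mlp_backward(f$mlp_arms, cc$mlp_al, dmlp_arms)
  mlp_backward(f$mlp_arms, cc$mlp_ar, dmlp_arms)

  lstm_backward(f$temporal_spine, cc$tmp_s, dtmp_s, need_dx = FALSE)
  lstm_backward(f$temporal_legs, cc$tmp_ll, dtmp_legs, need_dx = FALSE)
  lstm_backward(f$temporal_legs, cc$tmp_lr, dtmp_legs, need_dx = FALSE)
  lstm_backward(f$temporal_arms, cc$tmp_al, dtmp_arms, need_dx = FALSE)
  lstm_backward(f$temporal_arms, cc$tmp_ar, dtmp_arms, need_dx = FALSE)

  lstm_backward(f$adjacency_legs, cc$adj_ll, dadj_legs_tot, need_dx = FALSE)
  lstm_backward(f$adjacency_legs, cc$adj_lr, dadj_legs_tot, need_dx = FALSE)
  lstm_backward(f$adjacency_arms, cc$adj_al, dadj_arms_tot, need_dx = FALSE)
  lstm_backward(f$adjacency_arms, cc$adj_ar, dadj_arms_tot, need_dx = FALSE)

  lstm_backward(f$symmetry_legs, cc$sym_leg, dsym_legs, need_dx = FALSE)
  lstm_backward(f$symmetry_arms, cc$sym_arm, dsym_arms, need_dx = FALSE)
  invisible(NULL)
}

#' Predict the subject label for one recording
#'
#' @param object An `st_gait_model`.
#' @param bundle A [sequence_to_node_inputs()] bundle.
#' @param ... Ignored.
#' @return List with `label` (argmax of the class posterior; ties break to
#'   the lowest class index) and `probs` (named probability vector).
#' @export
predict.st_gait_model <- function(object, bundle, ...) {
  fw <- forward(object, bundle)
  p <- fw$probs
  names(p) <- object$labels
  list(label = object$labels[which.max(p)], probs = p)
}

#' Embed one recording in the learned latent space
#'
#' Returns the pre-tanh embedding vector read from the penultimate layer:
#' similar gaits map close in Euclidean distance.
#'
#' @param model An `st_gait_model`.
#' @param bundle A [sequence_to_node_inputs()] bundle.
#' @return Numeric vector of length `embedding_dim`.
#' @export
embed <- function(model, bundle) {
  forward(model, bundle)$embedding
}

#' Total number of trainable parameters
#' @param model An `st_gait_model`.
#' @return Integer count over the distinct (shared) factors.
#' @export
n_params <- function(model) {
  sum(vapply(model$factors, factor_n_params, 0L))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding the configuration, all
#' parameter (and optimizer-moment) arrays keyed by factor name, and the
#' label vocabulary. Restoring yields bit-identical parameters.
#'
#' @param model An `st_gait_model`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    labels = model$labels,
    adam_t = model$adam_t,
    factors = lapply(model$factors, function(f) {
      list(kind = f$kind, params = f$params, m = f$m, v = f$v,
           project = f$project %||% NULL,
           activation = f$activation %||% NULL,
           n_hidden = f$n_hidden %||% NULL)
    })
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  cfg <- structure(payload$config, class = "model_config")
  model <- build_model(build_gait_st_graph(), cfg, seed = 1L,
                       labels = payload$labels)
  for (nm in names(model$factors)) {
    src <- payload$factors[[nm]]
    f <- model$factors[[nm]]
    f$params <- src$params
    f$m <- src$m
    f$v <- src$v
  }
  model$adam_t <- payload$adam_t
  model
}

#' Write per-layer feature maps of one recording to CSV
#'
#' Runs a forward pass and writes every layer's feature-map sequence
#' (`T x width`: each edge factor's output, each body-part node output,
#' and the fusion layer) as one CSV per map — the raw material for
#' inspecting the oscillating features the recurrent layers learn.
#'
#' @param model An `st_gait_model`.
#' @param bundle A [sequence_to_node_inputs()] bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_feature_maps <- function(model, bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fw <- forward(model, bundle)
  maps <- c(
    stats::setNames(fw$layer1, paste0("layer1_", names(fw$layer1))),
    stats::setNames(fw$layer2, paste0("layer2_node_", names(fw$layer2))),
    list(layer3_fusion = fw$layer3)
  )
  paths <- character(0)
  for (nm in names(maps)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(maps[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
print.st_gait_model <- function(x, ...) {
  cfg <- x$config
  cat("Graph-factorized recurrent gait model\n")
  cat("  widths: base", cfg$base_width, "| node", cfg$node_width,
      "| fusion", cfg$fusion_width, "| embedding", cfg$embedding_dim, "\n")
  cat("  classes:", cfg$n_classes, " parameters:",
      format(n_params(x), big.mark = ","), "\n")
  invisible(x)
}
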