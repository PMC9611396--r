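#' Construct an embedding set
#'
#' @param embeddings Numeric matrix, one row per sample.
#' @param labels Subject labels, length `nrow(embeddings)`.
#' @param sample_ids Optional sample identifiers.
#' @return Object of class `embedding_set`.
#' @export
embedding_set <- function(embeddings, labels, sample_ids = NULL) {
  embeddings <- as.matrix(embeddings)
  labels <- as.character(labels)
  if (nrow(embeddings) != length(labels)) {
    stop("row count (", nrow(embeddings), ") != label count (",
         length(labels), ")")
  }
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(embeddings)))
  structure(list(embeddings = embeddings, labels = labels,
                 sample_ids = as.character(sample_ids)),
            class = "embedding_set")
}

#' Embed every sample of a set through a trained model
#'
#' @param model A trained `st_gait_model`.
#' @param bundles Named list of bundles (see [prepare_bundles()]).
#' @param sids Labels parallel to `bundles` (default: the `sids` attribute).
#' @return An [embedding_set()].
#' @export
embed_dataset <- function(model, bundles, sids = attr(bundles, "sids")) {
  emb <- t(vapply(bundles, function(b) embed(model, b),
                  numeric(model$config$embedding_dim)))
  embedding_set(emb, sids, names(bundles))
}

# pairwise squared Euclidean distances between rows of A and B
.cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' k-nearest-neighbor classification in embedding space
#'
#' Majority vote over the `k` Euclidean nearest reference embeddings. Vote
#' ties break by the largest summed inverse distance among the tied labels,
#' then by the lexicographically lowest label.
#'
#' @param reference Gallery [embedding_set()].
#' @param probes Probe [embedding_set()].
#' @param k Neighborhood size (`1 <= k <=` gallery size). Reference
#'   protocol values: 5, 11, 30.
#' @return Character vector of predicted labels, one per probe.
#' @export
knn_classify <- function(reference, probes, k = 5L) {
  stopifnot(inherits(reference, "embedding_set"),
            inherits(probes, "embedding_set"))
  if (ncol(reference$embeddings) != ncol(probes$embeddings)) {
    stop("embedding dimensionality mismatch: gallery ",
         ncol(reference$embeddings), ", probes ", ncol(probes$embeddings))
  }
  nref <- nrow(reference$embeddings)
  stopifnot(k >= 1, k <= nref)
  d2 <- .cross_dist2(probes$embeddings, reference$embeddings)
  vapply(seq_len(nrow(d2)), function(i) {
    ord <- order(d2[i, ])[seq_len(k)]
    labs <- reference$labels[ord]
    votes <- table(labs)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      inv <- vapply(top, function(l) {
        sum(1 / pmax(sqrt(d2[i, ord[labs == l]]), 1e-12))
      }, 0)
      top <- top[inv == max(inv)]
      top <- sort(top)[1]
    }
    top
  }, "")
}

#' Classification report: accuracy, per-class precision/recall/F1, confusion
#'
#' Precision, recall and F1 are computed per class from the confusion
#' matrix and macro-averaged; classes with no predicted (or true) samples
#' contribute 0 to the affected ratio.
#'
#' @param truth True labels.
#' @param predicted Predicted labels (must be drawn from the true label
#'   set's universe).
#' @param labels Optional label universe (default: union of truth levels).
#' @return List with `accuracy`, `precision`, `recall`, `f1`
#'   (macro averages), per-class data frame `by_class`, and the
#'   `confusion` matrix (rows = truth).
#' @export
classification_report <- function(truth, predicted, labels = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted lengths differ")
  }
  if (is.null(labels)) labels <- sort(unique(truth))
  unseen <- setdiff(unique(predicted), labels)
  if (length(unseen)) {
    stop("prediction contains label absent from the universe: ", unseen[1])
  }
  tf <- factor(truth, levels = labels)
  pf <- factor(predicted, levels = labels)
  confusion <- table(truth = tf, predicted = pf)
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(confusion) > 0
  by_class <- data.frame(label = labels, precision = as.numeric(prec),
                         recall = as.numeric(rec), f1 = as.numeric(f1),
                         support = as.numeric(rowSums(confusion)))
  list(accuracy = mean(truth == predicted),
       precision = mean(prec[present]),
       recall = mean(rec[present]),
       f1 = mean(f1[present]),
       by_class = by_class,
       confusion = confusion)
}

#' Equal error rate of a verification score distribution
#'
#' Sweeps the acceptance threshold over all observed scores (higher score =
#' more similar) and returns the rate where the false-accept rate equals
#' the false-reject rate, linearly interpolating between the two adjacent
#' thresholds that bracket the crossing.
#'
#' @param genuine Scores of same-subject comparisons.
#' @param impostor Scores of different-subject comparisons.
#' @return The equal error rate in `[0, 1]`.
#' @export
eer <- function(genuine, impostor) {
  if (length(genuine) == 0 || length(impostor) == 0) {
    stop("both genuine and impostor score sets must be nonempty")
  }
  thr <- sort(unique(c(genuine, impostor, -Inf, Inf)))
  # accept if score >= threshold
  far <- vapply(thr, function(t) mean(impostor >= t), 0)
  frr <- vapply(thr, function(t) mean(genuine < t), 0)
  diffs <- far - frr
  ix <- which(diffs <= 0)[1] # far decreases, frr increases with threshold
  if (is.na(ix)) return(0.5)
  if (ix == 1 || diffs[ix] == 0) return((far[ix] + frr[ix]) / 2)
  # interpolate between thresholds ix-1 and ix
  d0 <- diffs[ix - 1]; d1 <- diffs[ix]
  w <- d0 / (d0 - d1)
  fa <- far[ix - 1] + w * (far[ix] - far[ix - 1])
  fr <- frr[ix - 1] + w * (frr[ix] - frr[ix - 1])
  (fa + fr) / 2
}

#' Genuine/impostor scores from embedding distances
#'
#' Scores all probe pairs (or probe-vs-gallery pairs) by negative Euclidean
#' embedding distance; genuine = same subject.
#'
#' @param probes An [embedding_set()].
#' @param gallery Optional gallery set; default scores probe pairs.
#' @return List with `genuine` and `impostor` score vectors.
#' @export
verification_scores <- function(probes, gallery = NULL) {
  if (is.null(gallery)) {
    d <- sqrt(.cross_dist2(probes$embeddings, probes$embeddings))
    same <- outer(probes$labels, probes$labels, "==")
    ut <- upper.tri(d)
    list(genuine = -d[ut & same], impostor = -d[ut & !same])
  } else {
    d <- sqrt(.cross_dist2(probes$embeddings, gallery$embeddings))
    same <- outer(probes$labels, gallery$labels, "==")
    list(genuine = -d[same], impostor = -d[!same])
  }
}

#' Cumulative match characteristic curve
#'
#' Per probe, gallery classes are ranked by their minimum embedding
#' distance; `CMC(r)` is the fraction of probes whose true class ranks
#' within the top `r`. Nondecreasing; reaches 1 at the class count.
#'
#' @param reference Gallery [embedding_set()].
#' @param probes Probe [embedding_set()]; every probe label must exist in
#'   the gallery.
#' @param max_rank Curve length (default: number of gallery classes).
#' @return Numeric vector `cmc[r]`, r = 1..max_rank.
#' @export
cmc <- function(reference, probes, max_rank = NULL) {
  classes <- sort(unique(reference$labels))
  miss <- setdiff(unique(probes$labels), classes)
  if (length(miss)) {
    stop("probe label absent from the gallery: ", miss[1])
  }
  if (is.null(max_rank)) max_rank <- length(classes)
  stopifnot(max_rank >= 1, max_rank <= length(classes))
  d <- sqrt(.cross_dist2(probes$embeddings, reference$embeddings))
  ranks <- vapply(seq_len(nrow(d)), function(i) {
    class_score <- vapply(classes, function(cl) {
      min(d[i, reference$labels == cl])
    }, 0)
    ord <- order(class_score)
    which(classes[ord] == probes$labels[i])[1]
  }, 0L)
  vapply(seq_len(max_rank), function(r) mean(ranks <= r), 0)
}

#' Per-class mean silhouette of an embedding set
#'
#' Standard silhouette with Euclidean distance: for sample i,
#' `s(i) = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean distance to its
#' own class and `b_i` the smallest mean distance to another class.
#' Singleton classes are excluded with a warning.
#'
#' @param es An [embedding_set()] with at least 2 classes.
#' @return Named numeric vector of per-class mean silhouettes, with
#'   attribute `samples` holding the per-sample values.
#' @export
silhouette_by_class <- function(es) {
  labs <- es$labels
  classes <- sort(unique(labs))
  if (length(classes) < 2) stop("silhouette needs at least 2 classes")
  counts <- table(labs)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    warning("excluding singleton class(es): ",
            paste(singletons, collapse = ", "))
    keep <- !labs %in% singletons
    es <- embedding_set(es$embeddings[keep, , drop = FALSE], labs[keep],
                        es$sample_ids[keep])
    labs <- es$labels
    classes <- sort(unique(labs))
    if (length(classes) < 2) stop("fewer than 2 non-singleton classes")
  }
  d <- sqrt(.cross_dist2(es$embeddings, es$embeddings))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labs == labs[i]
    a <- sum(d[i, own]) / (sum(own) - 1) # exclude self
    b <- min(vapply(classes[classes != labs[i]], function(cl) {
      mean(d[i, labs == cl])
    }, 0))
    (b - a) / max(a, b)
  }, 0)
  out <- vapply(classes, function(cl) mean(s[labs == cl]), 0)
  attr(out, "samples") <- s
  out
}

#' Pairwise L2 distance matrix over an embedding set
#'
#' Rows/columns are ordered by subject label then sample id, giving the
#' block structure that makes intra-class cohesion visible.
#'
#' @param es An [embedding_set()].
#' @return Symmetric matrix with zero diagonal; dimnames are sample ids,
#'   attribute `labels` carries the reordered labels.
#' @export
distance_matrix <- function(es) {
  ord <- order(es$labels, es$sample_ids)
  e <- es$embeddings[ord, , drop = FALSE]
  d <- sqrt(.cross_dist2(e, e))
  diag(d) <- 0
  dimnames(d) <- list(es$sample_ids[ord], es$sample_ids[ord])
  attr(d, "labels") <- es$labels[ord]
  d
}

#' PCA of an embedding set
#'
#' Centered principal component analysis of the embedding matrix; reports
#' the projections and the explained-variance ratios (scree values).
#'
#' @param es An [embedding_set()].
#' @param n_components Number of components (`<=` embedding dim); truncated
#'   with a warning if it exceeds the matrix rank.
#' @return List with `projections` (n x n_components), `explained_variance_ratio`
#'   and `labels`.
#' @export
pca_report <- function(es, n_components = 2L) {
  d <- ncol(es$embeddings)
  stopifnot(n_components >= 1, n_components <= d)
  pc <- stats::prcomp(es$embeddings, center = TRUE, scale. = FALSE)
  avail <- ncol(pc$x)
  if (n_components > avail) {
    warning("requested ", n_components, " components but rank is ", avail,
            "; truncating")
    n_components <- avail
  }
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  list(projections = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance_ratio = ratio[seq_len(n_components)],
       all_ratios = ratio,
       labels = es$labels)
}

#' Random-subspace stability of embedding kNN
#'
#' For each requested subspace size, draws `reps` random coordinate subsets
#' of the embedding, runs kNN classification on each, and returns the
#' distribution of macro-F1 scores. Deterministic under `seed`.
#'
#' @param reference Gallery [embedding_set()].
#' @param probes Probe [embedding_set()].
#' @param sizes Subspace sizes (each `<=` embedding dim).
#' @param reps Draws per size.
#' @param k kNN neighborhood size.
#' @param seed Integer seed.
#' @return Data frame with columns `size`, `rep`, `f1`, `accuracy`.
#' @export
subspace_stability <- function(reference, probes, sizes, reps = 20L,
                               k = 5L, seed = 1L) {
  d <- ncol(reference$embeddings)
  stopifnot(all(sizes >= 1), all(sizes <= d))
  rng <- .local_rng(seed)
  out <- list()
  for (s in sizes) {
    for (r in seq_len(reps)) {
      coords <- if (s == d) seq_len(d) else rng$sample(seq_len(d), s)
      ref_s <- embedding_set(reference$embeddings[, coords, drop = FALSE],
                             reference$labels)
      prb_s <- embedding_set(probes$embeddings[, coords, drop = FALSE],
                             probes$labels)
      pred <- knn_classify(ref_s, prb_s, k = k)
      rep_ <- classification_report(probes$labels, pred,
                                    labels = sort(unique(c(
                                      reference$labels, probes$labels))))
      out[[length(out) + 1L]] <- data.frame(
        size = s, rep = r, f1 = rep_$f1, accuracy = rep_$accuracy)
    }
  }
  do.call(rbind, out)
}

#' Full biometric evaluation of a trained model on a test set
#'
#' Embeds gallery and probe samples, runs embedding kNN, and reports
#' accuracy, macro precision/recall/F1, EER (negative-embedding-distance
#' verification scores over probe pairs), the CMC curve with its rank-5
#' value, per-class silhouette, and the distance matrix.
#'
#' @param model Trained `st_gait_model`.
#' @param gallery_bundles,probe_bundles Bundle lists (see
#'   [prepare_bundles()]).
#' @param k kNN neighborhood size.
#' @return List of class `eval_report`.
#' @export
evaluate_model <- function(model, gallery_bundles, probe_bundles, k = 5L) {
  gal <- embed_dataset(model, gallery_bundles)
  prb <- embed_dataset(model, probe_bundles)
  pred_knn <- knn_classify(gal, prb, k = k)
  softmax_pred <- vapply(probe_bundles, function(b) {
    predict(model, b)$label
  }, "")
  labels <- sort(unique(c(gal$labels, prb$labels)))
  rep_knn <- classification_report(prb$labels, pred_knn, labels)
  rep_soft <- classification_report(prb$labels, softmax_pred, labels)
  sc <- verification_scores(prb)
  # a probe set of all-singleton classes has no genuine pairs
  eer_value <- if (length(sc$genuine) && length(sc$impostor)) {
    eer(sc$genuine, sc$impostor)
  } else NA_real_
  cmc_curve <- cmc(gal, prb)
  # silhouette needs >= 2 classes with >= 2 members; report NA otherwise
  cnt <- table(prb$labels)
  sil <- if (sum(cnt >= 2) >= 2) {
    silhouette_by_class(prb)
  } else NA_real_
  structure(list(
    knn = rep_knn,
    softmax = rep_soft,
    eer = eer_value,
    cmc = cmc_curve,
    cmc_rank5 = cmc_curve[min(5, length(cmc_curve))],
    silhouette = sil,
    distance_matrix = distance_matrix(prb),
    embeddings = list(gallery = gal, probes = prb),
    k = k
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Gait recognition evaluation (k =", x$k, "):\n")
  cat(sprintf("  softmax accuracy: %.3f\n", x$softmax$accuracy))
  cat(sprintf("  kNN accuracy:     %.3f  (P %.3f / R %.3f / F1 %.3f)\n",
              x$knn$accuracy, x$knn$precision, x$knn$recall, x$knn$f1))
  cat(sprintf("  EER: %.4f   CMC rank-5: %.3f   mean silhouette: %.3f\n",
              x$eer, x$cmc_rank5, mean(x$silhouette)))
  invisible(x)
}

#' Zero-shot evaluation: probing subjects the model never saw
#'
#' Embeds the observed training samples and the unseen subjects' enrollment
#' references as a combined gallery, then classifies observed-test and
#' unseen-probe samples by embedding kNN. Reports the overall mixture
#' accuracy and an unseen-only report. Errors out if any unseen sample id
#' appears in the training log.
#'
#' @param model Model trained only on `split$observed_train`.
#' @param bundles Named bundle list covering all split ids.
#' @param sids Labels parallel to `bundles`.
#' @param split A [zero_shot_split()] result.
#' @param k kNN neighborhood size.
#' @param trained_ids Sample ids the model was trained on (for the leakage
#'   check); defaults to `split$observed_train`.
#' @return List with `overall` and `unseen_only` classification reports and
#'   `unseen_silhouette`.
#' @export
zero_shot_evaluate <- function(model, bundles, sids, split, k = 5L,
                               trained_ids = split$observed_train) {
  leak <- intersect(trained_ids,
                    c(split$unseen_reference, split$unseen_probe))
  if (length(leak)) {
    stop("leakage: unseen sample found in the training log: ", leak[1])
  }
  sids <- as.character(sids)
  names(sids) <- names(bundles)
  pick <- function(ids) {
    b <- bundles[ids]
    attr(b, "sids") <- sids[ids]
    b
  }
  gal_ids <- c(split$observed_train, split$unseen_reference)
  prb_ids <- c(split$observed_test, split$unseen_probe)
  gal <- embed_dataset(model, pick(gal_ids), sids[gal_ids])
  prb <- embed_dataset(model, pick(prb_ids), sids[prb_ids])
  pred <- knn_classify(gal, prb, k = k)
  labels <- sort(unique(c(gal$labels, prb$labels)))
  overall <- classification_report(prb$labels, pred, labels)
  is_unseen <- prb$labels %in% split$unseen_sids
  unseen_only <- if (any(is_unseen)) {
    classification_report(prb$labels[is_unseen], pred[is_unseen], labels)
  } else NULL
  unseen_all_ids <- c(split$unseen_reference, split$unseen_probe)
  unseen_sil <- if (length(split$unseen_sids) >= 2) {
    silhouette_by_class(
      embed_dataset(model, pick(unseen_all_ids), sids[unseen_all_ids]))
  } else NA_real_
  list(overall = overall, unseen_only = unseen_only,
       unseen_silhouette = unseen_sil,
       gallery = gal, probes = prb, predicted = pred)
}
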