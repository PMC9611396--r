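blob_set <- function(centers, n_each, sd, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_each * ncol(centers), sd = sd), n_each) +
      matrix(centers[i, ], n_each, ncol(centers), byrow = TRUE)
  }))
  embedding_set(X, rep(sprintf("b%d", seq_len(nrow(centers))),
                       each = n_each))
}

test_that("kNN recovers exact matches and separates distant blobs perfectly", {
  ref <- blob_set(rbind(c(0, 0), c(10, 10)), 20, 0.01)
  expect_equal(knn_classify(ref, embedding_set(ref$embeddings[3, ,
                                                              drop = FALSE],
                                               "x"), k = 1),
               ref$labels[3])
  probes <- blob_set(rbind(c(0, 0), c(10, 10)), 15, 0.01, seed = 2)
  pred <- knn_classify(ref, probes, k = 5)
  expect_equal(mean(pred == probes$labels), 1)
  expect_error(knn_classify(ref, embedding_set(matrix(0, 1, 3), "x"), 1),
               "dimensionality mismatch")
})

test_that("classification reports match hand-computed precision and recall on a toy confusion", {
  # 3-class toy with confusion rows (5,1,0 / 0,6,0 / 1,0,5)
  truth <- c(rep("a", 6), rep("b", 6), rep("c", 6))
  pred <- c(rep("a", 5), "b", rep("b", 6), "a", rep("c", 5))
  r <- classification_report(truth, pred)
  expect_equal(unname(r$confusion["a", ]), c(5, 1, 0))
  expect_equal(unname(r$confusion["b", ]), c(0, 6, 0))
  expect_equal(unname(r$confusion["c", ]), c(1, 0, 5))
  expect_equal(r$by_class$precision, c(5 / 6, 6 / 7, 5 / 5))
  expect_equal(r$by_class$recall, c(5 / 6, 6 / 6, 5 / 6))
  expect_equal(r$accuracy, 16 / 18)
  # row sums equal per-class test counts
  expect_equal(unname(rowSums(r$confusion)), c(6, 6, 6))
  # perfect predictions
  rp <- classification_report(truth, truth)
  expect_equal(rp$accuracy, 1)
  expect_equal(rp$f1, 1)
  expect_equal(sum(rp$confusion) - sum(diag(rp$confusion)), 0)
  # degenerate single-class input
  rd <- classification_report(rep("z", 4), rep("z", 4))
  expect_equal(rd$accuracy, 1)
  expect_equal(rd$f1, rd$by_class$f1[1])
  expect_error(classification_report(truth, c(pred[-1], "zzz")),
               "absent from the universe")
})

test_that("EER hits the textbook operating points", {
  expect_equal(eer(c(5, 6, 7), c(1, 2, 3)), 0)
  set.seed(3)
  x <- rnorm(400)
  expect_equal(eer(x, x), 0.5, tolerance = 1e-9)
  # worked threshold-sweep instance
  expect_equal(eer(c(0.9, 0.8, 0.4), c(0.6, 0.3, 0.2)), 1 / 3,
               tolerance = 1e-12)
  expect_error(eer(numeric(0), 1), "nonempty")
})

test_that("CMC curves are nondecreasing, end at one and handle a single class", {
  ref <- blob_set(rbind(c(0, 0)), 5, 0.1)
  prb <- blob_set(rbind(c(0, 0)), 3, 0.1, seed = 5)
  expect_equal(cmc(ref, prb), 1)
  es <- random_embedding_set(40, 4, 4, seed = 8)
  pr <- random_embedding_set(10, 4, 4, seed = 9)
  pr$labels <- sample(unique(es$labels), 10, replace = TRUE)
  curve <- cmc(es, pr)
  expect_true(all(diff(curve) >= 0))
  expect_equal(curve[length(curve)], 1)
  bad <- embedding_set(matrix(0, 1, 4), "nope")
  expect_error(cmc(es, bad), "absent from the gallery")
})

test_that("silhouette separates tight blobs and flags split clusters", {
  good <- blob_set(rbind(c(0, 0), c(20, 20)), 15, 0.05)
  s <- silhouette_by_class(good)
  expect_true(all(s > 0.9))
  # one blob arbitrarily split into two labels scores near zero
  split <- blob_set(rbind(c(0, 0)), 30, 1)
  split$labels <- rep(c("u", "v"), 15)
  s2 <- silhouette_by_class(split)
  expect_true(all(s2 < 0.2))
  single <- embedding_set(rbind(c(9, 9), c(1, 1), c(1.2, 1),
                                c(5, 5), c(5.2, 5)),
                          c("a", "b", "b", "c", "c"))
  expect_warning(sil <- silhouette_by_class(single), "singleton")
  expect_setequal(names(sil), c("b", "c"))
})

test_that("PCA reports rank-2 data exactly and orders ratios", {
  set.seed(12)
  basis <- qr.Q(qr(matrix(rnorm(128 * 2), 128, 2)))
  coords <- matrix(rnorm(40 * 2, sd = c(3, 1)), 40, 2)
  X <- coords %*% t(basis)
  es <- embedding_set(X, rep(c("a", "b"), 20))
  pr <- pca_report(es, 5)
  expect_equal(sum(pr$explained_variance_ratio[1:2]), 1,
               tolerance = 1e-6)
  expect_true(all(diff(pr$all_ratios) <= 1e-9))
})

test_that("subspace stability at full width equals the plain kNN report and is seed-deterministic", {
  ref <- random_embedding_set(60, 16, 3, seed = 20)
  prb <- random_embedding_set(20, 16, 3, seed = 21)
  prb$labels <- sample(unique(ref$labels), 20, replace = TRUE)
  full_pred <- knn_classify(ref, prb, k = 3)
  full_f1 <- classification_report(
    prb$labels, full_pred,
    sort(unique(c(ref$labels, prb$labels))))$f1
  st <- subspace_stability(ref, prb, sizes = 16L, reps = 3L, k = 3L,
                           seed = 5)
  expect_true(all(abs(st$f1 - full_f1) < 1e-12))
  st2 <- subspace_stability(ref, prb, sizes = c(4L, 8L), reps = 5L,
                            k = 3L, seed = 9)
  st3 <- subspace_stability(ref, prb, sizes = c(4L, 8L), reps = 5L,
                            k = 3L, seed = 9)
  expect_identical(st2, st3)
})

test_that("zero-shot evaluation with no held-out subjects equals the standard protocol", {
  ds <- tiny_eval_ds()
  sp <- stratified_split(ds$man, 0.34, seed = 2)
  labels <- sort(unique(ds$sids))
  m <- build_model(build_gait_st_graph(),
                   model_config(3, width_multiplier = 0.125),
                   seed = 1, labels = labels)
  degenerate <- list(observed_train = sp$train, observed_test = sp$test,
                     unseen_reference = character(0),
                     unseen_probe = character(0),
                     unseen_sids = character(0))
  zs <- zero_shot_evaluate(m, ds$bundles, ds$sids, degenerate, k = 3)
  gal <- ds$bundles[sp$train]; attr(gal, "sids") <- ds$sids[sp$train]
  prb <- ds$bundles[sp$test]; attr(prb, "sids") <- ds$sids[sp$test]
  std <- evaluate_model(m, gal, prb, k = 3)
  expect_equal(zs$overall$accuracy, std$knn$accuracy)
  expect_null(zs$unseen_only)
})

test_that("zero-shot evaluation refuses leaked training samples", {
  ds <- tiny_eval_ds()
  sp <- zero_shot_split(ds$man, sort(unique(ds$sids))[3], 0.25, seed = 1)
  m <- build_model(build_gait_st_graph(),
                   model_config(2, width_multiplier = 0.125), seed = 1,
                   labels = sort(unique(ds$sids))[1:2])
  expect_error(
    zero_shot_evaluate(m, ds$bundles, ds$sids, sp, k = 3,
                       trained_ids = c(sp$observed_train,
                                       sp$unseen_probe[1])),
    "leakage")
})

test_that("well-separated unseen classes are matched to their own gallery, never the observed one", {
  # embeddings constructed directly: unseen clusters far from observed
  obs <- blob_set(rbind(c(0, 0), c(5, 5)), 10, 0.05)
  uns <- blob_set(rbind(c(40, 40), c(-40, 40)), 10, 0.05, seed = 3)
  uns$labels <- sub("b", "u", uns$labels)
  gal <- embedding_set(rbind(obs$embeddings, uns$embeddings[c(1:5, 11:15), ]),
                       c(obs$labels, uns$labels[c(1:5, 11:15)]))
  prb <- embedding_set(uns$embeddings[c(6:10, 16:20), ],
                       uns$labels[c(6:10, 16:20)])
  pred <- knn_classify(gal, prb, k = 3)
  expect_true(all(pred %in% c("u1", "u2")))
  expect_equal(pred, prb$labels)
})

test_that("trained-model embedding kNN tracks softmax accuracy within 0.02", {
  runs <- lapply(1:3, desk_run)
  knn <- vapply(runs, function(r) r$report$knn$accuracy, 0)
  soft <- vapply(runs, function(r) r$report$softmax$accuracy, 0)
  expect_gte(mean(knn), mean(soft) - 0.02)
})
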