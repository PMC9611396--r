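#' Read and validate a pipeline run configuration
#'
#' Run configs are YAML (or JSON) files with blocks `data`, `split`,
#' `model`, `train`, `knn` and an optional `simulate` block; a run is fully
#' reproducible from its config file alone. Missing required fields raise a
#' validation error naming the field.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`), or a list.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  required <- c("output_dir", "split", "model", "train", "knn")
  for (f in required) {
    if (is.null(cfg[[f]])) stop("config validation: missing field '", f, "'")
  }
  if (is.null(cfg$data_dir) && is.null(cfg$simulate)) {
    stop("config validation: missing field 'data_dir' (or a 'simulate' block)")
  }
  for (f in c("test_fraction", "seed")) {
    if (is.null(cfg$split[[f]])) {
      stop("config validation: missing field 'split.", f, "'")
    }
  }
  if (is.null(cfg$train$epochs)) {
    stop("config validation: missing field 'train.epochs'")
  }
  if (is.null(cfg$knn$k)) stop("config validation: missing field 'knn.k'")
  class(cfg) <- c("run_config", "list")
  cfg
}

.stage <- function(name, quiet, expr) {
  t0 <- Sys.time()
  if (!quiet) message("[", name, "] starting")
  res <- tryCatch(force(expr), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (!quiet) {
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  res
}

#' Run the full gait-recognition pipeline from a config
#'
#' Stages: simulate (optional) -> preprocess -> split -> train -> embed ->
#' evaluate -> zero-shot (if subjects are held out). Every stage writes its
#' artifacts (manifest, split JSONs, checkpoint, history CSV, embeddings
#' CSV, report JSON, confusion/distance CSVs, scree CSV) under
#' `output_dir`; rerunning with the same config reproduces the reports.
#'
#' @param config Path to a YAML/JSON config or a config list
#'   (see [read_run_config()]).
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the evaluation report, paths and history.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- read_run_config(config)
  out_dir <- cfg$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  manifest <- .stage("data", quiet, {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      noise <- noise_model(
        jitter_sd = sim$jitter_sd %||% 0.05,
        t_range = c(sim$t_min %||% 60L, sim$t_max %||% 140L))
      data_dir <- cfg$data_dir %||% file.path(out_dir, "data")
      simulate_dataset(sim$n_subjects, sim$recordings_per_subject,
                       noise, seed = sim$seed %||% 1L, dir = data_dir)
    } else {
      read_manifest(file.path(cfg$data_dir, "manifest.json"))
    }
  })

  smooth_cfg <- smoothing_config(alpha = cfg$smoothing$alpha %||% 0.5)
  zs_sids <- cfg$split$zero_shot_sids

  split <- .stage("split", quiet, {
    sp <- if (!is.null(zs_sids) && length(zs_sids) > 0) {
      zero_shot_split(manifest, zs_sids, cfg$split$test_fraction,
                      cfg$split$seed)
    } else {
      stratified_split(manifest, cfg$split$test_fraction, cfg$split$seed)
    }
    write_split(sp, file.path(out_dir, "split.json"))
    sp
  })
  train_ids <- split$observed_train %||% split$train
  test_ids <- split$observed_test %||% split$test

  bundles <- .stage("preprocess", quiet, {
    prepare_bundles(manifest, manifest$sample_id, smooth_cfg)
  })
  sids <- attr(bundles, "sids")

  trained <- .stage("train", quiet, {
    train_sids <- sids[train_ids]
    mcfg <- model_config(
      n_classes = length(unique(train_sids)),
      width_multiplier = cfg$model$width_multiplier %||% 1,
      embedding_dim = cfg$model$embedding_dim %||% 128L)
    model <- build_model(build_gait_st_graph(), mcfg,
                         seed = cfg$train$seed %||% 1L,
                         labels = sort(unique(train_sids)))
    tcfg <- train_config(learning_rate = cfg$train$learning_rate,
                         epochs = cfg$train$epochs,
                         seed = cfg$train$seed %||% 1L,
                         profile = cfg$train$profile %||% "reduced")
    tb <- bundles[train_ids]
    res <- train_model(model, tb, train_sids, tcfg, quiet = quiet)
    utils::write.csv(res$history,
                     file.path(out_dir, "train_history.csv"),
                     row.names = FALSE)
    save_checkpoint(res$model, file.path(out_dir, "model_final.rds"))
    res
  })

  report <- .stage("evaluate", quiet, {
    gal <- bundles[train_ids]
    attr(gal, "sids") <- sids[train_ids]
    prb <- bundles[test_ids]
    attr(prb, "sids") <- sids[test_ids]
    rep <- evaluate_model(trained$model, gal, prb, k = cfg$knn$k)
    es <- rep$embeddings$probes
    utils::write.csv(
      data.frame(sample_id = es$sample_ids, sid = es$labels,
                 es$embeddings),
      file.path(out_dir, "embeddings_test.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame.matrix(rep$knn$confusion),
                     file.path(out_dir, "confusion_knn.csv"))
    utils::write.csv(rep$distance_matrix,
                     file.path(out_dir, "distance_matrix.csv"))
    pca <- pca_report(es, n_components = min(3L, ncol(es$embeddings)))
    utils::write.csv(
      data.frame(component = seq_along(pca$all_ratios),
                 explained_variance_ratio = pca$all_ratios),
      file.path(out_dir, "scree.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(softmax_accuracy = rep$softmax$accuracy,
           knn_accuracy = rep$knn$accuracy,
           precision = rep$knn$precision, recall = rep$knn$recall,
           f1 = rep$knn$f1, eer = rep$eer, cmc_rank5 = rep$cmc_rank5,
           silhouette = as.list(rep$silhouette), k = cfg$knn$k),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    rep
  })

  zs_report <- NULL
  if (!is.null(zs_sids) && length(zs_sids) > 0) {
    zs_report <- .stage("zero-shot", quiet, {
      zr <- zero_shot_evaluate(trained$model, bundles, sids, split,
                               k = cfg$knn$k)
      jsonlite::write_json(
        list(overall_accuracy = zr$overall$accuracy,
             unseen_only_accuracy = zr$unseen_only$accuracy,
             unseen_mean_silhouette = mean(zr$unseen_silhouette)),
        file.path(out_dir, "zero_shot_report.json"),
        auto_unbox = TRUE, digits = NA)
      zr
    })
  }

  invisible(list(manifest = manifest, split = split, model = trained$model,
                 history = trained$history, report = report,
                 zero_shot = zs_report, output_dir = out_dir))
}
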