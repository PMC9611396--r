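# Shared fixtures. Expensive training runs are executed once per session
# and cached so that several test files can assert on the same run.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# Desk-scale study conditions: 8 subjects x 30 recordings, tracking jitter
# sd 0.05 rad, 60-120 frames, width multiplier 0.25, 30 training epochs,
# 80-20 stratified split.
desk_dataset <- function(seed) {
  cached(paste0("desk_data_", seed), {
    dir <- file.path(tempdir(), paste0("desk_data_", seed))
    man <- simulate_dataset(8, 30,
                            noise_model(jitter_sd = 0.05,
                                        t_range = c(60L, 120L)),
                            seed = seed, dir = dir)
    bundles <- prepare_bundles(man, man$sample_id)
    list(manifest = man, bundles = bundles, sids = attr(bundles, "sids"))
  })
}

desk_run <- function(seed) {
  cached(paste0("desk_run_", seed), {
    ds <- desk_dataset(seed)
    split <- stratified_split(ds$manifest, 0.2, seed = seed)
    labels <- sort(unique(ds$sids))
    model <- build_model(build_gait_st_graph(),
                         model_config(n_classes = length(labels),
                                      width_multiplier = 0.25),
                         seed = seed, labels = labels)
    fit <- train_model(model, ds$bundles[split$train],
                       ds$sids[split$train],
                       train_config(epochs = 30L, seed = seed))
    gal <- ds$bundles[split$train]
    attr(gal, "sids") <- ds$sids[split$train]
    prb <- ds$bundles[split$test]
    attr(prb, "sids") <- ds$sids[split$test]
    report <- evaluate_model(fit$model, gal, prb, k = 5)
    list(data = ds, split = split, model = fit$model,
         history = fit$history, report = report)
  })
}

# Zero-shot conditions: 10 subjects under the same generator settings,
# 2 subjects held entirely out of training.
zero_shot_run <- function(seed) {
  cached(paste0("zs_run_", seed), {
    dir <- file.path(tempdir(), paste0("zs_data_", seed))
    man <- simulate_dataset(10, 30,
                            noise_model(jitter_sd = 0.05,
                                        t_range = c(60L, 120L)),
                            seed = seed + 100L, dir = dir)
    bundles <- prepare_bundles(man, man$sample_id)
    sids <- attr(bundles, "sids")
    all_sids <- sort(unique(sids))
    held <- all_sids[c(9, 10)]
    split <- zero_shot_split(man, held, 0.2, seed = seed)
    obs_labels <- sort(setdiff(all_sids, held))
    model <- build_model(build_gait_st_graph(),
                         model_config(n_classes = length(obs_labels),
                                      width_multiplier = 0.25),
                         seed = seed, labels = obs_labels)
    fit <- train_model(model, bundles[split$observed_train],
                       sids[split$observed_train],
                       train_config(epochs = 30L, seed = seed))
    zs <- zero_shot_evaluate(fit$model, bundles, sids, split, k = 5)
    list(manifest = man, bundles = bundles, sids = sids, split = split,
         model = fit$model, zs = zs, held = held)
  })
}

# A small bundle for fast structural tests.
tiny_bundle <- function(T = 12L, seed = 3L, n_subject_seed = 7L) {
  pop <- sample_population(1, seed = n_subject_seed)
  rec <- simulate_recording(pop[[1]], noise_model(), T = T, seed = seed)
  sequence_to_node_inputs(rec)
}

random_unit_quaternions <- function(n, seed = 1L) {
  set.seed(seed)
  q <- matrix(rnorm(n * 4), n, 4)
  q <- q / sqrt(rowSums(q^2))
  flip <- q[, 4] < 0
  q[flip, ] <- -q[flip, ]
  q
}

# rotation matrix from a unit quaternion (independent oracle path)
quat_to_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Rodrigues rotation of vector v about unit axis u by angle theta
rodrigues <- function(v, u, theta) {
  v * cos(theta) + pracma_cross(u, v) * sin(theta) +
    u * sum(u * v) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# small shared dataset for evaluation-protocol tests
tiny_eval_ds <- function() {
  cached("tiny_eval_ds", {
    dir <- file.path(tempdir(), "tiny_eval")
    man <- simulate_dataset(3, 6, noise_model(t_range = c(30L, 40L)),
                            seed = 9, dir = dir)
    bundles <- prepare_bundles(man, man$sample_id)
    list(man = man, bundles = bundles, sids = attr(bundles, "sids"))
  })
}

# stack two T x J x 3 arrays along the frame axis
abind_rows <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# random labeled embedding cloud
random_embedding_set <- function(n, d, n_classes, seed) {
  set.seed(seed)
  embedding_set(matrix(rnorm(n * d), n, d),
                sample(sprintf("c%02d", seq_len(n_classes)), n,
                       replace = TRUE))
}
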