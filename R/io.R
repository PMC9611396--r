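#' Write a gait recording to CSV
#'
#' On-disk record format: one row per joint per frame with header
#' `sample_id,sid,frame,joint,px,py,pz,qx,qy,qz,qw`; frames are 0-based and
#' joint names follow [kinect_joints()]. The format round-trips losslessly.
#'
#' @param seq A [gait_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(seq, path) {
  stopifnot(inherits(seq, "gait_sequence"))
  joints <- kinect_joints$joint
  tt <- seq$T
  dt <- data.table::data.table(
    sample_id = seq$sample_id,
    sid = seq$sid,
    frame = rep(0:(tt - 1), each = 20L),
    joint = rep(joints, times = tt)
  )
  pos <- matrix(aperm(seq$positions, c(2, 1, 3)), ncol = 3)
  qt <- matrix(aperm(seq$quaternions, c(2, 1, 3)), ncol = 4)
  dt[, c("px", "py", "pz") := list(pos[, 1], pos[, 2], pos[, 3])]
  dt[, c("qx", "qy", "qz", "qw") :=
         list(qt[, 1], qt[, 2], qt[, 3], qt[, 4])]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a gait recording from CSV
#'
#' @param path File in the [write_recording()] format.
#' @return A [gait_sequence()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(
    character = c("sample_id", "sid", "joint")))
  need <- c("sample_id", "sid", "frame", "joint", "px", "py", "pz",
            "qx", "qy", "qz", "qw")
  if (nrow(dt) == 0) stop("empty recording file: ", path)
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("malformed recording ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  }
  joints <- kinect_joints$joint
  unk <- setdiff(unique(dt$joint), joints)
  if (length(unk)) {
    line <- which(dt$joint == unk[1])[1] + 1L # +1 for the header line
    stop("unknown joint name '", unk[1], "' at line ", line, " of ", path)
  }
  frames <- sort(unique(dt$frame))
  tt <- length(frames)
  if (!identical(as.integer(frames), 0:(tt - 1))) {
    stop("non-contiguous or non-monotone frame indices in ", path)
  }
  if (nrow(dt) != tt * 20L) {
    cnt <- table(dt$frame)
    bad <- names(cnt)[cnt != 20L][1]
    stop("frame ", bad, " of ", path, " does not contain all 20 joints")
  }
  data.table::setorder(dt, frame)
  jix <- match(dt$joint, joints)
  pos <- array(NA_real_, c(tt, 20, 3))
  qt <- array(NA_real_, c(tt, 20, 4))
  fix <- dt$frame + 1L
  pos[cbind(fix, jix, 1L)] <- dt$px
  pos[cbind(fix, jix, 2L)] <- dt$py
  pos[cbind(fix, jix, 3L)] <- dt$pz
  qt[cbind(fix, jix, 1L)] <- dt$qx
  qt[cbind(fix, jix, 2L)] <- dt$qy
  qt[cbind(fix, jix, 3L)] <- dt$qz
  qt[cbind(fix, jix, 4L)] <- dt$qw
  if (anyNA(qt)) {
    bad <- which(is.na(qt), arr.ind = TRUE)[1, ]
    stop("frame ", bad[1] - 1L, " of ", path, " is missing joint '",
         joints[bad[2]], "'")
  }
  gait_sequence(dt$sample_id[1], dt$sid[1], pos, qt)
}

#' Write / read a dataset manifest
#'
#' The manifest is a JSON file listing every recording: `sample_id`, `sid`,
#' relative `path` and frame count `T`, plus a format version.
#'
#' @param manifest A data frame with columns `sample_id`, `sid`, `path`, `T`.
#' @param path Manifest file path.
#' @return For the reader, a data frame of class `gait_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("sample_id", "sid", "path", "T") %in% names(manifest)))
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicate sample_ids in manifest")
  }
  jsonlite::write_json(
    list(format = "stgait-manifest-v1",
         records = manifest[, c("sample_id", "sid", "path", "T")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || !startsWith(obj$format, "stgait-manifest")) {
    stop("not a recognized manifest file: ", path)
  }
  m <- as.data.frame(obj$records, stringsAsFactors = FALSE)
  m$sample_id <- as.character(m$sample_id)
  m$sid <- as.character(m$sid)
  attr(m, "dir") <- dirname(path)
  class(m) <- c("gait_manifest", "data.frame")
  m
}

# resolve a manifest record's file path relative to the manifest location
.manifest_path <- function(manifest, sample_id) {
  row <- manifest[manifest$sample_id == sample_id, , drop = FALSE]
  if (nrow(row) != 1) stop("sample_id not in manifest: ", sample_id)
  file.path(attr(manifest, "dir"), row$path)
}

#' Load recordings listed in a manifest
#'
#' @param manifest A manifest from [read_manifest()].
#' @param sample_ids Which samples to load (default: all).
#' @return Named list of [gait_sequence()] objects.
#' @export
load_recordings <- function(manifest, sample_ids = manifest$sample_id) {
  out <- lapply(sample_ids, function(id) read_recording(
    .manifest_path(manifest, id)))
  names(out) <- sample_ids
  out
}

#' Per-subject stratified train/test split
#'
#' Splits every subject's recordings at the given test fraction. The
#' per-subject test count is `floor(fraction * count)`, clamped so both
#' sides keep at least one sample. Deterministic under `seed`.
#'
#' @param manifest Manifest data frame (`sample_id`, `sid`).
#' @param test_fraction Test fraction in (0, 1); the canonical protocols use
#'   0.2 (80-20) and 0.4 (60-40).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test` of sample ids.
#' @export
stratified_split <- function(manifest, test_fraction = 0.2, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  counts <- table(manifest$sid)
  if (any(counts < 2)) {
    stop("every sid needs >= 2 samples to stratify; offending sid: ",
         names(counts)[counts < 2][1])
  }
  rng <- .local_rng(seed)
  train <- character(0)
  test <- character(0)
  for (s in sort(unique(manifest$sid))) {
    ids <- sort(manifest$sample_id[manifest$sid == s])
    n <- length(ids)
    ntest <- min(max(floor(test_fraction * n), 1L), n - 1L)
    pick <- rng$sample(ids, ntest)
    test <- c(test, pick)
    train <- c(train, setdiff(ids, pick))
  }
  list(train = train, test = test)
}

#' Zero-shot split: hold entire subjects out of training
#'
#' Subjects in `zero_shot_sids` contribute nothing to training; their
#' recordings are split at the same fraction into an enrollment reference
#' set and a probe set. The remaining (observed) subjects undergo the usual
#' stratified split.
#'
#' @param manifest Manifest data frame.
#' @param zero_shot_sids Nonempty character vector of held-out subject ids.
#' @param test_fraction Split fraction, as in [stratified_split()].
#' @param seed Integer seed.
#' @return List with `observed_train`, `observed_test`, `unseen_reference`,
#'   `unseen_probe` (sample id vectors) and `unseen_sids`.
#' @export
zero_shot_split <- function(manifest, zero_shot_sids, test_fraction = 0.2,
                            seed = 1L) {
  zero_shot_sids <- as.character(zero_shot_sids)
  if (length(zero_shot_sids) == 0) stop("zero_shot_sids must be nonempty")
  absent <- setdiff(zero_shot_sids, manifest$sid)
  if (length(absent)) {
    stop("held-out sid not present in manifest: ", absent[1])
  }
  unseen <- manifest[manifest$sid %in% zero_shot_sids, , drop = FALSE]
  observed <- manifest[!manifest$sid %in% zero_shot_sids, , drop = FALSE]
  obs_split <- stratified_split(observed, test_fraction, seed)
  # the unseen side reuses the global fraction: probes play the role of the
  # test set, references the role of enrollment
  uns_split <- stratified_split(unseen, test_fraction, seed + 1L)
  list(observed_train = obs_split$train,
       observed_test = obs_split$test,
       unseen_reference = uns_split$train,
       unseen_probe = uns_split$test,
       unseen_sids = sort(zero_shot_sids))
}

#' Write / read a split as JSON for exact reruns
#'
#' @param split A list of character vectors of sample ids.
#' @param path File path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(split, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.character)
}

# Isolated RNG helper: runs sampling under a private seed without touching
# the caller's RNG state.
.local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  env$with <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <<- get(".Random.seed", globalenv())
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, globalenv())
      }
    })
    force(expr)
  }
  env$sample <- function(x, size = length(x)) {
    env$with(sample(x, size))
  }
  env$runif <- function(n, min = 0, max = 1) env$with(runif(n, min, max))
  env$rnorm <- function(n, mean = 0, sd = 1) env$with(rnorm(n, mean, sd))
  env$sample_int <- function(n, size = 1) env$with(sample.int(n, size))
  env
}
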