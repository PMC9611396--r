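#' Construct a labeled gait recording
#'
#' One recording of one subject: `T` ordered skeleton frames, each holding
#' all 20 joints with an absolute position (x, y, z, meters, camera space)
#' and a parent-relative orientation quaternion (qx, qy, qz, qw).
#'
#' @param sample_id Unique recording identifier (string).
#' @param sid Subject identification label (string); the class target.
#' @param positions Numeric array `T x 20 x 3`, joint order as in
#'   [kinect_joints()].
#' @param quaternions Numeric array `T x 20 x 4`, same joint order.
#' @return An object of class `gait_sequence` with fields `sample_id`,
#'   `sid`, `positions`, `quaternions` and `T`.
#' @export
gait_sequence <- function(sample_id, sid, positions, quaternions) {
  joints <- kinect_joints$joint
  if (length(dim(quaternions)) != 3 || dim(quaternions)[2] != 20L ||
      dim(quaternions)[3] != 4L) {
    stop("quaternions must be a T x 20 x 4 array")
  }
  if (length(dim(positions)) != 3 || dim(positions)[2] != 20L ||
      dim(positions)[3] != 3L) {
    stop("positions must be a T x 20 x 3 array")
  }
  tt <- dim(quaternions)[1]
  if (dim(positions)[1] != tt) {
    stop("positions and quaternions disagree on sequence length")
  }
  if (tt < 2) stop("a gait sequence needs at least 2 frames, got ", tt)
  dimnames(positions) <- list(NULL, joints, c("px", "py", "pz"))
  dimnames(quaternions) <- list(NULL, joints, c("qx", "qy", "qz", "qw"))
  structure(
    list(sample_id = as.character(sample_id), sid = as.character(sid),
         positions = positions, quaternions = quaternions, T = tt),
    class = "gait_sequence"
  )
}

#' @export
print.gait_sequence <- function(x, ...) {
  cat("Gait sequence", x$sample_id, "(subject", paste0(x$sid, "):"),
      x$T, "frames x 20 joints\n")
  invisible(x)
}

#' Convert a recording into per-body-part network input tensors
#'
#' The preprocessing chain: positional data are discarded (absolute in
#' tracking space and scale-variant as the subject approaches the sensor);
#' each included joint's quaternion is normalized, converted to its
#' exponential-map 3-vector, and each of the three channels is smoothed by
#' the exponential filter. Channels are assembled per body part in the fixed
#' joint order of [joints_for_vertex()].
#'
#' @param seq A [gait_sequence()].
#' @param graph The [build_gait_st_graph()] graph (determines vertices).
#' @param cfg A [smoothing_config()].
#' @return An object of class `node_input_bundle`: a list with one
#'   `T x J x 3` array per vertex (`spine`, `leg_left`, `leg_right` with
#'   J = 3; `arm_left`, `arm_right` with J = 4) and attribute `T`.
#' @export
sequence_to_node_inputs <- function(seq, graph = build_gait_st_graph(),
                                    cfg = smoothing_config()) {
  stopifnot(inherits(seq, "gait_sequence"))
  tt <- seq$T
  out <- list()
  for (v in graph$vertices) {
    joints <- joints_for_vertex(v)
    arr <- array(0, dim = c(tt, length(joints), 3),
                 dimnames = list(NULL, joints, c("wx", "wy", "wz")))
    for (jix in seq_along(joints)) {
      q <- seq$quaternions[, joints[jix], , drop = TRUE]
      if (tt == 1) q <- matrix(q, nrow = 1)
      if (any(!is.finite(q))) {
        stop("non-finite quaternion for joint ", joints[jix],
             " in sample ", seq$sample_id, " at frame ",
             which(!is.finite(rowSums(q)))[1])
      }
      qn <- normalize_quaternion(q, context = paste0(
        "sample ", seq$sample_id, ", joint ", joints[jix]))
      w <- quaternion_to_axis_angle(qn)$expmap
      arr[, jix, ] <- smooth_sequence(w, cfg)
    }
    out[[v]] <- arr
  }
  structure(out, T = tt, class = "node_input_bundle")
}

# Flatten a bundle vertex to a T x (J*3) matrix, joint-major column order
# (joint1.wx, joint1.wy, joint1.wz, joint2.wx, ...). This is the frame
# vector fed to the network factors.
.flatten_vertex <- function(bundle, vertex) {
  arr <- bundle[[vertex]]
  d <- dim(arr)
  m <- matrix(0, d[1], d[2] * d[3])
  for (j in seq_len(d[2])) {
    m[, (j - 1) * 3 + 1:3] <- arr[, j, ]
  }
  m
}

#' @export
print.node_input_bundle <- function(x, ...) {
  cat("Node input bundle, T =", attr(x, "T"), "\n")
  for (v in names(x)) {
    cat("  ", format(v, width = 10), paste(dim(x[[v]]), collapse = " x "),
        "\n")
  }
  invisible(x)
}
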