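#' Normalize a quaternion to the canonical unit hemisphere
#'
#' Scales `q = (qx, qy, qz, qw)` to unit Euclidean norm and, because `q` and
#' `-q` encode the same rotation, negates all four components when `qw < 0`.
#' Canonicalizing to `qw >= 0` keeps the derived rotation angle in
#' `[0, pi]` and prevents spurious axis flips between consecutive frames.
#'
#' @param q Numeric vector `(qx, qy, qz, qw)`, or a matrix with 4 columns
#'   (one quaternion per row).
#' @param context Optional string (e.g. sample/frame) used in error messages.
#' @return Normalized quaternion(s), same shape as the input.
#' @export
normalize_quaternion <- function(q, context = NULL) {
  if (is.null(dim(q))) {
    q <- matrix(q, nrow = 1)
    drop_out <- TRUE
  } else {
    drop_out <- FALSE
  }
  if (ncol(q) != 4L) stop("quaternions must have 4 components (qx,qy,qz,qw)")
  nrm <- sqrt(rowSums(q^2))
  bad <- which(nrm < 1e-300 | !is.finite(nrm))
  if (length(bad)) {
    stop("zero-norm or non-finite quaternion",
         if (!is.null(context)) paste0(" in ", context),
         " at row ", bad[1])
  }
  q <- q / nrm
  flip <- q[, 4] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  if (drop_out) q[1, ] else q
}

#' Convert unit quaternions to axis-angle (exponential map)
#'
#' For a unit quaternion with `qw >= 0`, the rotation angle is
#' `theta = 2*acos(qw)` and the unit axis is
#' `omega_i = q_i / sqrt(1 - qw^2)`. The exponential map is the 3-vector
#' `theta * omega`. Near the identity rotation (`1 - qw^2 < 1e-12`) the axis
#' is undefined; the conversion then returns a zero angle and zero map
#' rather than a NaN axis.
#'
#' @param qhat Normalized quaternion (vector of 4, or matrix with 4 columns).
#' @return A list with `theta` (angle in radians, in `[0, pi]`), `axis`
#'   (unit 3-vector(s)) and `expmap` (`theta * axis`). For matrix input,
#'   `theta` is a vector and `axis`/`expmap` are matrices with 3 columns.
#' @export
quaternion_to_axis_angle <- function(qhat) {
  if (is.null(dim(qhat))) {
    qhat <- matrix(qhat, nrow = 1)
    drop_out <- TRUE
  } else {
    drop_out <- FALSE
  }
  nrm <- sqrt(rowSums(qhat^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("quaternion_to_axis_angle() expects normalized quaternions; ",
         "max |norm - 1| = ", format(max(abs(nrm - 1))))
  }
  qw <- pmin(1, pmax(-1, qhat[, 4]))
  s2 <- 1 - qw^2
  theta <- 2 * acos(qw)
  axis <- matrix(0, nrow(qhat), 3)
  ok <- s2 >= 1e-12
  axis[ok, ] <- qhat[ok, 1:3, drop = FALSE] / sqrt(s2[ok])
  theta[!ok] <- 0
  expmap <- axis * theta
  if (drop_out) {
    list(theta = theta[1], axis = axis[1, ], expmap = expmap[1, ])
  } else {
    list(theta = theta, axis = axis, expmap = expmap)
  }
}

#' Convert an exponential-map vector back to a quaternion
#'
#' Inverse of [quaternion_to_axis_angle()]: `qw = cos(theta/2)`, vector part
#' `sin(theta/2) * omega`, where `theta` is the norm of the input.
#'
#' @param w Numeric 3-vector (or matrix with 3 columns).
#' @return Quaternion(s) `(qx, qy, qz, qw)` on the canonical hemisphere.
#' @export
axis_angle_to_quaternion <- function(w) {
  if (is.null(dim(w))) {
    w <- matrix(w, nrow = 1)
    drop_out <- TRUE
  } else {
    drop_out <- FALSE
  }
  theta <- sqrt(rowSums(w^2))
  q <- matrix(0, nrow(w), 4)
  q[, 4] <- cos(theta / 2)
  ok <- theta > 1e-300
  q[ok, 1:3] <- w[ok, , drop = FALSE] / theta[ok] * sin(theta[ok] / 2)
  if (drop_out) q[1, ] else q
}

#' Exponential smoothing configuration
#'
#' The sensor-jitter filter is the printed first-order recursion
#' `S_t = alpha * y_(t-1) + (1 - alpha) * S_(t-1)` with `S_1` initialized to
#' the first observation. Note the one-frame lag on `y`: the filter as
#' printed reads the previous observation. `lagged = FALSE` switches to the
#' common zero-lag variant `S_t = alpha * y_t + (1 - alpha) * S_(t-1)`.
#'
#' @param alpha Smoothing constant in `[0, 1]`. The default 0.5 is a middle
#'   setting; the filter constant is meant to be tuned by inspecting
#'   reconstructed skeletons.
#' @param lagged Use the lagged recursion as printed (default `TRUE`).
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(alpha = 0.5, lagged = TRUE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]")
  }
  structure(list(alpha = alpha, lagged = isTRUE(lagged)),
            class = "smoothing_config")
}

#' Exponentially smooth a scalar sequence
#'
#' Applies the recursion of [smoothing_config()] to one channel. `S_1` is the
#' first observation, so constant signals are fixed points for every alpha.
#'
#' @param y Numeric vector (length `T >= 1`), or a matrix smoothed
#'   column-wise.
#' @param cfg A [smoothing_config()].
#' @return Smoothed sequence, same shape as `y`.
#' @export
smooth_sequence <- function(y, cfg = smoothing_config()) {
  stopifnot(inherits(cfg, "smoothing_config"))
  if (is.matrix(y)) {
    return(apply(y, 2, smooth_sequence, cfg = cfg))
  }
  n <- length(y)
  if (n < 1) stop("sequence must have length >= 1")
  a <- cfg$alpha
  s <- numeric(n)
  s[1] <- y[1]
  if (n == 1) return(s)
  if (cfg$lagged) {
    for (t in 2:n) s[t] <- a * y[t - 1] + (1 - a) * s[t - 1]
  } else {
    for (t in 2:n) s[t] <- a * y[t] + (1 - a) * s[t - 1]
  }
  s
}
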