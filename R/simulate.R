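# Synthetic gait generator.
#
# Each subject carries a signature of per-joint single-axis sinusoidal
# rotations: angle_j(t) = baseline + amplitude * sin(2*pi*cadence*t/30 +
# phase) + jitter. Bilateral homologous joints share amplitude, baseline,
# axis and cadence and differ in phase by pi (anti-phase), the structural
# symmetry of the gait cycle. This is deliberately not a biomechanical
# model: it reproduces the three facts that matter for recognition
# (periodicity, bilateral anti-phase, subject-specific parameters) and
# nothing else.

# joint families: one parameter set per family, mirrored to both sides
.sided_families <- c("Hip", "Knee", "Ankle", "Shoulder", "Elbow", "Wrist",
                     "Hand")
.center_families <- c("HipCenter", "Spine", "ShoulderCenter")

.family_of_joint <- function(joint) {
  if (joint %in% .center_families) return(c(joint, "center"))
  side <- if (endsWith(joint, "Left")) "left" else "right"
  c(sub("(Left|Right)$", "", joint), side)
}

#' Draw a population of subject gait signatures
#'
#' Signatures are drawn from documented distributions: per-family amplitude
#' U(0.15, 0.8) rad, baseline U(-0.25, 0.25) rad, uniform random unit
#' rotation axis, phase U(0, 2*pi) with the right side anti-phase (+pi)
#' to the left, cadence U(0.6, 1.4) Hz, and per-subject limb segment
#' lengths (for the positional channel consumed by the handcrafted
#' baseline). Deterministic under `seed`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed.
#' @return List of `subject_signature` objects with unique `sid`s.
#' @export
sample_population <- function(n_subjects, seed = 1L) {
  stopifnot(n_subjects >= 1)
  rng <- .local_rng(seed)
  lapply(seq_len(n_subjects), function(i) {
    fams <- c(.center_families, .sided_families)
    pars <- lapply(fams, function(f) {
      list(
        amplitude = rng$runif(1, 0.15, 0.8),
        baseline = rng$runif(1, -0.25, 0.25),
        phase = rng$runif(1, 0, 2 * pi),
        axis = { a <- rng$rnorm(3); a / sqrt(sum(a^2)) }
      )
    })
    names(pars) <- fams
    # spine joints barely rotate during walking; damp their amplitude
    for (f in .center_families) pars[[f]]$amplitude <- pars[[f]]$amplitude * 0.3
    bones <- list(
      femur = rng$runif(1, 0.38, 0.50),
      tibia = rng$runif(1, 0.34, 0.46),
      humerus = rng$runif(1, 0.26, 0.36),
      forearm = rng$runif(1, 0.22, 0.30),
      hand = rng$runif(1, 0.16, 0.20),
      foot = rng$runif(1, 0.20, 0.28),
      spine_lower = rng$runif(1, 0.20, 0.28),
      spine_upper = rng$runif(1, 0.18, 0.26),
      neck = rng$runif(1, 0.20, 0.26),
      hip_width = rng$runif(1, 0.14, 0.20),
      shoulder_width = rng$runif(1, 0.16, 0.24)
    )
    structure(
      list(sid = sprintf("S%03d", i),
           joint_params = pars,
           cadence = rng$runif(1, 0.6, 1.4),
           amplitude_jitter = 0.05,
           step_amplitude = rng$runif(1, 0.25, 0.45),
           bones = bones),
      class = "subject_signature"
    )
  })
}

#' Sensor noise model for the simulator
#'
#' @param jitter_sd Per-frame angular jitter standard deviation (radians)
#'   added to every joint angle. Default 0.05, a visually plausible
#'   skeletal-tracking jitter level.
#' @param tempo_range Per-recording multiplicative cadence range.
#' @param t_range Frame-count range `[Tmin, Tmax]` recordings are drawn
#'   from. The default `[60, 140]` at 30 Hz averages about 100 frames and
#'   never exceeds 185.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(jitter_sd = 0.05, tempo_range = c(0.9, 1.1),
                        t_range = c(60L, 140L)) {
  stopifnot(jitter_sd >= 0, length(t_range) == 2, t_range[1] >= 20,
            t_range[2] <= 185, t_range[1] <= t_range[2])
  structure(list(jitter_sd = jitter_sd, tempo_range = tempo_range,
                 t_range = as.integer(t_range)),
            class = "noise_model")
}

#' Per-joint oscillation parameters of a signature
#'
#' Resolves a joint name to its subject-specific oscillation parameters,
#' with the bilateral anti-phase rule applied: right-side joints carry the
#' left phase shifted by pi.
#'
#' @param sig A `subject_signature`.
#' @param joint Joint name (must carry orientation, i.e. not an end joint).
#' @return List with `amplitude`, `baseline`, `phase`, `axis`.
#' @export
signature_joint_params <- function(sig, joint) {
  if (joint %in% .excluded_joints) {
    stop("joint ", joint, " carries no orientation in the simulator")
  }
  fam <- .family_of_joint(joint)
  par <- sig$joint_params[[fam[1]]]
  list(amplitude = par$amplitude, baseline = par$baseline,
       phase = par$phase + if (identical(fam[2], "right")) pi else 0,
       axis = par$axis)
}

# angle track for one joint: baseline + A*sin(2*pi*f*t/30 + phase)
.joint_angle_track <- function(par, cadence, tt, jitter, amp_scale = 1) {
  t0 <- seq_len(tt) - 1
  par$baseline + amp_scale * par$amplitude *
    sin(2 * pi * cadence * t0 / 30 + par$phase) + jitter
}

#' Simulate one gait recording for a subject
#'
#' Every included joint follows its signature sinusoid about its fixed
#' rotation axis (converted to a quaternion); end joints get the identity
#' orientation. Positions trace a simple forward-walking trajectory with
#' subject-specific bone lengths and oscillating ankle separation; only the
#' handcrafted-feature baseline consumes them.
#'
#' @param sig A `subject_signature` from [sample_population()].
#' @param noise A [noise_model()].
#' @param T Frame count; default drawn from the noise model's range.
#' @param seed Integer seed for this recording.
#' @param sample_id Identifier for the recording.
#' @return A [gait_sequence()].
#' @export
simulate_recording <- function(sig, noise = noise_model(), T = NULL,
                               seed = 1L, sample_id = NULL) {
  rng <- .local_rng(seed)
  if (is.null(T)) {
    T <- rng$sample_int(noise$t_range[2] - noise$t_range[1] + 1L) +
      noise$t_range[1] - 1L
  }
  tt <- as.integer(T)
  stopifnot(tt >= 2)
  if (is.null(sample_id)) sample_id <- paste0(sig$sid, "_r", seed)
  tempo <- rng$runif(1, noise$tempo_range[1], noise$tempo_range[2])
  cadence <- sig$cadence * tempo
  amp_scale <- max(0.5, 1 + rng$rnorm(1, 0, sig$amplitude_jitter))

  joints <- kinect_joints$joint
  qt <- array(0, c(tt, 20, 4))
  qt[, , 4] <- 1 # identity everywhere; overwritten for included joints
  angles <- list()
  for (j in joints) {
    if (j %in% .excluded_joints) next
    fam <- .family_of_joint(j)
    par <- sig$joint_params[[fam[1]]]
    phase <- par$phase + if (identical(fam[2], "right")) pi else 0
    jitter <- if (noise$jitter_sd > 0) {
      rng$rnorm(tt, 0, noise$jitter_sd)
    } else 0
    a <- .joint_angle_track(
      list(baseline = par$baseline, amplitude = par$amplitude,
           phase = phase),
      cadence, tt, jitter, amp_scale)
    angles[[j]] <- a
    jix <- match(j, joints)
    qt[, jix, 1:3] <- outer(sin(a / 2), par$axis)
    qt[, jix, 4] <- cos(a / 2)
  }
  pos <- .walking_positions(sig, cadence, tt, angles)
  gait_sequence(sample_id, sig$sid, pos, qt)
}

# Crude forward-walking positional layout: hip center advances toward the
# sensor, static bone offsets give limb segment lengths, and the ankles
# swing fore-aft in anti-phase so ankle-ankle distance oscillates like a
# step. Adequate for anthropometric/dynamic feature extraction; not a
# biomechanical trajectory.
.walking_positions <- function(sig, cadence, tt, angles) {
  b <- sig$bones
  joints <- kinect_joints$joint
  pos <- array(0, c(tt, 20, 3))
  t0 <- seq_len(tt) - 1
  leg <- b$femur + b$tibia
  hipy <- leg * 0.95
  hipz <- 3.5 - 1.2 * t0 / 30 # walking toward the sensor at 1.2 m/s
  phase <- 2 * pi * cadence * t0 / 30
  swing <- sig$step_amplitude * sin(phase)

  set_j <- function(j, x, y, z) {
    jix <- match(j, joints)
    pos[, jix, 1] <<- x; pos[, jix, 2] <<- y; pos[, jix, 3] <<- z
  }
  set_j("HipCenter", 0, hipy, hipz)
  set_j("Spine", 0, hipy + b$spine_lower, hipz)
  set_j("ShoulderCenter", 0, hipy + b$spine_lower + b$spine_upper, hipz)
  set_j("Head", 0, hipy + b$spine_lower + b$spine_upper + b$neck, hipz)
  for (side in c("Left", "Right")) {
    sgn <- if (side == "Left") -1 else 1
    sw <- if (side == "Left") swing else -swing
    set_j(paste0("Hip", side), sgn * b$hip_width / 2, hipy, hipz)
    set_j(paste0("Knee", side), sgn * b$hip_width / 2, hipy - b$femur,
          hipz + sw * 0.5)
    set_j(paste0("Ankle", side), sgn * b$hip_width / 2,
          hipy - b$femur - b$tibia, hipz + sw)
    set_j(paste0("Foot", side), sgn * b$hip_width / 2,
          hipy - b$femur - b$tibia - 0.05, hipz + sw + b$foot * 0.8)
    shy <- hipy + b$spine_lower + b$spine_upper
    set_j(paste0("Shoulder", side), sgn * b$shoulder_width / 2, shy, hipz)
    set_j(paste0("Elbow", side), sgn * b$shoulder_width / 2,
          shy - b$humerus, hipz - sw * 0.4)
    set_j(paste0("Wrist", side), sgn * b$shoulder_width / 2,
          shy - b$humerus - b$forearm, hipz - sw * 0.6)
    set_j(paste0("Hand", side), sgn * b$shoulder_width / 2,
          shy - b$humerus - b$forearm - b$hand, hipz - sw * 0.7)
  }
  pos
}

#' Simulate a full labeled dataset on disk
#'
#' Writes one CSV per recording in the [write_recording()] format plus a
#' JSON manifest. Per-recording frame counts are drawn from the noise
#' model's range. All randomness flows from `seed` through a documented
#' scheme: the population uses `seed`, recording `r` of subject `s` uses an
#' integer derived from `(seed, s, r)`.
#'
#' @param n_subjects Number of subjects.
#' @param recordings_per_subject Recordings per subject (the field-typical
#'   protocol uses about 30).
#' @param noise A [noise_model()].
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed).
#' @param population Optional pre-drawn population from
#'   [sample_population()]; defaults to drawing `n_subjects` under `seed`.
#' @return The manifest (invisibly readable back via [read_manifest()]).
#' @export
simulate_dataset <- function(n_subjects, recordings_per_subject,
                             noise = noise_model(), seed = 1L, dir,
                             population = NULL) {
  stopifnot(n_subjects >= 1, recordings_per_subject >= 1)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  if (is.null(population)) population <- sample_population(n_subjects, seed)
  stopifnot(length(population) >= n_subjects)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sig <- population[[s]]
    for (r in seq_len(recordings_per_subject)) {
      rec_seed <- .derive_seed(seed, s, r)
      sample_id <- sprintf("%s_r%02d", sig$sid, r)
      rec <- simulate_recording(sig, noise, T = NULL, seed = rec_seed,
                                sample_id = sample_id)
      fn <- paste0(sample_id, ".csv")
      write_recording(rec, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, sid = sig$sid, path = fn, T = rec$T,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.json"))
  read_manifest(file.path(dir, "manifest.json"))
}

# deterministic per-recording seed below 2^31
.derive_seed <- function(seed, subject, recording) {
  as.integer((as.double(seed) * 7919 + subject * 104729 +
                recording * 131) %% 2147483629)
}
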