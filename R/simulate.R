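# Synthetic voxel populations and BOLD time series with known numerosity
# tuning. The simulator is the stand-in for raw scanner data: every
# downstream statistic can be checked against the programmed ground truth.

ROI_VOXEL_COUNTS <- c(
  "MT+_L" = 449L, "MTG_L" = 417L, "OTS_L" = 470L, "MT+_R" = 306L,
  "NPC1_L" = 152L, "NPC2_L" = 86L, "NPC3_L" = 203L, "phAIP_L" = 419L
)

TUNING_CLASSES <- c("action_numerosity", "ball_numerosity",
                    "attention_only", "null")

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-convention double gamma: a positive gamma density (shape 6, scale 1)
#' minus an undershoot gamma (shape 16, scale 1) weighted 1/6, evaluated at
#' `t` seconds and normalised to unit peak.
#'
#' @param t Numeric vector of times in seconds.
#' @param peak_shape,undershoot_shape,undershoot_ratio HRF shape parameters.
#' @return Numeric vector of HRF values.
#' @export
canonical_hrf <- function(t, peak_shape = 6, undershoot_shape = 16,
                          undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_shape) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_shape)
  h[t < 0] <- 0
  h / max(h)
}

#' Convolve per-block-label video boxcars with the HRF on the TR grid
#'
#' One column per requested label; the boxcar is 1 during the video period
#' of every trial carrying that label (the response period carries no
#' signal). Convolution is done at `oversample`-fold resolution and
#' decimated back to the TR grid.
#'
#' @param schedule Run schedule from [build_session()].
#' @param labels Character vector of block labels (defaults to the four
#'   discrimination sub-conditions plus `"fixation"`).
#' @param oversample Integer oversampling factor within a TR.
#' @return Matrix n_TR x length(labels) with label column names.
#' @export
condition_regressors <- function(schedule, labels = c(BLOCK_LABELS, "fixation"),
                                 oversample = 9L) {
  n_tr <- schedule_n_tr(schedule)
  dt <- TR_SECONDS / oversample
  n_fine <- n_tr * oversample
  grid_t <- (seq_len(n_fine) - 1) * dt
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  ev <- schedule$events
  out <- sapply(labels, function(lab) {
    kind <- if (lab == "fixation") "fixation" else "video"
    sel <- ev[ev$block_label == lab & ev$kind == kind, , drop = FALSE]
    box <- numeric(n_fine)
    for (i in seq_len(nrow(sel))) {
      on <- grid_t >= sel$onset[i] & grid_t < sel$onset[i] + sel$duration[i]
      box[on] <- 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_fine)] * dt
    conv[seq(1L, n_fine, by = oversample)]
  })
  colnames(out) <- labels
  out
}

#' Draw a voxel population for one ROI
#'
#' Voxels are assigned one of four tuning classes (action-numerosity
#' selective, ball-numerosity selective, attention-only, null) by sampling
#' the mixture, then per-voxel parameters are drawn: baseline signal,
#' attentional gains for the action and ball tasks, tuning depths (the
#' response difference, in percent of baseline, between the preferred and
#' non-preferred numerosity), a preferred numerosity (1 or 3, equiprobable)
#' and a noise SD. Null voxels have all gains and depths zero; selective
#' voxels have a positive depth for their feature only.
#'
#' @param roi_name ROI label; if one of the eight built-in ROIs,
#'   `n_voxels` defaults to its voxel count.
#' @param mixture Numeric length-4 proportions over
#'   `c("action_numerosity","ball_numerosity","attention_only","null")`;
#'   must sum to 1.
#' @param n_voxels Number of voxels.
#' @param baseline Mean baseline signal (arbitrary scanner units).
#' @param attend_gain Mean attentional gain, percent of baseline, applied to
#'   the attended feature's blocks for non-null voxels.
#' @param delta Mean tuning depth (percent of baseline) for selective voxels.
#' @param noise_sd Voxel noise SD in signal units.
#' @param param_jitter Relative SD of the lognormal jitter applied to
#'   baseline, gains and depths across voxels.
#' @param seed Integer seed.
#' @return List with `roi_name`, `n_voxels`, `mixture` and `voxels`, a data
#'   frame of per-voxel tuning parameters.
#' @export
make_population <- function(roi_name, mixture = c(0.25, 0.25, 0.25, 0.25),
                            n_voxels = NULL, baseline = 100,
                            attend_gain = 0.3, delta = 0.5, noise_sd = 1,
                            param_jitter = 0.2, seed = 1L) {
  mixture <- as.numeric(mixture)
  if (length(mixture) != 4L || any(mixture < 0) ||
      abs(sum(mixture) - 1) > 1e-8)
    stop("`mixture` must be 4 non-negative proportions summing to 1")
  if (is.null(n_voxels)) {
    if (!roi_name %in% names(ROI_VOXEL_COUNTS))
      stop("unknown ROI `", roi_name, "`; supply n_voxels")
    n_voxels <- ROI_VOXEL_COUNTS[[roi_name]]
  }
  local_rng(seed)
  cls <- sample(TUNING_CLASSES, n_voxels, replace = TRUE, prob = mixture)
  jitter <- function(mean, n) mean * exp(stats::rnorm(n, 0, param_jitter))
  vox <- data.frame(
    voxel = seq_len(n_voxels),
    tuning_class = cls,
    baseline = jitter(baseline, n_voxels),
    attend_gain_action = ifelse(cls == "null", 0, jitter(attend_gain, n_voxels)),
    attend_gain_ball = ifelse(cls == "null", 0, jitter(attend_gain, n_voxels)),
    preferred_action_numerosity = sample(c(1L, 3L), n_voxels, replace = TRUE),
    delta_action = ifelse(cls == "action_numerosity", jitter(delta, n_voxels), 0),
    preferred_ball_numerosity = sample(c(1L, 3L), n_voxels, replace = TRUE),
    delta_ball = ifelse(cls == "ball_numerosity", jitter(delta, n_voxels), 0),
    noise_sd = rep(noise_sd, n_voxels),
    stringsAsFactors = FALSE
  )
  list(roi_name = roi_name, n_voxels = n_voxels, mixture = mixture,
       voxels = vox)
}

# Per-voxel response amplitude (percent of baseline) for each of the four
# discrimination sub-conditions, derived from the tuning parameters.
voxel_amplitudes <- function(voxels) {
  num <- c(1L, 3L, 1L, 3L)   # numerosity of each BLOCK_LABELS entry
  amp <- sapply(seq_along(BLOCK_LABELS), function(j) {
    if (j <= 2L) {
      voxels$attend_gain_action +
        ifelse(voxels$preferred_action_numerosity == num[j],
               voxels$delta_action, 0)
    } else {
      voxels$attend_gain_ball +
        ifelse(voxels$preferred_ball_numerosity == num[j],
               voxels$delta_ball, 0)
    }
  })
  amp <- matrix(amp, nrow = nrow(voxels))
  colnames(amp) <- BLOCK_LABELS
  amp
}

#' Simulate a BOLD matrix for one population and one run
#'
#' The noiseless signal of a voxel is its baseline plus, for each
#' discrimination sub-condition, the HRF-convolved video boxcar scaled by
#' the voxel's condition amplitude (attentional gain plus tuning depth when
#' the block's numerosity matches the voxel's preference), expressed in
#' signal units as percent of baseline. Gaussian white noise with the
#' voxel's noise SD is added; AR(1) correlation and a linear drift are
#' available but off by default.
#'
#' @param pop Population from [make_population()].
#' @param schedule Run schedule.
#' @param seed Integer seed for the noise.
#' @param gain Multiplicative scaling of all response amplitudes (subject
#'   responsiveness); `baseline_shift` is added to every voxel's baseline.
#' @param ar1 AR(1) coefficient of the noise (0 = white).
#' @param drift_amplitude Peak-to-peak linear drift in signal units.
#' @return Matrix voxels x TRs.
#' @export
simulate_bold <- function(pop, schedule, seed = 1L, gain = 1,
                          baseline_shift = 0, ar1 = 0, drift_amplitude = 0) {
  reg <- condition_regressors(schedule, labels = BLOCK_LABELS)
  amp <- voxel_amplitudes(pop$voxels) * gain       # voxels x 4, in %
  base <- pop$voxels$baseline + baseline_shift
  n_tr <- nrow(reg)
  # signal units: baseline * amp/100 per condition regressor
  signal <- (amp * base / 100) %*% t(reg) + base   # voxels x TRs
  local_rng(seed)
  n_vox <- nrow(signal)
  noise <- matrix(stats::rnorm(n_vox * n_tr), n_vox, n_tr)
  if (ar1 != 0) {
    for (t in 2:n_tr) noise[, t] <- ar1 * noise[, t - 1] +
        sqrt(1 - ar1^2) * noise[, t]
  }
  noise <- noise * pop$voxels$noise_sd
  if (drift_amplitude != 0) {
    drift <- drift_amplitude * (seq_len(n_tr) - 1) / (n_tr - 1)
    signal <- sweep(signal, 2, drift, `+`)
  }
  signal + noise
}

#' Smooth zero-mean motion nuisance regressors
#'
#' Six series built as random-walk excursions low-pass filtered with a
#' moving average, then demeaned — a crude stand-in for realignment
#' parameters.
#'
#' @param n_tr Number of TRs.
#' @param seed Integer seed.
#' @param amplitude SD of the underlying random-walk increments.
#' @return Matrix n_tr x 6.
#' @export
make_motion_regressors <- function(n_tr, seed = 1L, amplitude = 0.05) {
  stopifnot(n_tr > 0)
  local_rng(seed)
  out <- sapply(1:6, function(i) {
    walk <- cumsum(stats::rnorm(n_tr, 0, amplitude))
    sm <- stats::filter(walk, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- walk[is.na(sm)]
    as.numeric(sm - mean(sm))
  })
  colnames(out) <- paste0("motion", 1:6)
  out
}

#' Simulate a full subject dataset
#'
#' One BOLD matrix and one set of motion regressors per run, with
#' per-subject multiplicative response gain and additive baseline shift.
#'
#' @param pop ROI population.
#' @param session List of 9 run schedules.
#' @param subject_id Integer id; folded into the noise seeds.
#' @param seed Session-level seed.
#' @param subject_gain_sd SD of the lognormal subject gain.
#' @param subject_baseline_sd SD of the subject baseline shift.
#' @inheritParams simulate_bold
#' @return List with `subject_id`, `gain`, `baseline_shift`, and `runs`, a
#'   list of `list(bold, motion, schedule)` per run.
#' @export
simulate_subject <- function(pop, session, subject_id, seed = 1L,
                             subject_gain_sd = 0.2, subject_baseline_sd = 2,
                             ar1 = 0, drift_amplitude = 0) {
  local_rng(seed + 1000003L * (subject_id %% 2048L))
  gain <- exp(stats::rnorm(1, 0, subject_gain_sd))
  shift <- stats::rnorm(1, 0, subject_baseline_sd)
  run_seeds <- sample.int(.Machine$integer.max, length(session))
  runs <- lapply(seq_along(session), function(r) {
    sched <- session[[r]]
    list(
      bold = simulate_bold(pop, sched, seed = run_seeds[r], gain = gain,
                           baseline_shift = shift, ar1 = ar1,
                           drift_amplitude = drift_amplitude),
      motion = make_motion_regressors(schedule_n_tr(sched),
                                      seed = run_seeds[r] %% 1000000L + r),
      schedule = sched
    )
  })
  list(subject_id = subject_id, gain = gain, baseline_shift = shift,
       runs = runs)
}
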