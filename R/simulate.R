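#' Draw the per-subject, per-trial signal parameters of a cohort
#'
#' Realises the hierarchical parameter model of a [cohort_spec()]: subject
#' traits (MLSS speed, cadence, per-parameter multipliers) are drawn once per
#' subject and shared across that subject's trials; trial-level multipliers
#' are drawn independently per trial. Stride-level (within-trial) variation
#' is applied later, inside [simulate_trial()].
#'
#' Amplitude-like parameters scale mildly with the trial speed relative to
#' the subject's MLSS speed, so the faster (`F`) and slower (`S`) trials
#' carry slightly larger and smaller oscillations.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject x trial holding the realised
#'   signal parameters (`amp_vt`, `amp_ml`, `amp_ap`, `impact_vt`,
#'   `noise_*`, `cadence`, `speed`, `duration`, `rpe_end`) and a
#'   deterministic `trial_seed`.
#' @export
make_cohort_params <- function(spec) {
  spec <- validate_cohort_spec(spec)
  set.seed(spec$seed)
  amp_pars <- c("amp_vt", "amp_ml", "amp_ap", "impact_vt",
                "noise_vt", "noise_ml", "noise_ap")
  labels <- spec$trial_labels
  rows <- vector("list", spec$n_subjects * length(labels))
  r <- 0L
  for (s in seq_len(spec$n_subjects)) {
    speed_s <- rnorm(1, spec$speed_mlss_mean, spec$speed_mlss_sd)
    speed_s <- max(speed_s, 1.5)
    cadence_s <- max(rnorm(1, spec$cadence_mean, spec$cadence_sd), 120)
    subj_mult <- 1 + rnorm(length(amp_pars), 0, spec$between_subject_sd)
    names(subj_mult) <- amp_pars
    for (t in seq_along(labels)) {
      lab <- labels[[t]]
      trial_mult <- 1 + rnorm(length(amp_pars), 0, spec$between_trial_sd)
      names(trial_mult) <- amp_pars
      speed <- speed_s * (1 + spec$speed_offsets[[lab]])
      rel <- speed / speed_s
      speed_gain <- 1 + 0.6 * (rel - 1)       # amplitude response to speed
      cadence <- cadence_s * (1 + 0.3 * (rel - 1)) *
        (1 + rnorm(1, 0, spec$between_trial_sd))
      dur <- rnorm(1, spec$duration_mean[[lab]], spec$duration_sd)
      dur <- min(max(dur, spec$duration_min), 45)
      par <- vapply(amp_pars, function(p) {
        max(spec[[p]] * subj_mult[[p]] * trial_mult[[p]] * speed_gain, 0)
      }, numeric(1))
      r <- r + 1L
      rows[[r]] <- tibble::tibble(
        subject_id = sprintf("S%02d", s),
        trial_label = lab,
        speed = speed,
        duration = dur,
        cadence = cadence,
        amp_vt = par[["amp_vt"]], amp_ml = par[["amp_ml"]],
        amp_ap = par[["amp_ap"]], impact_vt = par[["impact_vt"]],
        noise_vt = par[["noise_vt"]], noise_ml = par[["noise_ml"]],
        noise_ap = par[["noise_ap"]],
        jitter_cv = spec$jitter_cv,
        rpe_end = min(max(rnorm(1, spec$rpe_end_mean, spec$rpe_end_sd), 12), 20),
        trial_seed = trial_seed(spec$seed, s, t)
      )
    }
  }
  dplyr::bind_rows(rows)
}

stride_param_names <- c("amp_vt", "amp_ml", "amp_ap", "impact_vt",
                        "noise_vt", "noise_ml", "noise_ap")

check_stride_params <- function(params) {
  vals <- unlist(params[intersect(names(params), stride_param_names)])
  if (length(vals) == 0 || any(!is.finite(vals))) {
    abort("Stride-shape parameters must be finite numbers.")
  }
  invisible(params)
}

# one step of trunk acceleration: gravity offset + low-frequency oscillation
# + decaying impact transient at initial contact; `side` flips the ML lobe
step_waveform <- function(n, sampling_rate, params, side, impact_rise) {
  u <- (seq_len(n) - 1) / n
  t <- (seq_len(n) - 1) / sampling_rate
  impact <- params$impact_vt * (t / impact_rise) * exp(1 - t / impact_rise)
  vt <- 1 + params$amp_vt * cos(2 * pi * u + pi) + impact
  ml <- side * (params$amp_ml * sin(pi * u) + 0.15 * impact)
  ap <- params$amp_ap * sin(2 * pi * u + pi / 4) + 0.25 * impact
  if (params$noise_vt > 0) vt <- vt + rnorm(n, 0, params$noise_vt)
  if (params$noise_ml > 0) ml <- ml + rnorm(n, 0, params$noise_ml)
  if (params$noise_ap > 0) ap <- ap + rnorm(n, 0, params$noise_ap)
  list(vt = vt, ml = ml, ap = ap)
}

#' Simulate one stride (two steps) of tri-axial trunk acceleration
#'
#' The waveform family is a per-step gravity offset plus a low-frequency
#' oscillation plus an exponentially decaying impact transient at each
#' initial contact; the mediolateral lobe mirrors between the left and right
#' step, which is what makes the stride — not the step — the true period of
#' the signal. Units are g, with gravity carried in the vertical axis.
#'
#' @param params List or one-row data frame with `amp_vt`, `amp_ml`,
#'   `amp_ap`, `impact_vt`, `noise_vt`, `noise_ml`, `noise_ap` and
#'   optionally `jitter_cv` (step-duration coefficient of variation,
#'   default 0).
#' @param cadence Steps per minute (> 0).
#' @param sampling_rate Hz (>= 100).
#' @param impact_rise Impact-transient rise time, seconds.
#' @param left_first Whether the first step's ML lobe is positive.
#' @return A tibble `time_s, vt, ml, ap` covering two steps, with attributes
#'   `ic_offsets` (0-based sample indices of the two step onsets) and
#'   `step_samples` (samples per step).
#' @export
#' @examples
#' st <- simulate_stride_waveform(
#'   list(amp_vt = 0.45, amp_ml = 0.35, amp_ap = 0.3, impact_vt = 2.8,
#'        noise_vt = 0, noise_ml = 0, noise_ap = 0),
#'   cadence = 180, sampling_rate = 1125)
#' nrow(st)  # ~ 2 * (60/180) * 1125
simulate_stride_waveform <- function(params, cadence, sampling_rate,
                                     impact_rise = 0.006, left_first = TRUE) {
  if (!is.finite(cadence) || cadence <= 0) abort("`cadence` must be positive.")
  if (!is.finite(sampling_rate) || sampling_rate < 100) {
    abort("`sampling_rate` must be at least 100 Hz.")
  }
  params <- as.list(params)
  check_stride_params(params)
  st <- stride_core(params, cadence, sampling_rate, impact_rise, left_first)
  out <- tibble::tibble(
    time_s = (seq_along(st$vt) - 1) / sampling_rate,
    vt = st$vt, ml = st$ml, ap = st$ap
  )
  attr(out, "ic_offsets") <- c(0L, st$n_steps[[1]])
  attr(out, "step_samples") <- st$n_steps
  out
}

# hot path shared with simulate_trial(): plain vectors, no tibble overhead
stride_core <- function(params, cadence, sampling_rate, impact_rise,
                        left_first) {
  jitter <- params$jitter_cv %||% 0
  step_t <- 60 / cadence
  n_steps <- pmax(round(step_t * (1 + rnorm(2, 0, jitter)) * sampling_rate), 2L)
  sides <- if (left_first) c(1, -1) else c(-1, 1)
  a <- step_waveform(n_steps[[1]], sampling_rate, params, sides[[1]], impact_rise)
  b <- step_waveform(n_steps[[2]], sampling_rate, params, sides[[2]], impact_rise)
  list(vt = c(a$vt, b$vt), ml = c(a$ml, b$ml), ap = c(a$ap, b$ap),
       n_steps = n_steps)
}

#' Simulate one treadmill running trial
#'
#' Concatenates a short standing period (used downstream as the static
#' window for attitude correction), a warmup at reduced speed and cadence,
#' and the main constant-speed run. Fatigue is a linear ramp of the additive
#' parameter shifts in `spec$fatigue_effects`, starting after the
#' non-fatigued window (warmup + 5 min) and reaching full magnitude at the
#' start of the final five minutes, so the fatigued window sits on the
#' plateau. The sensor is tilted by a small random rotation and gravity is
#' carried in the vertical channel, so attitude correction has real work to
#' do. Ground-truth initial-contact times are recorded for validation.
#'
#' @param spec A [cohort_spec()].
#' @param params One row of [make_cohort_params()] (a list or one-row data
#'   frame); its `trial_seed` drives all randomness in this trial.
#' @return A `raw_trial`: list with `accel` (tibble `time_s, vt, ml, ap`,
#'   units g, time 0 = warmup start, negative times = standing),
#'   protocol metadata, `rpe_log` (tibble `minute, rpe`) and
#'   `true_ic_times` (seconds, onset of each impact transient).
#' @export
simulate_trial <- function(spec, params) {
  spec <- validate_cohort_spec(spec)
  params <- as.list(params)
  check_stride_params(params)
  if (!params$trial_label %in% spec$trial_labels) {
    abort(paste0("Unknown trial label: ", params$trial_label))
  }
  dur_s <- params$duration * 60
  warm_s <- spec$warmup_duration * 60
  if (dur_s < warm_s + 600) {
    abort("Trial duration must be at least warmup + 10 min; the NF and FT windows would overlap.")
  }
  set.seed(params$trial_seed)
  fs <- spec$sampling_rate
  n_static <- round(spec$static_lead * fs)
  n_trial <- round(dur_s * fs)

  # fatigue ramp: 0 until the NF window ends, 1 from the FT plateau onward
  ramp_start <- warm_s + 300
  ramp_end <- max(dur_s - 300, ramp_start)
  ramp_at <- function(t) {
    if (ramp_end <= ramp_start) return(as.numeric(t >= ramp_start))
    pmin(pmax((t - ramp_start) / (ramp_end - ramp_start), 0), 1)
  }

  fx <- spec$fatigue_effects
  base <- params[stride_param_names]
  warm_scale <- spec$warmup_speed / params$speed

  vt <- numeric(n_trial); ml <- numeric(n_trial); ap <- numeric(n_trial)
  ic_times <- numeric(0)
  pos <- 0L
  left <- TRUE
  while (pos < n_trial) {
    t_now <- pos / fs
    warm <- t_now < warm_s
    p <- base
    if (warm) {
      for (nm in c("amp_vt", "amp_ml", "amp_ap", "impact_vt")) {
        p[[nm]] <- p[[nm]] * warm_scale
      }
      cad <- params$cadence * 0.92
    } else {
      r <- ramp_at(t_now)
      if (r > 0) {
        for (nm in intersect(names(fx), stride_param_names)) {
          p[[nm]] <- max(p[[nm]] + r * fx[[nm]], 0)
        }
      }
      cad <- params$cadence
    }
    if (spec$within_trial_sd > 0) {
      wob <- 1 + rnorm(4, 0, spec$within_trial_sd)
      p$amp_vt <- p$amp_vt * wob[[1]]; p$amp_ml <- p$amp_ml * wob[[2]]
      p$amp_ap <- p$amp_ap * wob[[3]]; p$impact_vt <- p$impact_vt * wob[[4]]
    }
    p$jitter_cv <- params$jitter_cv
    st <- stride_core(p, cad, fs, spec$impact_rise, left)
    offs <- c(0L, st$n_steps[[1]])
    n_st <- length(st$vt)
    take <- min(n_st, n_trial - pos)
    idx <- seq_len(take)
    vt[pos + idx] <- st$vt[idx]
    ml[pos + idx] <- st$ml[idx]
    ap[pos + idx] <- st$ap[idx]
    ic_times <- c(ic_times, (pos + offs[offs < take]) / fs)
    pos <- pos + n_st
  }

  static <- list(
    vt = 1 + rnorm(n_static, 0, 0.1 * base$noise_vt),
    ml = rnorm(n_static, 0, 0.1 * base$noise_ml),
    ap = rnorm(n_static, 0, 0.1 * base$noise_ap)
  )
  vt <- c(static$vt, vt); ml <- c(static$ml, ml); ap <- c(static$ap, ap)

  # random mounting tilt: the stored signal lives in the (mis-aligned)
  # sensor frame; attitude correction must recover the global frame
  tilt <- rotation_xyz(rnorm(3, 0, spec$tilt_sd_deg * pi / 180))
  sens <- tilt %*% rbind(vt, ml, ap)
  vt <- pmin(pmax(sens[1, ], -16), 16)
  ml <- pmin(pmax(sens[2, ], -16), 16)
  ap <- pmin(pmax(sens[3, ], -16), 16)

  n_total <- n_static + n_trial
  accel <- tibble::tibble(
    time_s = (seq_len(n_total) - 1) / fs - spec$static_lead,
    vt = vt, ml = ml, ap = ap
  )

  structure(list(
    subject_id = params$subject_id %||% "S01",
    trial_label = params$trial_label,
    sampling_rate = fs,
    speed = params$speed,
    duration = params$duration,
    warmup_duration = spec$warmup_duration,
    static_lead = spec$static_lead,
    cadence = params$cadence,
    accel = accel,
    rpe_log = simulate_rpe_log(params$duration, spec$warmup_duration,
                               spec$rpe_start, params$rpe_end),
    true_ic_times = ic_times,
    tilt = tilt
  ), class = "raw_trial")
}

# saturating, monotone RPE trajectory sampled every 5 min plus termination
simulate_rpe_log <- function(duration, warmup, rpe_start, rpe_end) {
  marks <- seq(5, 5 * floor(duration / 5), by = 5)
  if (duration > max(marks) + 1e-9) marks <- c(marks, duration)
  rpe_warm <- rpe_start - 2
  val <- rpe_end - (rpe_end - rpe_warm) *
    exp(-2.5 * pmax(marks - warmup, 0) / max(duration - warmup, 1))
  val <- cummax(pmin(pmax(round(val), 6), 20))
  tibble::tibble(minute = marks, rpe = as.integer(val))
}

# small-angle rotation about the three axes (intrinsic x-y-z composition)
rotation_xyz <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' @export
print.raw_trial <- function(x, ...) {
  cat("<raw_trial> ", x$subject_id, " ", x$trial_label, ": ",
      round(x$duration, 1), " min at ", round(x$speed, 2), " m/s, ",
      x$sampling_rate, " Hz (", nrow(x$accel), " samples)\n", sep = "")
  invisible(x)
}

#' Simulate a full cohort of running trials
#'
#' Draws the hierarchical parameters with [make_cohort_params()] and
#' generates every subject's trials. Reproducible: the same spec (same seed)
#' yields bit-identical signals.
#'
#' @param spec A [cohort_spec()].
#' @param params Optional pre-drawn parameter table (to inspect or modify
#'   the realised parameters before signal synthesis).
#' @return A list of class `gait_cohort`: `spec`, `params`, and `trials`
#'   (list of `raw_trial`, subjects x trials).
#' @export
simulate_cohort <- function(spec, params = NULL) {
  spec <- validate_cohort_spec(spec)
  if (is.null(params)) params <- make_cohort_params(spec)
  trials <- purrr::pmap(params, function(...) {
    simulate_trial(spec, list(...))
  })
  structure(list(spec = spec, params = params, trials = trials),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat("<gait_cohort> ", length(x$trials), " trials (",
      x$spec$n_subjects, " subjects)\n", sep = "")
  invisible(x)
}

#' Simulate subject-condition feature means directly
#'
#' Realises the variance-component model that sits underneath the waveform
#' generator, at the level the statistical layer consumes: one value per
#' subject x trial x fatigue window, `value = mu + subject + trial_constant +
#' shift * [FT] + error`. Useful for calibrating the ANOVA and ICC
#' machinery (type-I error, power, variance-ratio recovery) without signal
#' synthesis.
#'
#' @param n_subjects Number of subjects.
#' @param trial_labels Trial labels (columns of the reliability matrix).
#' @param windows Fatigue windows to emit, default `c("NF", "FT")`.
#' @param mu Grand mean.
#' @param sigma_subject SD of the subject random effect.
#' @param sigma_trial SD of the trial-specific constants (a column effect,
#'   shared by all subjects — this is what absolute-agreement ICC
#'   penalises).
#' @param sigma_error Residual SD per cell.
#' @param fatigue_shift Additive shift applied in the FT window.
#' @param seed Optional seed.
#' @return Tibble `subject_id, trial_label, window, value`.
#' @export
simulate_condition_means <- function(n_subjects,
                                     trial_labels = c("MLSS1", "MLSS2", "F", "S"),
                                     windows = c("NF", "FT"),
                                     mu = 0,
                                     sigma_subject = 1,
                                     sigma_trial = 0,
                                     sigma_error = 1,
                                     fatigue_shift = 0,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subj <- rnorm(n_subjects, 0, sigma_subject)
  trl <- rnorm(length(trial_labels), 0, sigma_trial)
  grid <- tidyr::expand_grid(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    trial_label = trial_labels,
    window = windows
  )
  grid$value <- mu +
    subj[match(grid$subject_id, sprintf("S%03d", seq_len(n_subjects)))] +
    trl[match(grid$trial_label, trial_labels)] +
    fatigue_shift * (grid$window == "FT") +
    rnorm(nrow(grid), 0, sigma_error)
  grid
}

#' Write / read a trial as CSV plus a JSON metadata sidecar
#'
#' The on-disk contract for real recordings: a columnar CSV with header
#' `time_s,ax_g,ay_g,az_g` (x = vertical, y = mediolateral,
#' z = anterior-posterior, units g) and a sidecar `<stem>.json` holding the
#' protocol metadata (subject, label, speed, rate, durations, cadence and
#' the RPE log).
#'
#' @param trial A `raw_trial`.
#' @param dir Output directory (created if needed).
#' @return `write_trial()` returns the CSV path invisibly; `read_trial()`
#'   returns a `raw_trial`.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "raw_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, paste0(trial$subject_id, "_", trial$trial_label))
  df <- trial$accel
  names(df) <- c("time_s", "ax_g", "ay_g", "az_g")
  readr::write_csv(df, paste0(stem, ".csv"))
  meta <- list(
    subject_id = trial$subject_id,
    trial_label = trial$trial_label,
    sampling_rate = trial$sampling_rate,
    speed = trial$speed,
    duration = trial$duration,
    warmup_duration = trial$warmup_duration,
    static_lead = trial$static_lead,
    cadence = trial$cadence,
    rpe_log = as.data.frame(trial$rpe_log)
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(stem, ".csv"))
}

#' @rdname write_trial
#' @param csv_path Path to the CSV written by `write_trial()` (the sidecar
#'   is found by swapping the extension).
#' @export
read_trial <- function(csv_path) {
  json_path <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(csv_path)) abort(paste0("No such trial file: ", csv_path))
  if (!file.exists(json_path)) {
    abort(paste0("Missing metadata sidecar: ", json_path))
  }
  df <- readr::read_csv(csv_path, show_col_types = FALSE)
  stopifnot(identical(names(df), c("time_s", "ax_g", "ay_g", "az_g")))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(
    subject_id = meta$subject_id,
    trial_label = meta$trial_label,
    sampling_rate = meta$sampling_rate,
    speed = meta$speed,
    duration = meta$duration,
    warmup_duration = meta$warmup_duration,
    static_lead = meta$static_lead,
    cadence = meta$cadence,
    accel = tibble::tibble(time_s = df$time_s, vt = df$ax_g,
                           ml = df$ay_g, ap = df$az_g),
    rpe_log = tibble::as_tibble(meta$rpe_log),
    true_ic_times = NULL
  ), class = "raw_trial")
}
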