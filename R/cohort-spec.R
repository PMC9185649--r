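#' Specify a synthetic running cohort
#'
#' A cohort specification fixes the experimental design and the statistical
#' structure of the synthetic trunk-accelerometer signals: one subject runs
#' four constant-speed treadmill trials — two at the speed associated with
#' maximal lactate steady state (`MLSS1`, `MLSS2`), one 5% faster (`F`) and
#' one 5% slower (`S`) — each preceded by a 5 min warmup at 1.92 m/s and a
#' short standing period used for attitude correction. Signal parameters
#' (oscillation amplitudes, impact magnitude, broadband noise, cadence) carry
#' between-subject, between-trial and within-trial (per-stride) variance
#' components, and fatigue is expressed as additive parameter shifts that ramp
#' up over the run and plateau over the final five minutes.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param sampling_rate Accelerometer sampling rate in Hz (default 1125).
#' @param trial_labels Ordered trial labels; the default four-trial design.
#' @param speed_mlss_mean,speed_mlss_sd Between-subject distribution of the
#'   MLSS treadmill speed, m/s.
#' @param speed_offsets Named fractional speed offsets per trial label
#'   (F = +0.05, S = -0.05).
#' @param cadence_mean,cadence_sd Between-subject cadence distribution,
#'   steps/min.
#' @param duration_mean Named mean trial durations per label, minutes
#'   (warmup included); drawn per subject with `duration_sd` and clipped to
#'   `[duration_min, 45]`.
#' @param duration_sd,duration_min Duration spread (min) and shortest
#'   admissible trial (must leave room for non-overlapping 5 min
#'   non-fatigued and fatigued windows).
#' @param warmup_duration Warmup length, minutes.
#' @param warmup_speed Warmup treadmill speed, m/s.
#' @param static_lead Standing time before the warmup, seconds, used as the
#'   static window for attitude correction.
#' @param amp_vt,amp_ml,amp_ap Oscillation amplitudes per axis, g.
#' @param impact_vt Peak amplitude of the vertical impact transient at each
#'   initial contact, g.
#' @param impact_rise Rise time of the impact transient, seconds.
#' @param noise_vt,noise_ml,noise_ap Broadband (white) noise standard
#'   deviations per axis, g; these control signal irregularity and hence
#'   sample entropy.
#' @param jitter_cv Coefficient of variation of step duration (timing
#'   jitter).
#' @param tilt_sd_deg Standard deviation of the random sensor mounting tilt,
#'   degrees, so that attitude correction has real work to do.
#' @param between_subject_sd,between_trial_sd,within_trial_sd Multiplicative
#'   coefficients of variation applied to the amplitude-like parameters at
#'   the subject, trial and stride level respectively.
#' @param fatigue_effects Named additive shifts applied to signal parameters
#'   at full fatigue (reached over the final 5 min). Defaults follow the
#'   directions this class of feature typically shows under running fatigue:
#'   amplitudes up in every axis with the mediolateral axis largest,
#'   vertical irregularity up, mediolateral irregularity down.
#' @param rpe_start,rpe_end_mean,rpe_end_sd Borg 6-20 rating of perceived
#'   exertion: approximate early-run value and the per-trial distribution of
#'   the terminal value.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [simulate_cohort()], [simulate_trial()], [make_cohort_params()]
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 2, sampling_rate = 250,
#'                     duration_mean = c(MLSS1 = 16, MLSS2 = 16, F = 15, S = 16))
#' spec$trial_labels
cohort_spec <- function(n_subjects = 16,
                        sampling_rate = 1125,
                        trial_labels = c("MLSS1", "MLSS2", "F", "S"),
                        speed_mlss_mean = 3.35,
                        speed_mlss_sd = 0.4,
                        speed_offsets = c(MLSS1 = 0, MLSS2 = 0, F = 0.05, S = -0.05),
                        cadence_mean = 180,
                        cadence_sd = 8,
                        duration_mean = c(MLSS1 = 40, MLSS2 = 38, F = 29, S = 42),
                        duration_sd = 5,
                        duration_min = 15,
                        warmup_duration = 5,
                        warmup_speed = 1.92,
                        static_lead = 2,
                        amp_vt = 0.45, amp_ml = 0.35, amp_ap = 0.30,
                        impact_vt = 2.8,
                        impact_rise = 0.006,
                        noise_vt = 0.05, noise_ml = 0.04, noise_ap = 0.04,
                        jitter_cv = 0.02,
                        tilt_sd_deg = 3,
                        between_subject_sd = 0.10,
                        between_trial_sd = 0.04,
                        within_trial_sd = 0.01,
                        fatigue_effects = c(amp_vt = 0.04, amp_ml = 0.10,
                                            amp_ap = 0.05, impact_vt = 0.25,
                                            noise_vt = 0.015, noise_ml = -0.012,
                                            noise_ap = 0),
                        rpe_start = 11,
                        rpe_end_mean = 15.5,
                        rpe_end_sd = 1.6,
                        seed = 1L) {
  spec <- list(
    n_subjects = as.integer(n_subjects),
    sampling_rate = sampling_rate,
    trial_labels = trial_labels,
    speed_mlss_mean = speed_mlss_mean,
    speed_mlss_sd = speed_mlss_sd,
    speed_offsets = speed_offsets,
    cadence_mean = cadence_mean,
    cadence_sd = cadence_sd,
    duration_mean = duration_mean,
    duration_sd = duration_sd,
    duration_min = duration_min,
    warmup_duration = warmup_duration,
    warmup_speed = warmup_speed,
    static_lead = static_lead,
    amp_vt = amp_vt, amp_ml = amp_ml, amp_ap = amp_ap,
    impact_vt = impact_vt,
    impact_rise = impact_rise,
    noise_vt = noise_vt, noise_ml = noise_ml, noise_ap = noise_ap,
    jitter_cv = jitter_cv,
    tilt_sd_deg = tilt_sd_deg,
    between_subject_sd = between_subject_sd,
    between_trial_sd = between_trial_sd,
    within_trial_sd = within_trial_sd,
    fatigue_effects = fatigue_effects,
    rpe_start = rpe_start,
    rpe_end_mean = rpe_end_mean,
    rpe_end_sd = rpe_end_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects < 1) abort("`n_subjects` must be at least 1.")
  if (spec$sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  if (spec$cadence_mean <= 0) abort("`cadence_mean` must be positive.")
  if (anyDuplicated(spec$trial_labels)) abort("`trial_labels` must be unique.")
  if (!all(spec$trial_labels %in% names(spec$speed_offsets))) {
    abort("Every trial label needs a named entry in `speed_offsets`.")
  }
  if (!all(spec$trial_labels %in% names(spec$duration_mean))) {
    abort("Every trial label needs a named entry in `duration_mean`.")
  }
  vc <- c(spec$between_subject_sd, spec$between_trial_sd, spec$within_trial_sd,
          spec$noise_vt, spec$noise_ml, spec$noise_ap, spec$jitter_cv,
          spec$speed_mlss_sd, spec$cadence_sd, spec$duration_sd)
  if (any(!is.finite(vc)) || any(vc < 0)) {
    abort("All variance components must be finite and non-negative.")
  }
  # the F/S speed contract: +/-5 % of each subject's MLSS speed
  off <- spec$speed_offsets
  if ("F" %in% names(off) && abs(off[["F"]] - 0.05) > 1e-12) {
    warn("`F` speed offset differs from the standard +5 %.")
  }
  if (any(spec$duration_mean < spec$duration_min) ||
      any(spec$duration_mean > 45)) {
    abort("`duration_mean` entries must lie in [duration_min, 45] minutes.")
  }
  if (spec$duration_min < spec$warmup_duration + 10) {
    abort("`duration_min` must be at least warmup + 10 min so the NF and FT windows cannot overlap.")
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_subjects, " subjects x ",
      length(x$trial_labels), " trials (",
      paste(x$trial_labels, collapse = ", "), ")\n", sep = "")
  cat("  sampling ", x$sampling_rate, " Hz, MLSS speed ", x$speed_mlss_mean,
      " m/s, cadence ", x$cadence_mean, " spm\n", sep = "")
  cat("  variance CVs: subject ", x$between_subject_sd, ", trial ",
      x$between_trial_sd, ", stride ", x$within_trial_sd, "\n", sep = "")
  invisible(x)
}

#' Build a cohort specification from a YAML or JSON config file
#'
#' The config mirrors the arguments of [cohort_spec()]; fields that are
#' absent keep their defaults. Named numeric maps (`speed_offsets`,
#' `duration_mean`, `fatigue_effects`) are given as mappings.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  named_fields <- c("speed_offsets", "duration_mean", "fatigue_effects")
  for (f in named_fields) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  }
  keep <- intersect(names(cfg), names(formals(cohort_spec)))
  do.call(cohort_spec, cfg[keep])
}

# deterministic per-(subject, trial) seed below 2^31, mixed from the cohort
# seed so trials can be regenerated independently of draw order
trial_seed <- function(seed, subject_idx, trial_idx) {
  as.integer((as.double(seed) * 48271 + subject_idx * 2654435 + trial_idx * 97561) %%
               2147483647)
}
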