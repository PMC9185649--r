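#' Estimate a static attitude correction
#'
#' Finds the rotation that aligns the sensor frame with the global frame,
#' from a window in which the wearer stands still so that the only measured
#' acceleration is gravity. The rotation maps the mean static acceleration
#' vector onto the +VT axis `(1, 0, 0)` and, being a rotation, preserves the
#' norm of every sample — so the resultant is unchanged by correction.
#'
#' @param accel Data frame with columns `time_s, vt, ml, ap` (units g).
#' @param sampling_rate Hz.
#' @param static_window Length-2 numeric, `c(start_s, end_s)` on the
#'   `time_s` axis. Must span at least 0.5 s of low-dynamics signal.
#' @param max_static_sd Largest admissible standard deviation of the
#'   acceleration magnitude inside the window, g; above this the window is
#'   judged dynamic and an error asks for another window.
#' @return List of class `attitude_correction`: `rotation` (3x3 orthonormal,
#'   det +1), `gravity_estimate` (sensor-frame unit gravity, g) and
#'   `static_window`.
#' @export
estimate_attitude_correction <- function(accel, sampling_rate,
                                         static_window,
                                         max_static_sd = 0.05) {
  stopifnot(all(c("time_s", "vt", "ml", "ap") %in% names(accel)))
  in_win <- accel$time_s >= static_window[1] & accel$time_s < static_window[2]
  if (sum(in_win) < 0.5 * sampling_rate) {
    abort("The static window must contain at least 0.5 s of signal.")
  }
  seg <- accel[in_win, c("vt", "ml", "ap")]
  mag <- sqrt(seg$vt^2 + seg$ml^2 + seg$ap^2)
  if (sd(mag) > max_static_sd) {
    abort(paste0("Static window too dynamic (|a| sd = ", signif(sd(mag), 3),
                 " g > ", max_static_sd,
                 " g); choose a window where the wearer stands still."))
  }
  g <- c(mean(seg$vt), mean(seg$ml), mean(seg$ap))
  gn <- sqrt(sum(g^2))
  if (gn < 0.5) {
    abort("Mean static acceleration is far from 1 g; cannot estimate gravity.")
  }
  structure(list(
    rotation = rotation_to_axis(g / gn),
    gravity_estimate = g,
    static_window = static_window
  ), class = "attitude_correction")
}

# minimal rotation taking unit vector a onto e1 = (1, 0, 0) (Rodrigues form)
rotation_to_axis <- function(a) {
  e1 <- c(1, 0, 0)
  v <- c(a[2] * e1[3] - a[3] * e1[2],
         a[3] * e1[1] - a[1] * e1[3],
         a[1] * e1[2] - a[2] * e1[1])
  cth <- sum(a * e1)
  s2 <- sum(v^2)
  if (s2 < 1e-24) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about ML
    return(diag(c(-1, 1, -1)))
  }
  k <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + k + k %*% k * (1 - cth) / s2
}

#' @rdname estimate_attitude_correction
#' @param correction An `attitude_correction`.
#' @return `apply_attitude_correction()` returns `accel` with the `vt, ml,
#'   ap` columns rotated into the global frame.
#' @export
apply_attitude_correction <- function(accel, correction) {
  stopifnot(inherits(correction, "attitude_correction"))
  rot <- correction$rotation %*% t(as.matrix(accel[, c("vt", "ml", "ap")]))
  out <- accel
  out$vt <- rot[1, ]; out$ml <- rot[2, ]; out$ap <- rot[3, ]
  out
}

#' Detect initial contacts in corrected trunk acceleration
#'
#' Each foot strike leaves an impact transient in the centre-of-mass signal.
#' Candidate events are local maxima of the resultant acceleration exceeding
#' a robust threshold (median + `threshold_k` x MAD); candidates closer than
#' half the expected step period to a stronger candidate are suppressed, so
#' exactly one event survives per impact.
#'
#' @param accel Data frame `time_s, vt, ml, ap` in the corrected (global)
#'   frame.
#' @param sampling_rate Hz.
#' @param expected_cadence Steps per minute; sets the minimum inter-event
#'   spacing (0.5 x step period).
#' @param threshold_k MAD multiplier for the detection threshold.
#' @return Strictly increasing integer vector of sample indices (1-based,
#'   into the rows of `accel`), one per detected impact peak.
#' @export
detect_initial_contacts <- function(accel, sampling_rate, expected_cadence = 180,
                                    threshold_k = 2) {
  step_period <- 60 / expected_cadence
  n <- nrow(accel)
  if (n < 10 * step_period * sampling_rate) {
    abort("Signal shorter than 10 expected steps; cannot segment gait.")
  }
  r <- sqrt(accel$vt^2 + accel$ml^2 + accel$ap^2)
  thr <- median(r) + threshold_k * stats::mad(r)
  is_peak <- c(FALSE, r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n],
               FALSE) & r > thr
  cand <- which(is_peak)
  if (length(cand) >= 2) {
    min_gap <- 0.5 * step_period * sampling_rate
    keep <- logical(length(cand))
    taken <- integer(0)
    for (i in order(r[cand], decreasing = TRUE)) {
      if (length(taken) == 0 || all(abs(cand[i] - taken) >= min_gap)) {
        keep[i] <- TRUE
        taken <- c(taken, cand[i])
      }
    }
    cand <- sort(cand[keep])
  }
  if (length(cand) < 10) {
    abort(paste0("Gait segmentation failure: only ", length(cand),
                 " initial contacts found (need at least 10)."))
  }
  cand
}

#' Segment steps and strides and exclude outlying steps
#'
#' A step spans consecutive initial contacts (contralateral feet); a stride
#' spans every second contact (ipsilateral foot), i.e. two steps. Step
#' lengths (in samples) lying more than two standard deviations from the
#' mean are labelled improperly segmented and excluded; the mean and the
#' (population) standard deviation are computed once, over all steps, before
#' any exclusion, and a zero standard deviation excludes nothing. Foot
#' alternation is physical, so strides are paired by global step parity —
#' steps (1,2), (3,4), ... — and a stride is retained only when both of its
#' steps are.
#'
#' @param ic_indices Strictly increasing initial-contact sample indices.
#' @param sampling_rate Hz (kept on the result for downstream timing).
#' @return List of class `gait_events`: `steps` (tibble `step, start, end,
#'   length, retained`; `[start, end)` sample bounds), `strides` (tibble
#'   `stride, start, end, step1, step2, retained`), `excluded_steps`,
#'   `sampling_rate`.
#' @export
segment_and_filter_steps <- function(ic_indices, sampling_rate) {
  ic <- as.integer(ic_indices)
  if (length(ic) < 10) abort("Need at least 10 initial contacts.")
  if (any(diff(ic) <= 0)) abort("`ic_indices` must be strictly increasing.")
  len <- diff(ic)
  mu <- mean(len)
  sd_pop <- sqrt(mean((len - mu)^2))
  retained <- if (sd_pop == 0) rep(TRUE, length(len)) else abs(len - mu) <= 2 * sd_pop
  if (mean(!retained) > 0.5) {
    warn(paste0(sum(!retained), " of ", length(len),
                " steps excluded (> 50 %); segmentation is suspect."))
  }
  steps <- tibble::tibble(
    step = seq_along(len),
    start = ic[-length(ic)],
    end = ic[-1],
    length = len,
    retained = retained
  )
  n_strides <- floor(nrow(steps) / 2)
  if (n_strides < 1) abort("No complete strides.")
  s1 <- 2 * seq_len(n_strides) - 1
  s2 <- s1 + 1
  strides <- tibble::tibble(
    stride = seq_len(n_strides),
    start = steps$start[s1],
    end = steps$end[s2],
    step1 = s1, step2 = s2,
    retained = steps$retained[s1] & steps$retained[s2]
  )
  if (!any(strides$retained)) abort("All strides excluded by the +/-2 SD rule.")
  structure(list(steps = steps, strides = strides,
                 excluded_steps = steps$step[!steps$retained],
                 sampling_rate = sampling_rate),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events> ", nrow(x$steps), " steps (",
      length(x$excluded_steps), " excluded), ",
      sum(x$strides$retained), " retained strides\n", sep = "")
  invisible(x)
}

#' Write a gait-events debug table
#'
#' One row per step: initial-contact index, step length in samples and
#' whether the step survived the exclusion rule. Useful for inspecting
#' segmentation quality.
#'
#' @param events A `gait_events`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_gait_events <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  readr::write_csv(
    tibble::tibble(ic_index = events$steps$start,
                   step_length = events$steps$length,
                   retained = events$steps$retained),
    path)
  invisible(path)
}

#' Group retained strides into consecutive n-stride samples
#'
#' Samples are non-overlapping groups of `n_strides` strides that are
#' consecutive both in index and in time: an excluded step breaks the run,
#' so no sample spans the gap it leaves.
#'
#' @param events A `gait_events`.
#' @param n_strides Strides per sample (default 5).
#' @return Tibble `sample_idx, start, end, stride_first, stride_last,
#'   bounds` where `bounds` is a list column holding the `n_strides + 1`
#'   stride boundary sample indices of each sample.
#' @export
build_stride_samples <- function(events, n_strides = 5) {
  st <- events$strides[events$strides$retained, ]
  if (nrow(st) == 0) {
    return(tibble::tibble(sample_idx = integer(), start = integer(),
                          end = integer(), stride_first = integer(),
                          stride_last = integer(), bounds = list()))
  }
  # contiguous runs: adjacent stride index AND touching sample bounds
  brk <- c(TRUE, diff(st$stride) != 1 | head(st$end, -1) != tail(st$start, -1))
  run_id <- cumsum(brk)
  out <- list()
  idx <- 0L
  for (rid in unique(run_id)) {
    run <- st[run_id == rid, ]
    n_grp <- floor(nrow(run) / n_strides)
    for (g in seq_len(n_grp)) {
      rows <- run[((g - 1) * n_strides + 1):(g * n_strides), ]
      idx <- idx + 1L
      out[[idx]] <- tibble::tibble(
        sample_idx = idx,
        start = rows$start[1],
        end = rows$end[n_strides],
        stride_first = rows$stride[1],
        stride_last = rows$stride[n_strides],
        bounds = list(c(rows$start, rows$end[n_strides]))
      )
    }
  }
  if (idx == 0L) {
    return(tibble::tibble(sample_idx = integer(), start = integer(),
                          end = integer(), stride_first = integer(),
                          stride_last = integer(), bounds = list()))
  }
  dplyr::bind_rows(out)
}

#' Non-fatigued and fatigued window bounds for a trial
#'
#' The non-fatigued (NF) window is the first five minutes at the main speed,
#' i.e. starting when the warmup ends. The fatigued (FT) window is the last
#' complete five-minute block of the trial, aligned to the five-minute RPE
#' schedule: a trial terminated at 38 min has FT = 30-35 min.
#'
#' @param duration Trial duration, minutes (warmup included).
#' @param warmup_duration Warmup, minutes.
#' @return Tibble `window, start_s, end_s` (half-open, trial clock).
#' @export
condition_windows <- function(duration, warmup_duration = 5) {
  nf <- c(warmup_duration, warmup_duration + 5) * 60
  ft_end <- 5 * floor(duration / 5) * 60
  ft <- c(ft_end - 300, ft_end)
  if (ft[1] < nf[2]) {
    abort("Trial too short: the NF and FT windows would overlap.")
  }
  tibble::tibble(window = c("NF", "FT"),
                 start_s = c(nf[1], ft[1]),
                 end_s = c(nf[2], ft[2]))
}

rpe_at_minute <- function(rpe_log, minute) {
  ok <- rpe_log$minute <= minute + 1e-9
  if (!any(ok)) return(NA_integer_)
  rpe_log$rpe[max(which(ok))]
}

#' Extract fatigue-labelled five-stride samples from a trial
#'
#' The full preprocessing chain: attitude-correct the signal using the
#' standing period before the warmup (or a supplied correction), cut the NF
#' and FT windows, detect initial contacts within each window, segment and
#' filter steps, and group retained strides into non-overlapping
#' `n_strides`-stride samples. Each sample carries the RPE value recorded at
#' the end of its window.
#'
#' @param trial A `raw_trial`.
#' @param correction Optional pre-computed [estimate_attitude_correction()]
#'   result; by default one is estimated from the standing lead.
#' @param expected_cadence Steps/min for event detection; defaults to the
#'   trial's recorded cadence, falling back to 180.
#' @param n_strides Strides per sample (default 5).
#' @return Tibble with one row per sample: `subject_id, trial_label, window,
#'   rpe, sample_idx, n_strides, accel` (list column: tibble
#'   `vt, ml, ap, res`) and `stride_bounds` (list column: boundary offsets
#'   within the sample, 1-based, length `n_strides + 1`). The attribute
#'   `"events"` keeps the per-window `gait_events` for diagnostics.
#' @export
extract_condition_windows <- function(trial, correction = NULL,
                                      expected_cadence = NULL,
                                      n_strides = 5) {
  stopifnot(inherits(trial, "raw_trial"))
  if (trial$duration < trial$warmup_duration + 10) {
    abort("Trial duration must be at least warmup + 10 min.")
  }
  fs <- trial$sampling_rate
  if (is.null(correction)) {
    correction <- estimate_attitude_correction(
      trial$accel, fs, static_window = c(-trial$static_lead, 0))
  }
  corrected <- apply_attitude_correction(trial$accel, correction)
  cadence <- expected_cadence %||% trial$cadence %||% 180
  wins <- condition_windows(trial$duration, trial$warmup_duration)
  events <- list()
  rows <- list()
  for (w in seq_len(nrow(wins))) {
    win <- wins[w, ]
    sel <- which(corrected$time_s >= win$start_s & corrected$time_s < win$end_s)
    seg <- corrected[sel, ]
    ic <- detect_initial_contacts(seg, fs, cadence)
    ev <- segment_and_filter_steps(ic, fs)
    events[[win$window]] <- ev
    samples <- build_stride_samples(ev, n_strides = n_strides)
    if (nrow(samples) == 0) next
    rpe <- rpe_at_minute(trial$rpe_log, win$end_s / 60)
    rows[[w]] <- dplyr::mutate(
      samples,
      subject_id = trial$subject_id,
      trial_label = trial$trial_label,
      window = win$window,
      rpe = rpe,
      n_strides = n_strides,
      accel = purrr::map2(.data$start, .data$end, function(a, b) {
        x <- seg[a:(b - 1), c("vt", "ml", "ap")]
        x$res <- sqrt(x$vt^2 + x$ml^2 + x$ap^2)
        x
      }),
      stride_bounds = purrr::map2(.data$bounds, .data$start,
                                  function(b, a) as.integer(b - a + 1L))
    )
  }
  if (length(rows) == 0) {
    abort(paste0("No stride samples could be built for ", trial$subject_id,
                 " ", trial$trial_label, "."))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[, c("subject_id", "trial_label", "window", "rpe", "sample_idx",
                 "n_strides", "accel", "stride_bounds")]
  attr(out, "events") <- events
  out
}
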