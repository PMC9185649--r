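feature_stats <- c("mean", "sd", "median", "p25", "p75", "rms", "max", "min", "se")
feature_axes <- c("vt", "ml", "ap", "res")

#' Names of the 39 per-sample features
#'
#' Nine statistics (mean, standard deviation, median, 25th and 75th
#' percentile, RMS, maximum, minimum, sample entropy) on each of the three
#' axes and the resultant, plus the three RMS ratios (single-axis RMS over
#' resultant RMS). The resultant has no RMS ratio — it would be identically
#' one — which is what fixes the count at 39.
#'
#' @return Character vector of length 39, `<stat>_<axis>` plus `rmsr_*`.
#' @export
feature_names <- function() {
  c(as.vector(outer(feature_stats, feature_axes, paste, sep = "_")),
    paste0("rmsr_", c("vt", "ml", "ap")))
}

#' Basic distributional statistics of one acceleration segment
#'
#' @param x Numeric vector (one axis of a stride sample), length >= 2.
#' @return One-row tibble `mean, sd, median, p25, p75, rms, max, min`.
#'   `sd` is the sample (n-1) standard deviation; percentiles use linear
#'   interpolation between closest ranks (the default quantile type);
#'   `rms = sqrt(mean(x^2))`.
#' @export
#' @examples
#' compute_basic_stats(c(0, 0, 3, 4))  # rms 2.5, mean 1.75
compute_basic_stats <- function(x) {
  tibble::as_tibble(as.list(basic_stats_vec(x)))
}

basic_stats_vec <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("Segment must contain at least 2 non-missing values.")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  c(mean = mean(x), sd = sd(x), median = q[2], p25 = q[1], p75 = q[3],
    rms = sqrt(mean(x^2)), max = max(x), min = min(x))
}

#' Sample entropy of a segment
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of length-`m` templates
#' matching within tolerance under the Chebyshev distance and A counts the
#' pairs still matching at length `m + 1`; self-matches are excluded. The
#' tolerance is the factor `r` multiplied by the segment's (n-1) standard
#' deviation unless an absolute tolerance is given, which makes the statistic
#' invariant to rescaling the segment. When no template pair matches the
#' entropy is undefined and `NA` is returned with a warning of class
#' `fatiguegait_undefined_sampen`, rather than an infinite value.
#'
#' @param x Numeric vector. Values below ~2000 points are acceptable but the
#'   estimate stabilises with longer segments; a warning is raised under
#'   `warn_below` points.
#' @param m Template length (default 2).
#' @param r Tolerance factor relative to `sd(x)` (default 0.2).
#' @param r_absolute Optional absolute tolerance overriding the relative one.
#' @param warn_below Segment length under which a stability warning is
#'   raised; set 0 to silence.
#' @return A single number (dimensionless), or `NA` if undefined.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, r_absolute = NULL,
                           warn_below = 0) {
  x <- as.numeric(x)
  if (anyNA(x)) abort("Sample entropy input must not contain NA.")
  if (m < 1) abort("`m` must be at least 1.")
  if (length(x) < m + 2) abort("Segment too short for the requested `m`.")
  if (warn_below > 0 && length(x) < warn_below) {
    warn(paste0("Sample entropy on ", length(x), " points (< ", warn_below,
                "); the estimate may not have stabilised."))
  }
  tol <- if (is.null(r_absolute)) {
    if (r <= 0) abort("`r` must be positive.")
    r * sd(x)
  } else {
    if (r_absolute < 0) abort("`r_absolute` must be non-negative.")
    r_absolute
  }
  out <- sampen_count(x, as.integer(m), tol)
  if (is.na(out)) {
    warn("Sample entropy undefined (no template matches); returning NA.",
         class = "fatiguegait_undefined_sampen")
  }
  out
}

#' RMS ratios of the three axes to the resultant
#'
#' @param rms_vt,rms_ml,rms_ap,rms_res Single-axis and resultant RMS values
#'   (g). Because the resultant is the per-sample Euclidean norm of the
#'   axes, the three squared ratios sum to one.
#' @return One-row tibble `rmsr_vt, rmsr_ml, rmsr_ap`.
#' @export
#' @examples
#' compute_rmsr(3, 4, 0, 5)  # 0.6, 0.8, 0
compute_rmsr <- function(rms_vt, rms_ml, rms_ap, rms_res) {
  if (!is.finite(rms_res) || rms_res <= 0) {
    abort("`rms_res` must be positive: an all-zero signal has no RMS ratios.")
  }
  tibble::tibble(rmsr_vt = rms_vt / rms_res,
                 rmsr_ml = rms_ml / rms_res,
                 rmsr_ap = rms_ap / rms_res)
}

# linearly resample each stride to a fixed number of points ("gait cycle"
# time base), then concatenate; entropy computed on this base compares
# cycles at like phase regardless of stride-duration drift
normalize_gait_cycles <- function(x, bounds, points_per_stride = 200) {
  k <- length(bounds) - 1
  out <- vector("list", k)
  for (i in seq_len(k)) {
    seg <- x[bounds[i]:(bounds[i + 1] - 1)]
    if (length(seg) < 2) abort("Stride segment shorter than 2 samples.")
    out[[i]] <- approx(seq_along(seg), seg, n = points_per_stride)$y
  }
  unlist(out)
}

#' Extract the 39 features of one stride sample
#'
#' Applies [compute_basic_stats()] and [sample_entropy()] to the VT, ML and
#' AP axes and the resultant, and appends the three RMS ratios. Sample
#' entropy uses a gait-cycle approach by default: each stride is linearly
#' resampled to `points_per_stride` points before concatenation, so the
#' statistic compares cycles at like phase. An axis with zero variance gets
#' an `NA` entropy sentinel (its relative tolerance collapses to zero).
#'
#' @param accel Tibble with columns `vt, ml, ap, res` spanning the sample.
#' @param stride_bounds Integer boundary offsets (1-based, length
#'   `n_strides + 1`) delimiting the strides within `accel`.
#' @param se_m,se_r Sample-entropy template length and tolerance factor.
#' @param points_per_stride Resampling density per stride for the
#'   gait-cycle entropy base (default 200).
#' @param gait_cycle If `FALSE`, entropy is computed on the raw time base
#'   (sensitivity checks).
#' @return One-row tibble with the 39 columns of [feature_names()].
#' @export
extract_features <- function(accel, stride_bounds, se_m = 2, se_r = 0.2,
                             points_per_stride = 200, gait_cycle = TRUE) {
  tibble::as_tibble(as.list(
    feature_vec(accel, stride_bounds, se_m, se_r, points_per_stride,
                gait_cycle)))
}

feature_vec <- function(accel, stride_bounds, se_m, se_r, points_per_stride,
                        gait_cycle) {
  stopifnot(all(c("vt", "ml", "ap", "res") %in% names(accel)))
  out <- numeric(0)
  rms_by_axis <- numeric(0)
  for (ax in feature_axes) {
    x <- accel[[ax]]
    st <- basic_stats_vec(x)
    names(st) <- paste0(names(st), "_", ax)
    se_base <- if (gait_cycle) {
      normalize_gait_cycles(x, stride_bounds, points_per_stride)
    } else {
      x
    }
    se_val <- if (sd(se_base) == 0) {
      warn(paste0("Axis `", ax, "` has zero variance; sample entropy flagged NA."),
           class = "fatiguegait_undefined_sampen")
      NA_real_
    } else {
      suppressWarnings(sample_entropy(se_base, m = se_m, r = se_r))
    }
    st[[paste0("se_", ax)]] <- se_val
    out <- c(out, st)
    rms_by_axis[[ax]] <- st[[paste0("rms_", ax)]]
  }
  if (!is.finite(rms_by_axis[["res"]]) || rms_by_axis[["res"]] <= 0) {
    abort("`rms_res` must be positive: an all-zero signal has no RMS ratios.")
  }
  out[paste0("rmsr_", c("vt", "ml", "ap"))] <-
    rms_by_axis[c("vt", "ml", "ap")] / rms_by_axis[["res"]]
  out[feature_names()]
}

#' Extract features for every stride sample of a table
#'
#' Maps [extract_features()] over the samples produced by
#' [extract_condition_windows()], keeping the sample metadata alongside the
#' 39 feature columns.
#'
#' @param samples Tibble with `subject_id, trial_label, window, rpe,
#'   sample_idx, accel, stride_bounds` (as returned by
#'   [extract_condition_windows()]).
#' @inheritParams extract_features
#' @return Tibble: metadata columns followed by the 39 features, one row
#'   per sample.
#' @export
extract_feature_table <- function(samples, se_m = 2, se_r = 0.2,
                                  points_per_stride = 200, gait_cycle = TRUE) {
  feats <- purrr::map2(samples$accel, samples$stride_bounds, function(a, b) {
    feature_vec(a, b, se_m, se_r, points_per_stride, gait_cycle)
  })
  dplyr::bind_cols(
    samples[, c("subject_id", "trial_label", "window", "rpe", "sample_idx")],
    tibble::as_tibble(do.call(rbind, feats))
  )
}

#' Average features to subject-condition means
#'
#' Produces the cell values the statistical layer consumes: the arithmetic
#' mean of every feature per subject x trial x fatigue window. Undefined
#' sample-entropy sentinels (`NA`) are excluded from that feature's mean and
#' their count is reported via a message.
#'
#' @param features Output of [extract_feature_table()].
#' @return Long tibble `subject_id, trial_label, window, feature, value,
#'   n_samples, n_used` (`n_used` = samples contributing after sentinel
#'   removal).
#' @export
aggregate_condition_means <- function(features) {
  if (nrow(features) == 0) abort("Empty feature table: no samples to average.")
  long <- tidyr::pivot_longer(
    features[, c("subject_id", "trial_label", "window", feature_names())],
    cols = dplyr::all_of(feature_names()),
    names_to = "feature", values_to = "value"
  )
  out <- long |>
    dplyr::group_by(.data$subject_id, .data$trial_label, .data$window,
                    .data$feature) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_used = sum(!is.na(.data$value)),
      value = mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
  dropped <- sum(out$n_samples - out$n_used)
  if (dropped > 0) {
    inform(paste0(dropped, " undefined sample-entropy value(s) excluded from",
                  " condition means."))
  }
  if (any(out$n_used == 0)) {
    bad <- out[out$n_used == 0, ]
    abort(paste0("No usable values for ", bad$feature[1], " in ",
                 bad$subject_id[1], "/", bad$trial_label[1], "/",
                 bad$window[1], "."))
  }
  out[, c("subject_id", "trial_label", "window", "feature", "value",
          "n_samples", "n_used")]
}

#' Write a feature table to CSV
#'
#' @param features Wide feature table from [extract_feature_table()].
#' @param path Output file.
#' @param format `"wide"` (one column per feature) or `"long"`
#'   (`subject,trial,window,sample_idx,feature,value`).
#' @return The path, invisibly.
#' @export
write_feature_table <- function(features, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "long") {
    features <- tidyr::pivot_longer(
      features, cols = dplyr::all_of(feature_names()),
      names_to = "feature", values_to = "value")
  }
  readr::write_csv(features, path)
  invisible(path)
}
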