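#' Plot an ICC reliability report
#'
#' The ICC view mirrors the usual presentation of per-axis reliability:
#' one panel per axis, features on the vertical axis, ICC(2,k) on the
#' horizontal, coloured by fatigue window and shaped by comparison method,
#' with reference lines at the interpretation bin edges (0.5 / 0.75 / 0.9).
#' The p-value view shows the fatigue main-effect p per feature and method
#' on a log scale with the significance level marked.
#'
#' @param object A `reliability_report` from [run_pipeline()].
#' @param type `"icc"` or `"pvalues"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reliability_report <- function(object, type = c("icc", "pvalues"),
                                        ...) {
  type <- match.arg(type)
  if (type == "icc") {
    d <- object$icc
    sp <- split_feature(d$feature)
    d$axis <- factor(sp$axis, levels = c("VT", "ML", "AP", "RES"))
    d$stat <- sp$stat
    ggplot2::ggplot(d, ggplot2::aes(x = .data$icc, y = .data$stat,
                                    colour = .data$window,
                                    shape = .data$method)) +
      ggplot2::geom_vline(xintercept = c(0.5, 0.75, 0.9),
                          linetype = "dotted", colour = "grey50") +
      ggplot2::geom_point(size = 2, na.rm = TRUE) +
      ggplot2::facet_wrap(~axis, nrow = 1) +
      ggplot2::coord_cartesian(xlim = c(0, 1)) +
      ggplot2::labs(x = "ICC(2,k)", y = NULL, colour = "window",
                    shape = "method") +
      ggplot2::theme_minimal()
  } else {
    d <- object$anova
    sp <- split_feature(d$feature)
    d$axis <- factor(sp$axis, levels = c("VT", "ML", "AP", "RES"))
    d$stat <- sp$stat
    alpha <- object$summary$alpha
    ggplot2::ggplot(d, ggplot2::aes(x = .data$p_fatigue, y = .data$stat,
                                    colour = .data$method)) +
      ggplot2::geom_vline(xintercept = alpha, linetype = "dashed") +
      ggplot2::geom_point(size = 2, na.rm = TRUE) +
      ggplot2::scale_x_log10() +
      ggplot2::facet_wrap(~axis, nrow = 1) +
      ggplot2::labs(x = "fatigue main-effect p (log scale)", y = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot a stretch of a trial's tri-axial acceleration
#'
#' @param object A `raw_trial`.
#' @param from,to Time window to show, seconds on the trial clock
#'   (default: the first three seconds of the main run).
#' @param ... Unused.
#' @return A ggplot object with one panel per axis; ground-truth initial
#'   contacts, when present, are marked.
#' @export
autoplot.raw_trial <- function(object,
                               from = object$warmup_duration * 60,
                               to = from + 3, ...) {
  d <- object$accel[object$accel$time_s >= from & object$accel$time_s < to, ]
  long <- tidyr::pivot_longer(d, cols = c("vt", "ml", "ap"),
                              names_to = "axis", values_to = "accel_g")
  long$axis <- factor(toupper(long$axis), levels = c("VT", "ML", "AP"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s,
                                          y = .data$accel_g)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "acceleration (g)") +
    ggplot2::theme_minimal()
  ic <- object$true_ic_times
  if (!is.null(ic)) {
    ic <- ic[ic >= from & ic < to]
    if (length(ic) > 0) {
      p <- p + ggplot2::geom_vline(xintercept = ic, colour = "firebrick",
                                   linetype = "dotted", linewidth = 0.3)
    }
  }
  p
}
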