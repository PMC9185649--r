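#' Interpretation bin of an ICC value
#'
#' Below 0.5 poor, 0.5 to 0.75 moderate, 0.75 to 0.9 good, 0.9 and above
#' excellent.
#'
#' @param icc Numeric vector of ICC values.
#' @return Character vector of categories (`NA` preserved).
#' @export
icc_category <- function(icc) {
  out <- rep(NA_character_, length(icc))
  ok <- !is.na(icc)
  out[ok] <- as.character(cut(icc[ok],
                              breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
                              labels = c("poor", "moderate", "good", "excellent"),
                              right = FALSE))
  out
}

#' ICC(2,k): two-way random effects, absolute agreement, average measures
#'
#' The classical average-measures intraclass correlation for a subjects x
#' trials table of one feature's condition means. From the two-way ANOVA
#' mean squares — MSR between subjects, MSC between trials, MSE residual —
#' \deqn{ICC(2,k) = \frac{MSR - MSE}{MSR + (MSC - MSE)/n}}
#' with `n` subjects. Absolute agreement: a constant added to one trial's
#' column lowers the coefficient. Subjects with any missing cell are dropped
#' first (listwise deletion, reported via a message).
#'
#' @param ratings A numeric matrix (subjects in rows, trials in columns) or
#'   a data frame with columns `subject_id`, `trial_label`, `value`.
#' @return Object of class `icc_2k`: `icc`, `category`, `n_subjects`,
#'   `k_trials`, mean squares, `degenerate` (TRUE when the denominator is
#'   not positive, in which case `icc` is `NA`), `n_dropped`.
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
#' icc_2k(m)$icc  # identical columns with subject spread: 1
icc_2k <- function(ratings) {
  if (is.data.frame(ratings) && !is.matrix(ratings)) {
    stopifnot(all(c("subject_id", "trial_label", "value") %in% names(ratings)))
    wide <- tidyr::pivot_wider(
      ratings[, c("subject_id", "trial_label", "value")],
      names_from = "trial_label", values_from = "value")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$subject_id
  } else {
    m <- as.matrix(ratings)
  }
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " subject(s) dropped from the ICC (missing cells)."))
  }
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3) abort("ICC(2,k) needs at least 3 complete subjects.")
  if (k < 2) abort("ICC(2,k) needs at least 2 trials.")
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (msc - mse) / n
  degenerate <- !is.finite(denom) || denom <= 0
  icc <- if (degenerate) NA_real_ else (msr - mse) / denom
  structure(list(icc = icc, category = icc_category(icc),
                 n_subjects = n, k_trials = k,
                 msr = msr, msc = msc, mse = mse,
                 degenerate = degenerate, n_dropped = n_dropped),
            class = "icc_2k")
}

#' @export
print.icc_2k <- function(x, ...) {
  cat("ICC(2,k) = ",
      if (is.na(x$icc)) "NA (degenerate)" else
        paste0(round(x$icc, 3), " (", x$category, ")"),
      "  [n = ", x$n_subjects, ", k = ", x$k_trials, "]\n", sep = "")
  invisible(x)
}

#' @export
tidy.icc_2k <- function(x, ...) {
  tibble::tibble(icc = x$icc, category = x$category,
                 n_subjects = x$n_subjects, k_trials = x$k_trials,
                 msr = x$msr, msc = x$msc, mse = x$mse,
                 degenerate = x$degenerate)
}

#' @export
glance.icc_2k <- function(x, ...) {
  tibble::tibble(icc = x$icc, category = x$category,
                 n_subjects = x$n_subjects, k_trials = x$k_trials)
}

# parse one aov() Error-strata summary into a tidy effect table, patching
# the 0/0 cases explicit construction can produce (no variation at all ->
# F = 0, p = 1; an exact effect with zero residual -> F = Inf, p = 0)
parse_aov_strata <- function(sm, wanted) {
  # grand scale across all strata: distinguishes a genuinely null term
  # (round-off sums of squares) from a small-but-real one
  grand <- sum(vapply(sm, function(s) sum(s[[1]][, "Sum Sq"]), numeric(1)))
  eps <- 1e-12 * max(grand, .Machine$double.xmin)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid_i <- which(terms == "Residuals")
    df2 <- if (length(resid_i)) tab[resid_i, "Df"] else NA_real_
    ss_res <- if (length(resid_i)) tab[resid_i, "Sum Sq"] else NA_real_
    for (i in which(terms %in% wanted)) {
      f <- tab[i, "F value"]; p <- tab[i, "Pr(>F)"]
      ss_eff <- tab[i, "Sum Sq"]
      if (ss_eff < eps) {
        f <- 0; p <- 1          # no effect variation beyond round-off
      } else if (!is.na(ss_res) && ss_res < eps) {
        f <- Inf; p <- 0        # an exact effect with zero residual
      } else if (!is.finite(f)) {
        f <- NA_real_; p <- NA_real_
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        effect = terms[i], df1 = tab[i, "Df"], df2 = df2,
        statistic = f, p.value = p)
    }
  }
  dplyr::bind_rows(rows)
}

#' Two-way fatigue-state x trial repeated-measures ANOVA for one feature
#'
#' Within-subject ANOVA with factors fatigue state (NF vs FT) and trial —
#' either the two same-speed trials (`MM`: MLSS1 vs MLSS2) or all four
#' (`ALL`) — with subject as the random blocking factor, so each effect is
#' tested against its own subject-by-effect stratum. Subjects missing any
#' cell are dropped listwise; remaining imbalance is an error. When the
#' fatigue main effect is significant at `alpha`, the direction of change is
#' the sign of the FT grand mean minus the NF grand mean.
#'
#' @param cells Data frame `subject_id, trial_label, window, value` for one
#'   feature (one row per cell).
#' @param method `"MM"` (restrict to MLSS1/MLSS2) or `"ALL"`.
#' @param alpha Significance level for reporting the direction (default
#'   0.05).
#' @return Object of class `fatigue_anova`: effect table (`fatigue`,
#'   `trial`, `fatigue:trial` with F, df pair and p), `direction`
#'   (`"+"`, `"-"` or `"none"`), `method`, `n_subjects`.
#' @export
fatigue_trial_anova <- function(cells, method = c("MM", "ALL"), alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(all(c("subject_id", "trial_label", "window", "value") %in%
                  names(cells)))
  d <- cells
  if (method == "MM") d <- d[d$trial_label %in% c("MLSS1", "MLSS2"), ]
  trials <- sort(unique(d$trial_label))
  n_cells <- length(trials) * 2
  counts <- d |>
    dplyr::distinct(.data$subject_id, .data$trial_label, .data$window) |>
    dplyr::count(.data$subject_id, name = "n_cells")
  complete <- counts$subject_id[counts$n_cells == n_cells]
  dropped <- setdiff(counts$subject_id, complete)
  if (length(dropped) > 0) {
    inform(paste0("Dropped incomplete subject(s): ",
                  paste(dropped, collapse = ", ")))
  }
  d <- d[d$subject_id %in% complete, ]
  if (length(complete) < 3) abort("Fewer than 3 complete subjects.")
  bad <- d |>
    dplyr::count(.data$subject_id, .data$trial_label, .data$window) |>
    dplyr::filter(.data$n != 1)
  if (nrow(bad) > 0) {
    abort(paste0("Unbalanced cells for subject(s): ",
                 paste(unique(bad$subject_id), collapse = ", ")))
  }
  d$fatigue <- factor(d$window, levels = c("NF", "FT"))
  d$trial <- factor(d$trial_label, levels = trials)
  d$subject <- factor(d$subject_id)
  fit <- aov(value ~ fatigue * trial + Error(subject / (fatigue * trial)),
             data = d)
  eff <- parse_aov_strata(summary(fit),
                          c("fatigue", "trial", "fatigue:trial"))
  eff <- eff[match(c("fatigue", "trial", "fatigue:trial"), eff$effect), ]
  delta <- mean(d$value[d$fatigue == "FT"]) - mean(d$value[d$fatigue == "NF"])
  p_fat <- eff$p.value[eff$effect == "fatigue"]
  direction <- if (is.finite(p_fat) && p_fat < alpha) {
    if (delta > 0) "+" else if (delta < 0) "-" else "none"
  } else {
    "none"
  }
  structure(list(effects = eff, direction = direction, delta = delta,
                 method = method, alpha = alpha,
                 n_subjects = length(complete), trials = trials),
            class = "fatigue_anova")
}

#' @export
print.fatigue_anova <- function(x, ...) {
  cat("Fatigue-state x trial repeated-measures ANOVA (", x$method, ", n = ",
      x$n_subjects, ")\n", sep = "")
  print(as.data.frame(x$effects), row.names = FALSE)
  cat("direction of change (FT - NF): ", x$direction, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.fatigue_anova <- function(x, ...) {
  out <- x$effects
  out$method <- x$method
  out$direction <- ifelse(out$effect == "fatigue", x$direction, NA_character_)
  out
}

#' @export
glance.fatigue_anova <- function(x, ...) {
  tibble::tibble(method = x$method, n_subjects = x$n_subjects,
                 p_fatigue = x$effects$p.value[x$effects$effect == "fatigue"],
                 p_trial = x$effects$p.value[x$effects$effect == "trial"],
                 p_interaction = x$effects$p.value[x$effects$effect == "fatigue:trial"],
                 direction = x$direction)
}

#' One-way repeated-measures ANOVA of a trial variable
#'
#' Compares a per-trial scalar (trial time, RPE, stride counts, ...) across
#' the trials, with subject as the blocking factor. Subjects with missing
#' trials are dropped listwise and reported.
#'
#' @param values Data frame `subject_id, trial_label, value`.
#' @return One-row tibble `effect, df1, df2, statistic, p.value,
#'   n_subjects`.
#' @export
trial_variable_anova <- function(values) {
  stopifnot(all(c("subject_id", "trial_label", "value") %in% names(values)))
  trials <- sort(unique(values$trial_label))
  if (length(trials) < 2) abort("Need at least 2 trials.")
  counts <- values |> dplyr::count(.data$subject_id)
  complete <- counts$subject_id[counts$n == length(trials)]
  dropped <- setdiff(counts$subject_id, complete)
  if (length(dropped) > 0) {
    inform(paste0("Dropped incomplete subject(s): ",
                  paste(dropped, collapse = ", ")))
  }
  d <- values[values$subject_id %in% complete, ]
  if (length(complete) < 3) abort("Fewer than 3 complete subjects.")
  d$trial <- factor(d$trial_label, levels = trials)
  d$subject <- factor(d$subject_id)
  fit <- aov(value ~ trial + Error(subject / trial), data = d)
  eff <- parse_aov_strata(summary(fit), "trial")
  tibble::tibble(effect = "trial", df1 = eff$df1, df2 = eff$df2,
                 statistic = eff$statistic, p.value = eff$p.value,
                 n_subjects = length(complete))
}

#' Paired t-test between non-fatigued and fatigued RPE
#'
#' Two-sided paired t-test of the Borg ratings at the end of the NF window
#' against those at the end of the FT window for one trial. Zero variance of
#' the differences is a degenerate case: it is flagged, with `t = 0, p = 1`
#' when the means also agree and an infinite statistic otherwise.
#'
#' @param rpe_nf,rpe_ft Paired numeric vectors (same subjects, same order),
#'   length at least 3, no missing values.
#' @return One-row tibble `statistic, df, p.value, mean_diff, degenerate`.
#' @export
paired_rpe_test <- function(rpe_nf, rpe_ft) {
  if (length(rpe_nf) != length(rpe_ft)) abort("Paired vectors differ in length.")
  if (length(rpe_nf) < 3) abort("Need at least 3 pairs.")
  if (anyNA(rpe_nf) || anyNA(rpe_ft)) abort("Missing pairs are not allowed.")
  d <- rpe_ft - rpe_nf
  n <- length(d)
  if (sd(d) == 0) {
    warn("Zero variance of paired differences; degenerate t-test.",
         class = "fatiguegait_degenerate_test")
    if (mean(d) == 0) {
      return(tibble::tibble(statistic = 0, df = n - 1, p.value = 1,
                            mean_diff = 0, degenerate = TRUE))
    }
    return(tibble::tibble(statistic = sign(mean(d)) * Inf, df = n - 1,
                          p.value = 0, mean_diff = mean(d),
                          degenerate = TRUE))
  }
  tt <- t.test(rpe_ft, rpe_nf, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value, mean_diff = mean(d),
                 degenerate = FALSE)
}

#' Maximal lactate steady state criterion
#'
#' A constant-speed trial is at (or below) the maximal lactate steady state
#' when at least 30 minutes were completed and blood lactate rose by less
#' than 1 mmol/L between minutes 10 and 30.
#'
#' @param lactate_10min,lactate_30min Blood lactate concentrations, mmol/L.
#' @param completed_30min Logical: was 30 min of exercise completed?
#' @return Character vector, `"steady"` or `"not_steady"` (vectorised).
#' @export
#' @examples
#' identify_mlss(3.0, 3.8, TRUE)   # steady (rise 0.8 < 1)
#' identify_mlss(3.0, 4.0, TRUE)   # not steady (rise 1.0 is not < 1)
identify_mlss <- function(lactate_10min, lactate_30min, completed_30min) {
  if (anyNA(lactate_10min) || anyNA(lactate_30min) || anyNA(completed_30min)) {
    abort("Missing lactate measurement or completion flag.")
  }
  if (any(lactate_10min < 0) || any(lactate_30min < 0)) {
    abort("Lactate concentrations must be non-negative.")
  }
  ifelse(completed_30min & (lactate_30min - lactate_10min < 1.0),
         "steady", "not_steady")
}
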