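#' Configure a reliability-pipeline run
#'
#' @param mode `"simulate"` (generate a synthetic cohort from `spec`) or
#'   `"read"` (load trial CSV/JSON pairs from `input_dir`).
#' @param spec A [cohort_spec()] (simulate mode).
#' @param input_dir Directory of [write_trial()] outputs (read mode).
#' @param se_m,se_r,points_per_stride,gait_cycle Sample-entropy settings,
#'   see [extract_features()].
#' @param alpha Significance level, in (0, 1).
#' @param methods Non-empty subset of `c("MM", "ALL")`: compare the two
#'   same-speed MLSS trials only, and/or all four trials.
#' @param outdir Optional output directory; when given, result tables are
#'   written there by [write_report()].
#' @param seed Optional integer overriding the spec's seed (simulate mode).
#' @param expected_cadence Steps/min hint for event detection (read mode
#'   without cadence metadata).
#' @param adjust_p Add Benjamini-Hochberg adjusted fatigue p-values per
#'   method (off by default: the primary analysis is unadjusted and the
#'   chance-significance diagnostic is reported instead).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "read"),
                       spec = NULL, input_dir = NULL,
                       se_m = 2, se_r = 0.2, points_per_stride = 200,
                       gait_cycle = TRUE,
                       alpha = 0.05, methods = c("MM", "ALL"),
                       outdir = NULL, seed = NULL,
                       expected_cadence = NULL,
                       adjust_p = FALSE) {
  mode <- match.arg(mode)
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  if (length(methods) == 0 || !all(methods %in% c("MM", "ALL"))) {
    abort("`methods` must be a non-empty subset of {MM, ALL}.")
  }
  if (mode == "simulate" && is.null(spec)) {
    abort("Simulate mode needs a `cohort_spec`.")
  }
  if (mode == "read" && is.null(input_dir)) {
    abort("Read mode needs `input_dir`.")
  }
  structure(list(mode = mode, spec = spec, input_dir = input_dir,
                 se_m = se_m, se_r = se_r,
                 points_per_stride = points_per_stride,
                 gait_cycle = gait_cycle, alpha = alpha, methods = methods,
                 outdir = outdir, seed = seed,
                 expected_cadence = expected_cadence,
                 adjust_p = adjust_p),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level fields mirror [run_config()]; a nested `cohort` mapping is
#' passed to [cohort_spec()] via [read_cohort_spec()] semantics.
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$cohort)) {
    co <- cfg$cohort
    for (f in c("speed_offsets", "duration_mean", "fatigue_effects")) {
      if (!is.null(co[[f]])) co[[f]] <- unlist(co[[f]])
    }
    cfg$spec <- do.call(cohort_spec,
                        co[intersect(names(co), names(formals(cohort_spec)))])
    cfg$cohort <- NULL
  }
  if (!is.null(cfg$methods)) cfg$methods <- unlist(cfg$methods)
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

#' Expected number of chance-significant comparisons
#'
#' The multiple-comparisons diagnostic reported alongside the unadjusted
#' feature tests: with `n_comparisons` tests at level `alpha`, about
#' `n_comparisons * alpha` would reach significance by chance alone.
#'
#' @param n_comparisons Number of feature-level comparisons (>= 1).
#' @param alpha Significance level.
#' @return One-row tibble `n_comparisons, alpha, expected, rounded`.
#' @export
#' @examples
#' expected_chance_significances(78, 0.05)  # 3.9, rounded 4
expected_chance_significances <- function(n_comparisons, alpha = 0.05) {
  if (n_comparisons < 1) abort("`n_comparisons` must be at least 1.")
  if (alpha < 0 || alpha >= 1) abort("`alpha` must be in [0, 1).")
  expected <- n_comparisons * alpha
  tibble::tibble(n_comparisons = n_comparisons, alpha = alpha,
                 expected = expected, rounded = round(expected))
}

# per-trial processing shared by both input modes: preprocess, extract
# features, collect trial-level diagnostics
process_trial <- function(trial, config) {
  samples <- extract_condition_windows(
    trial, expected_cadence = config$expected_cadence)
  events <- attr(samples, "events")
  feats <- extract_feature_table(
    samples, se_m = config$se_m, se_r = config$se_r,
    points_per_stride = config$points_per_stride,
    gait_cycle = config$gait_cycle)
  diag <- purrr::imap(events, function(ev, win) {
    tibble::tibble(
      subject_id = trial$subject_id, trial_label = trial$trial_label,
      window = win,
      n_strides_retained = sum(ev$strides$retained),
      n_steps_excluded = length(ev$excluded_steps),
      n_samples = sum(samples$window == win),
      rpe = samples$rpe[match(win, samples$window)]
    )
  })
  trial_row <- tibble::tibble(
    subject_id = trial$subject_id, trial_label = trial$trial_label,
    duration = trial$duration, speed = trial$speed,
    rpe_nf = samples$rpe[match("NF", samples$window)],
    rpe_ft = samples$rpe[match("FT", samples$window)]
  )
  list(features = feats, diagnostics = dplyr::bind_rows(diag),
       trial_row = trial_row)
}

read_cohort_trials <- function(config) {
  files <- sort(list.files(config$input_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) abort("No trial CSV files in `input_dir`.")
  files
}

#' Run the full reliability pipeline
#'
#' Simulate (or read) a cohort of running trials, preprocess each trial
#' into fatigue-labelled five-stride samples, extract the 39 features,
#' average them to subject-condition means and run the statistical layer:
#' per-feature fatigue-state x trial repeated-measures ANOVA and ICC(2,k)
#' reliability for each requested comparison method, plus trial-variable
#' ANOVAs and paired RPE tests. Deterministic given the seed. Trials are
#' processed one at a time, so only one signal is ever held in memory.
#'
#' @param config A [run_config()].
#' @return A `reliability_report`: list of tibbles `anova` (one row per
#'   feature x method, Table-2 shaped), `anova_effects` (all three effects
#'   per feature x method), `icc` (feature x method x window),
#'   `trial_variables`, `rpe_tests`, `condition_means`, `diagnostics`, and
#'   a `summary` list (ICC means per window x method, significance counts,
#'   chance diagnostic).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  need_all <- "ALL" %in% config$methods
  need_trials <- if (need_all) c("MLSS1", "MLSS2", "F", "S") else
    c("MLSS1", "MLSS2")

  features <- list(); diagnostics <- list(); trial_rows <- list()
  if (config$mode == "simulate") {
    spec <- config$spec
    if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
    params <- make_cohort_params(spec)
    for (i in seq_len(nrow(params))) {
      trial <- simulate_trial(spec, params[i, ])
      res <- process_trial(trial, config)
      features[[i]] <- res$features
      diagnostics[[i]] <- res$diagnostics
      trial_rows[[i]] <- res$trial_row
      rm(trial)
    }
  } else {
    files <- read_cohort_trials(config)
    # validate the design from the metadata sidecars before any processing
    meta <- purrr::map(sub("\\.csv$", ".json", files),
                       jsonlite::read_json, simplifyVector = TRUE)
    subjects <- vapply(meta, function(m) m$subject_id, character(1))
    labels <- vapply(meta, function(m) m$trial_label, character(1))
    for (s in unique(subjects)) {
      missing <- setdiff(need_trials, labels[subjects == s])
      if (length(missing) > 0) {
        abort(paste0("Subject ", s, " is missing trial(s): ",
                     paste(missing, collapse = ", ")))
      }
    }
    for (i in seq_along(files)) {
      trial <- read_trial(files[[i]])
      res <- process_trial(trial, config)
      features[[i]] <- res$features
      diagnostics[[i]] <- res$diagnostics
      trial_rows[[i]] <- res$trial_row
    }
  }
  features <- dplyr::bind_rows(features)
  diagnostics <- dplyr::bind_rows(diagnostics)
  trial_rows <- dplyr::bind_rows(trial_rows)

  # design validation: every subject must hold the trials the methods need
  have <- features |>
    dplyr::distinct(.data$subject_id, .data$trial_label)
  for (s in unique(have$subject_id)) {
    missing <- setdiff(need_trials, have$trial_label[have$subject_id == s])
    if (length(missing) > 0) {
      abort(paste0("Subject ", s, " is missing trial(s): ",
                   paste(missing, collapse = ", ")))
    }
  }

  means <- aggregate_condition_means(features)

  anova_rows <- list(); effect_rows <- list(); icc_rows <- list()
  for (method in config$methods) {
    trials_m <- if (method == "MM") c("MLSS1", "MLSS2") else need_trials
    for (feat in feature_names()) {
      cells <- means[means$feature == feat &
                       means$trial_label %in% trials_m,
                     c("subject_id", "trial_label", "window", "value")]
      fit <- fatigue_trial_anova(cells, method = method,
                                 alpha = config$alpha)
      td <- tidy(fit)
      effect_rows[[length(effect_rows) + 1]] <-
        dplyr::mutate(td, feature = feat, .before = 1)
      anova_rows[[length(anova_rows) + 1]] <- tibble::tibble(
        feature = feat, method = method,
        p_fatigue = td$p.value[td$effect == "fatigue"],
        p_trial = td$p.value[td$effect == "trial"],
        p_interaction = td$p.value[td$effect == "fatigue:trial"],
        direction = fit$direction, delta = fit$delta,
        n_subjects = fit$n_subjects
      )
      for (win in c("NF", "FT")) {
        m <- cells[cells$window == win, ]
        ic <- icc_2k(m)
        icc_rows[[length(icc_rows) + 1]] <- tibble::tibble(
          feature = feat, method = method, window = win,
          icc = ic$icc, category = ic$category,
          n_subjects = ic$n_subjects, k_trials = ic$k_trials,
          degenerate = ic$degenerate
        )
      }
    }
  }
  anova <- dplyr::bind_rows(anova_rows)
  if (config$adjust_p) {
    anova <- anova |>
      dplyr::group_by(.data$method) |>
      dplyr::mutate(p_fatigue_bh = stats::p.adjust(.data$p_fatigue,
                                                   method = "BH")) |>
      dplyr::ungroup()
  }
  icc <- dplyr::bind_rows(icc_rows)

  trial_vars <- build_trial_variables(trial_rows, diagnostics)
  tv_anova <- trial_vars |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(d, key) trial_variable_anova(d)) |>
    dplyr::ungroup()
  rpe_tests <- trial_rows |>
    dplyr::group_by(.data$trial_label) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) return(tibble::tibble())
      # degeneracy is kept as a flag column; no warning at pipeline level
      suppressWarnings(paired_rpe_test(d$rpe_nf, d$rpe_ft))
    }) |>
    dplyr::ungroup()

  n_comparisons <- length(config$methods) * length(feature_names())
  chance <- expected_chance_significances(n_comparisons, config$alpha)
  icc_summary <- icc |>
    dplyr::group_by(.data$method, .data$window) |>
    dplyr::summarise(mean_icc = mean(.data$icc, na.rm = TRUE),
                     sd_icc = sd(.data$icc, na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop")
  summary <- list(
    n_features = length(feature_names()),
    methods = config$methods,
    n_comparisons = n_comparisons,
    n_significant_fatigue = sum(anova$p_fatigue < config$alpha,
                                na.rm = TRUE),
    expected_chance = chance$expected,
    expected_chance_rounded = chance$rounded,
    icc_summary = icc_summary,
    alpha = config$alpha
  )

  report <- structure(list(
    anova = anova,
    anova_effects = dplyr::bind_rows(effect_rows),
    icc = icc,
    trial_variables = tv_anova,
    trial_variable_values = trial_vars,
    rpe_tests = rpe_tests,
    condition_means = means,
    diagnostics = diagnostics,
    summary = summary
  ), class = "reliability_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

build_trial_variables <- function(trial_rows, diagnostics) {
  strides <- diagnostics |>
    dplyr::select(dplyr::all_of(c("subject_id", "trial_label", "window",
                                  "n_strides_retained"))) |>
    tidyr::pivot_wider(names_from = "window",
                       values_from = "n_strides_retained",
                       names_prefix = "strides_")
  tv <- trial_rows |>
    dplyr::left_join(strides, by = c("subject_id", "trial_label")) |>
    dplyr::mutate(delta_rpe = .data$rpe_ft - .data$rpe_nf)
  tv |>
    dplyr::select(dplyr::all_of(c("subject_id", "trial_label", "duration",
                                  "rpe_nf", "rpe_ft", "delta_rpe",
                                  "strides_NF", "strides_FT"))) |>
    tidyr::pivot_longer(cols = c("duration", "rpe_nf", "rpe_ft", "delta_rpe",
                                 "strides_NF", "strides_FT"),
                        names_to = "variable", values_to = "value")
}

#' @export
print.reliability_report <- function(x, ...) {
  s <- x$summary
  cat("<reliability_report> ", s$n_features, " features, methods: ",
      paste(s$methods, collapse = "/"), "\n", sep = "")
  cat("  significant fatigue effects: ", s$n_significant_fatigue, " of ",
      s$n_comparisons, " (expected by chance: ",
      round(s$expected_chance, 2), " ~ ", s$expected_chance_rounded,
      ")\n", sep = "")
  ic <- s$icc_summary
  for (i in seq_len(nrow(ic))) {
    cat(sprintf("  ICC(2,k) %s %s: %.3f +/- %.3f\n", ic$window[i],
                ic$method[i], ic$mean_icc[i], ic$sd_icc[i]))
  }
  invisible(x)
}

#' @export
tidy.reliability_report <- function(x, type = c("icc", "anova", "effects",
                                                "trial_variables", "rpe"),
                                    ...) {
  type <- match.arg(type)
  switch(type,
         icc = x$icc,
         anova = x$anova,
         effects = x$anova_effects,
         trial_variables = x$trial_variables,
         rpe = x$rpe_tests)
}

#' @export
glance.reliability_report <- function(x, ...) {
  s <- x$summary
  wide <- tidyr::pivot_wider(
    s$icc_summary[, c("method", "window", "mean_icc")],
    names_from = c("window", "method"), values_from = "mean_icc",
    names_glue = "icc_{tolower(window)}_{tolower(method)}")
  dplyr::bind_cols(
    tibble::tibble(n_features = s$n_features,
                   n_comparisons = s$n_comparisons,
                   n_significant_fatigue = s$n_significant_fatigue,
                   expected_chance = s$expected_chance),
    wide)
}

split_feature <- function(feature) {
  axis <- sub("^.*_", "", feature)
  stat <- sub("_[^_]*$", "", feature)
  list(axis = toupper(axis), stat = stat)
}

#' Write the report tables of a pipeline run
#'
#' Emits `fatigue_effects.csv` (axis, feature, method, p-values,
#' direction), `icc.csv` (axis, feature, method, window, ICC, category),
#' `trial_variables.csv`, `rpe_tests.csv`, `condition_means.csv` and
#' `summary.json` (counts of significant effects and the
#' chance-significance diagnostic).
#'
#' @param report A `reliability_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- split_feature(report$anova$feature)
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(axis = fa$axis, stat = fa$stat),
                     report$anova),
    file.path(dir, "fatigue_effects.csv"))
  fi <- split_feature(report$icc$feature)
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(axis = fi$axis, stat = fi$stat),
                     report$icc),
    file.path(dir, "icc.csv"))
  readr::write_csv(report$trial_variables,
                   file.path(dir, "trial_variables.csv"))
  readr::write_csv(report$rpe_tests, file.path(dir, "rpe_tests.csv"))
  readr::write_csv(report$condition_means,
                   file.path(dir, "condition_means.csv"))
  s <- report$summary
  jsonlite::write_json(
    list(n_features = s$n_features,
         methods = as.list(s$methods),
         n_comparisons = s$n_comparisons,
         n_significant_fatigue = s$n_significant_fatigue,
         expected_chance = s$expected_chance,
         expected_chance_rounded = s$expected_chance_rounded,
         alpha = s$alpha,
         icc_summary = s$icc_summary),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
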