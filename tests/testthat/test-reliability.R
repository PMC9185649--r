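test_that("ICC interpretation bins match the reliability convention", {
  expect_equal(icc_category(c(0.2, 0.5, 0.6, 0.75, 0.8, 0.9, 0.97, NA)),
               c("poor", "moderate", "moderate", "good", "good",
                 "excellent", "excellent", NA))
})

test_that("identical trial columns with subject spread give ICC of 1", {
  m <- cbind(t1 = c(1, 2, 3, 4, 7), t2 = c(1, 2, 3, 4, 7))
  fit <- icc_2k(m)
  expect_equal(fit$icc, 1)
  expect_equal(fit$category, "excellent")
})

test_that("ICC(2,k) equals first-principles sums of squares", {
  set.seed(21)
  for (s in 1:100) {
    m <- matrix(rnorm(32, sd = runif(1, 0.5, 3)), 8, 4) +
      outer(rnorm(8, 0, runif(1, 0, 2)), rep(1, 4)) +      # subject effects
      outer(rep(1, 8), rnorm(4, 0, runif(1, 0, 1)))        # trial constants
    fit <- icc_2k(m)
    expect_equal(fit$icc, icc_oracle(m), tolerance = 1e-9)
  }
})

test_that("a trial-specific constant lowers absolute-agreement ICC", {
  set.seed(5)
  m <- outer(rnorm(12, 0, 2), rep(1, 3)) + matrix(rnorm(36, sd = 0.3), 12, 3)
  base <- icc_2k(m)$icc
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 2
  expect_lt(icc_2k(shifted)$icc, base)
  # pure rescaling does not change it
  expect_equal(icc_2k(m * 3.7)$icc, base, tolerance = 1e-9)
})

test_that("ICC handles degenerate and deficient inputs", {
  # rows equal, columns opposed: non-positive denominator
  m <- rbind(c(0, 1), c(1, 0), c(0.5, 0.5))
  fit <- icc_2k(m)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$icc))
  expect_error(icc_2k(matrix(rnorm(4), 2, 2)), "3 complete subjects")
  # listwise deletion drops incomplete subjects with a message
  m4 <- matrix(rnorm(20), 5, 4)
  m4[2, 3] <- NA
  expect_message(fit4 <- icc_2k(m4), "dropped")
  expect_equal(fit4$n_subjects, 4)
  # data-frame interface agrees with the matrix interface
  d <- tidyr::expand_grid(subject_id = paste0("S", 1:5),
                          trial_label = paste0("t", 1:3))
  set.seed(9)
  d$value <- rnorm(15) + rep(rnorm(5, 0, 2), each = 3)
  wide <- matrix(d$value, 5, 3, byrow = TRUE)
  expect_equal(icc_2k(d)$icc, icc_2k(wide)$icc, tolerance = 1e-12)
})

test_that("ICC under a null subject effect is near zero", {
  # a single replicate at n = 200, k = 4 has sampling sd ~ 0.12, so the
  # check is on the Monte-Carlo mean across seeded replicates
  vals <- vapply(1:10, function(s) {
    d <- simulate_condition_means(200, windows = "NF", sigma_subject = 0,
                                  sigma_error = 1, seed = 100 + s)
    icc_2k(d)$icc
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("ICC recovers the variance-ratio expectation", {
  # sigma_s = sigma_e = 1, k = 2: ICC(2,k) -> 2/(2+1) = 0.667
  for (s in 1:3) {
    d <- simulate_condition_means(500, trial_labels = c("MLSS1", "MLSS2"),
                                  windows = "NF", sigma_subject = 1,
                                  sigma_error = 1, seed = 200 + s)
    expect_lt(abs(icc_2k(d)$icc - 2 / 3), 0.05)
  }
})

make_cells <- function(n = 8, trials = c("MLSS1", "MLSS2", "F", "S"),
                       shift = 0, noise = 0.01, seed = 1) {
  set.seed(seed)
  base <- rnorm(n, 10, 2)
  g <- tidyr::expand_grid(subject_id = sprintf("P%02d", 1:n),
                          trial_label = trials, window = c("NF", "FT"))
  g$value <- base[match(g$subject_id, sprintf("P%02d", 1:n))] +
    shift * (g$window == "FT") + rnorm(nrow(g), 0, noise)
  g
}

test_that("a constructed fatigue shift is detected with its direction", {
  cells <- make_cells(shift = 1.5)
  fit <- fatigue_trial_anova(cells, method = "ALL")
  td <- tidy(fit)
  expect_lt(td$p.value[td$effect == "fatigue"], 0.05)
  expect_gt(td$p.value[td$effect == "trial"], 0.05)
  expect_equal(fit$direction, "+")
  expect_equal(fit$delta, 1.5, tolerance = 0.05)
  # negative shift flips the sign
  fit_neg <- fatigue_trial_anova(make_cells(shift = -1.5), method = "ALL")
  expect_equal(fit_neg$direction, "-")
  # no direction is reported for a null effect
  fit0 <- fatigue_trial_anova(make_cells(shift = 0), method = "ALL")
  expect_equal(fit0$direction, "none")
})

test_that("the MM method restricts the design to the two MLSS trials", {
  cells <- make_cells(shift = 1)
  fit <- fatigue_trial_anova(cells, method = "MM")
  expect_equal(fit$trials, c("MLSS1", "MLSS2"))
  td <- tidy(fit)
  expect_equal(td$df1, c(1, 1, 1))       # 2-level factors throughout
  fit_all <- fatigue_trial_anova(cells, method = "ALL")
  expect_equal(tidy(fit_all)$df1, c(1, 3, 3))
})

test_that("ANOVA p-values are invariant to location shift and relabeling", {
  cells <- make_cells(shift = 0.8, seed = 3)
  p0 <- tidy(fatigue_trial_anova(cells, "ALL"))$p.value
  shifted <- cells
  shifted$value <- shifted$value + 100
  expect_equal(tidy(fatigue_trial_anova(shifted, "ALL"))$p.value, p0,
               tolerance = 1e-9)
  relabeled <- cells
  map <- setNames(sprintf("Q%02d", sample(8)), sprintf("P%02d", 1:8))
  relabeled$subject_id <- map[relabeled$subject_id]
  expect_equal(tidy(fatigue_trial_anova(relabeled, "ALL"))$p.value, p0,
               tolerance = 1e-9)
})

test_that("incomplete subjects are dropped and imbalance is an error", {
  cells <- make_cells(n = 6, shift = 1)
  incomplete <- cells[!(cells$subject_id == "P01" & cells$window == "FT" &
                          cells$trial_label == "S"), ]
  expect_message(fit <- fatigue_trial_anova(incomplete, "ALL"), "P01")
  expect_equal(fit$n_subjects, 5)
  dup <- dplyr::bind_rows(cells, cells[1, ])
  expect_error(fatigue_trial_anova(dup, "ALL"), "Unbalanced")
  tiny <- cells[cells$subject_id %in% c("P01", "P02"), ]
  expect_error(fatigue_trial_anova(tiny, "ALL"), "3 complete")
})

test_that("type-I error of the fatigue effect is near the nominal level", {
  rejections <- 0
  for (s in 1:100) {
    d <- simulate_condition_means(16, sigma_subject = 1, sigma_error = 1,
                                  fatigue_shift = 0, seed = 4000 + s)
    names(d)[names(d) == "value"] <- "value"
    fit <- fatigue_trial_anova(d, "ALL")
    p <- fit$effects$p.value[fit$effects$effect == "fatigue"]
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections, 1)   # binomial tolerance around 5 % of 100
  expect_lte(rejections, 11)
})

test_that("the trial-variable ANOVA flags real trial differences only", {
  d <- tidyr::expand_grid(subject_id = sprintf("P%02d", 1:8),
                          trial_label = c("MLSS1", "MLSS2", "F", "S"))
  d$value <- rep(rnorm(8, 40, 5), each = 4)   # identical across trials
  res <- trial_variable_anova(d)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  d2 <- d
  d2$value[d2$trial_label == "F"] <- d2$value[d2$trial_label == "F"] - 10
  d2$value <- d2$value + rnorm(nrow(d2), 0, 0.5)
  res2 <- trial_variable_anova(d2)
  expect_lt(res2$p.value, 0.05)
  # null rejection rate within binomial tolerance of 5 %
  rej <- 0
  for (s in 1:100) {
    set.seed(6000 + s)
    dn <- d
    dn$value <- rep(rnorm(8, 40, 5), each = 4) + rnorm(32)
    if (trial_variable_anova(dn)$p.value < 0.05) rej <- rej + 1
  }
  expect_gte(rej, 1)
  expect_lte(rej, 11)
})

test_that("paired RPE test matches hand computation and edge cases", {
  # differences 1,2,3,4: t = 2.5 / (sd/sqrt(4)) = 3.873, df 3
  nf <- c(10, 11, 12, 13)
  ft <- nf + 1:4
  res <- paired_rpe_test(nf, ft)
  expect_equal(res$statistic, 2.5 / (sd(1:4) / 2), tolerance = 1e-4)
  expect_equal(res$statistic, 3.873, tolerance = 1e-3)
  expect_equal(res$df, 3)
  expect_false(res$degenerate)
  # identical vectors: degenerate, t = 0, p = 1
  expect_warning(res0 <- paired_rpe_test(nf, nf),
                 class = "fatiguegait_degenerate_test")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  expect_true(res0$degenerate)
  # constant non-zero difference: flagged with an infinite statistic
  expect_warning(resc <- paired_rpe_test(nf, nf + 2),
                 class = "fatiguegait_degenerate_test")
  expect_true(is.infinite(resc$statistic) && resc$statistic > 0)
  expect_true(resc$degenerate)
  expect_error(paired_rpe_test(1:3, 1:4), "length")
  expect_error(paired_rpe_test(c(1, 2), c(2, 3)), "3 pairs")
  expect_error(paired_rpe_test(c(1, NA, 3), c(2, 3, 4)), "Missing")
})

test_that("a paper-scale RPE rise is detected almost surely at n = 16", {
  hits <- 0
  for (s in 1:100) {
    set.seed(5000 + s)
    nf <- round(rnorm(16, 11.5, 1.7))
    ft <- nf + round(rnorm(16, 4, 2))
    res <- suppressWarnings(paired_rpe_test(nf, ft))
    if (res$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("the MLSS rule applies the 1 mmol/L and 30-min criteria", {
  expect_equal(identify_mlss(3.0, 3.8, TRUE), "steady")
  expect_equal(identify_mlss(3.0, 4.0, TRUE), "not_steady")  # 1.0 is not < 1
  expect_equal(identify_mlss(2.5, 3.0, FALSE), "not_steady")
  expect_equal(identify_mlss(c(3, 3), c(3.5, 4.5), c(TRUE, TRUE)),
               c("steady", "not_steady"))
  expect_error(identify_mlss(NA, 3, TRUE), "Missing")
  expect_error(identify_mlss(-1, 3, TRUE), "non-negative")
})
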