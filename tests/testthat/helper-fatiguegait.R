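# Shared fixtures and independent oracles. The oracles deliberately use
# naive enumeration so they share no code path with the implementation.

# small, quick cohort: short trials at a modest sampling rate
quick_spec <- function(n_subjects = 4, sampling_rate = 150, seed = 1, ...) {
  args <- list(n_subjects = n_subjects, sampling_rate = sampling_rate,
               duration_mean = c(MLSS1 = 16, MLSS2 = 16, F = 15, S = 17),
               duration_sd = 0.5, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_spec, args)
}

# a fully deterministic spec: no noise, no jitter, no stride-level wobble
noiseless_spec <- function(...) {
  quick_spec(noise_vt = 0, noise_ml = 0, noise_ap = 0, jitter_cv = 0,
             within_trial_sd = 0, duration_sd = 0, ...)
}

# brute-force sample entropy: nested loops over all template pairs
sampen_oracle <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# first-principles ICC(2,k): explicit-loop sums of squares for the two-way
# (subject x trial) single-observation layout, then the average-measures
# absolute-agreement formula
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_total <- 0
  for (i in 1:n) for (j in 1:k) ss_total <- ss_total + (m[i, j] - gm)^2
  ss_rows <- 0
  for (i in 1:n) ss_rows <- ss_rows + k * (mean(m[i, ]) - gm)^2
  ss_cols <- 0
  for (j in 1:k) ss_cols <- ss_cols + n * (mean(m[, j]) - gm)^2
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_total - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

# independent count of 5-stride samples obtainable from an IC list under
# the +/-2 SD step-exclusion rule and global-parity stride pairing
samples_oracle <- function(ic, n_strides = 5) {
  len <- diff(ic)
  mu <- mean(len)
  s <- sqrt(mean((len - mu)^2))
  keep <- if (s == 0) rep(TRUE, length(len)) else abs(len - mu) <= 2 * s
  ns <- floor(length(len) / 2)
  total <- 0; run <- 0
  for (q in seq_len(ns)) {
    if (keep[2 * q - 1] && keep[2 * q]) {
      run <- run + 1
    } else {
      total <- total + run %/% n_strides
      run <- 0
    }
  }
  total + run %/% n_strides
}
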