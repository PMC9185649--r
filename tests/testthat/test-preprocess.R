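make_static_accel <- function(vec, n = 200, fs = 100, noise = 0) {
  tibble::tibble(
    time_s = (seq_len(n) - 1) / fs,
    vt = vec[1] + rnorm(n, 0, noise),
    ml = vec[2] + rnorm(n, 0, noise),
    ap = vec[3] + rnorm(n, 0, noise)
  )
}

test_that("attitude correction maps the static vector onto +VT", {
  # already aligned: identity
  acc <- make_static_accel(c(1, 0, 0))
  corr <- estimate_attitude_correction(acc, 100, c(0, 2))
  expect_equal(corr$rotation, diag(3), tolerance = 1e-12)

  # tilted sensor
  acc <- make_static_accel(c(0.999, 0.04, 0.02))
  corr <- estimate_attitude_correction(acc, 100, c(0, 2))
  r <- corr$rotation
  expect_equal(t(r) %*% r, diag(3), tolerance = 1e-9)
  expect_equal(det(r), 1, tolerance = 1e-9)
  g_rot <- as.vector(r %*% corr$gravity_estimate)
  angle <- acos(g_rot[1] / sqrt(sum(g_rot^2))) * 180 / pi
  expect_lt(angle, 0.5)
  # norm preservation on arbitrary samples
  set.seed(1)
  pts <- matrix(rnorm(30), 3)
  expect_equal(sqrt(colSums((r %*% pts)^2)), sqrt(colSums(pts^2)),
               tolerance = 1e-9)
})

test_that("attitude correction rejects degenerate static windows", {
  expect_error(estimate_attitude_correction(
    make_static_accel(c(0, 0, 0)), 100, c(0, 2)), "gravity")
  set.seed(2)
  dyn <- make_static_accel(c(1, 0, 0), noise = 0.5)
  expect_error(estimate_attitude_correction(dyn, 100, c(0, 2)), "dynamic")
  expect_error(estimate_attitude_correction(
    make_static_accel(c(1, 0, 0), n = 20), 100, c(0, 2)), "0.5 s")
})

test_that("the resultant is invariant under attitude correction", {
  spec <- quick_spec(n_subjects = 1, sampling_rate = 100, seed = 4)
  tr <- simulate_trial(spec, make_cohort_params(spec)[1, ])
  corr <- estimate_attitude_correction(tr$accel, 100, c(-2, 0))
  out <- apply_attitude_correction(tr$accel, corr)
  res_before <- sqrt(tr$accel$vt^2 + tr$accel$ml^2 + tr$accel$ap^2)
  res_after <- sqrt(out$vt^2 + out$ml^2 + out$ap^2)
  expect_equal(res_after, res_before, tolerance = 1e-9)
})

test_that("initial contacts on noiseless trials match ground truth within 10 ms", {
  spec <- noiseless_spec(n_subjects = 1, sampling_rate = 300, seed = 6)
  tr <- simulate_trial(spec, make_cohort_params(spec)[1, ])
  corr <- estimate_attitude_correction(tr$accel, 300, c(-2, 0))
  acc <- apply_attitude_correction(tr$accel, corr)
  for (win in list(c(300, 600), c(5 * floor(tr$duration / 5) * 60 - 300,
                                  5 * floor(tr$duration / 5) * 60))) {
    seg <- acc[acc$time_s >= win[1] & acc$time_s < win[2], ]
    ic <- detect_initial_contacts(seg, 300, tr$cadence)
    expect_true(all(diff(ic) > 0))
    t_det <- seg$time_s[ic]
    truth <- tr$true_ic_times[tr$true_ic_times >= win[1] &
                                tr$true_ic_times < win[2]]
    err <- vapply(t_det, function(t) min(abs(truth - t)), numeric(1))
    expect_lt(max(err), 0.010)
    # one detection per impact
    expect_equal(length(t_det), length(truth), tolerance = 0.01)
  }
})

test_that("detected cadence tracks the configured cadence", {
  for (cad in c(160, 180)) {
    spec <- noiseless_spec(n_subjects = 1, sampling_rate = 300, seed = 8,
                           cadence_mean = cad, cadence_sd = 0,
                           between_trial_sd = 0)
    tr <- simulate_trial(spec, make_cohort_params(spec)[1, ])
    corr <- estimate_attitude_correction(tr$accel, 300, c(-2, 0))
    acc <- apply_attitude_correction(tr$accel, corr)
    seg <- acc[acc$time_s >= 300 & acc$time_s < 600, ]
    ic <- detect_initial_contacts(seg, 300, cad)
    cad_hat <- 60 / (median(diff(ic)) / 300)
    expect_lt(abs(cad_hat - cad), 2)
  }
})

test_that("gait-free signals produce a segmentation error", {
  flat <- tibble::tibble(time_s = (0:9999) / 100, vt = 1, ml = 0, ap = 0)
  expect_error(detect_initial_contacts(flat, 100, 180), "segmentation")
  short <- tibble::tibble(time_s = (0:99) / 100, vt = 1, ml = 0, ap = 0)
  expect_error(detect_initial_contacts(short, 100, 180), "10 expected steps")
})

test_that("the +/-2 SD rule excludes exactly the planted aberrant steps", {
  # 98 regular steps of 375 samples plus one long (500) and one short (250)
  ic <- cumsum(c(1, rep(375, 98), 500, 250))
  ev <- segment_and_filter_steps(ic, 1125)
  expect_identical(ev$excluded_steps, c(99L, 100L))
  expect_true(all(ev$steps$retained[1:98]))

  # all-equal step lengths: sd = 0 excludes nothing
  ic_eq <- cumsum(c(1, rep(375, 100)))
  ev_eq <- segment_and_filter_steps(ic_eq, 1125)
  expect_length(ev_eq$excluded_steps, 0)
  expect_equal(sum(ev_eq$strides$retained), 50)
})

test_that("the events debug table mirrors the step bookkeeping", {
  ic <- cumsum(c(1, rep(375, 98), 500, 250))
  ev <- segment_and_filter_steps(ic, 1125)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gait_events(ev, path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(names(tab), c("ic_index", "step_length", "retained"))
  expect_equal(nrow(tab), 100)
  expect_equal(sum(!tab$retained), 2)
})

test_that("an excluded middle step splits the stride stream", {
  # 41 steps of 375 with one aberrant step in the middle (position 21)
  lens <- rep(375, 41)
  lens[21] <- 800
  ic <- cumsum(c(1, lens))
  ev <- segment_and_filter_steps(ic, 1125)
  expect_identical(ev$excluded_steps, 21L)
  samples <- build_stride_samples(ev, n_strides = 5)
  # no sample may span the excluded step's interval
  bad_lo <- ev$steps$start[21]; bad_hi <- ev$steps$end[21]
  for (i in seq_len(nrow(samples))) {
    expect_true(samples$end[i] <= bad_lo || samples$start[i] >= bad_hi)
  }
  expect_equal(nrow(samples), samples_oracle(ic, 5))
})

test_that("sample counts match brute-force enumeration across IC patterns", {
  set.seed(99)
  for (rep in 1:20) {
    lens <- round(rnorm(80, 375, 8))
    n_bad <- sample(0:3, 1)
    if (n_bad > 0) lens[sample(80, n_bad)] <- sample(c(180, 700), n_bad,
                                                     replace = TRUE)
    ic <- cumsum(c(1, lens))
    ev <- segment_and_filter_steps(ic, 1125)
    samples <- build_stride_samples(ev, 5)
    expect_equal(nrow(samples), samples_oracle(ic, 5))
  }
})

test_that("NF/FT windows follow the five-minute RPE schedule", {
  w <- condition_windows(38, 5)
  expect_equal(w$start_s[w$window == "FT"], 30 * 60)
  expect_equal(w$end_s[w$window == "FT"], 35 * 60)
  w45 <- condition_windows(45, 5)
  expect_equal(w45$start_s[w45$window == "FT"], 40 * 60)
  expect_equal(w45$end_s[w45$window == "FT"], 45 * 60)
  w15 <- condition_windows(15, 5)
  expect_equal(w15$start_s, c(300, 600))
  expect_equal(w15$end_s, c(600, 900))
  expect_error(condition_windows(14, 5), "overlap")
  # each window spans exactly 5 min and they never overlap
  for (d in c(15, 17.3, 22, 38, 44.9, 45)) {
    w <- condition_windows(d, 5)
    expect_equal(w$end_s - w$start_s, c(300, 300))
    expect_lte(w$end_s[w$window == "NF"], w$start_s[w$window == "FT"])
  }
})

test_that("end-to-end window extraction yields labelled consecutive samples", {
  spec <- quick_spec(n_subjects = 1, sampling_rate = 150, seed = 12)
  tr <- simulate_trial(spec, make_cohort_params(spec)[1, ])
  sam <- extract_condition_windows(tr)
  expect_setequal(unique(sam$window), c("NF", "FT"))
  # RPE labels come from the end of each window
  wins <- condition_windows(tr$duration, tr$warmup_duration)
  for (w in c("NF", "FT")) {
    end_min <- wins$end_s[wins$window == w] / 60
    lab <- tr$rpe_log$rpe[max(which(tr$rpe_log$minute <= end_min + 1e-9))]
    expect_true(all(sam$rpe[sam$window == w] == lab))
  }
  # FT RPE exceeds NF RPE (fatigue accrues)
  expect_gt(sam$rpe[sam$window == "FT"][1], sam$rpe[sam$window == "NF"][1])
  # resultant equals the Euclidean norm, and strides are contiguous
  a <- sam$accel[[1]]
  expect_equal(a$res, sqrt(a$vt^2 + a$ml^2 + a$ap^2), tolerance = 1e-12)
  for (i in seq_len(nrow(sam))) {
    b <- sam$stride_bounds[[i]]
    expect_length(b, 6)
    expect_true(all(diff(b) > 0))
    expect_equal(b[1], 1)
    expect_equal(b[6], nrow(sam$accel[[i]]) + 1)
  }
  # bookkeeping: 5 x samples never exceeds retained strides per window
  ev <- attr(sam, "events")
  for (w in c("NF", "FT")) {
    expect_lte(5 * sum(sam$window == w), sum(ev[[w]]$strides$retained))
  }
})
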