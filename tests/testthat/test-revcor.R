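test_that("a two-trial toy kernel equals the hand-computed group means", {
  fm <- 1000 / 30
  # 2 bars x 6 frames; responses at frames 5 and 6 (rt = frame * fm + 250)
  n1l <- matrix(seq(0.01, 0.12, by = 0.01), 2, 6)
  n1r <- -n1l
  n2l <- matrix(rep(c(0.2, -0.2), 6), 2, 6)
  n2r <- matrix(0.05, 2, 6)
  trials <- list(
    make_trial(n1l, n1r, choice = "left", rt = 5 * fm + 250),
    make_trial(n2l, n2r, choice = "right", rt = 6 * fm + 250)
  )
  ci <- response_locked_kernel(trials, max_lag = 2, min_count = 1)
  # lag 0: trial 1 chosen col 5, trial 2 chosen (right field) col 6
  mu1_lag0 <- (n1l[, 5] + n2r[, 6]) / 2
  mu0_lag0 <- (n1r[, 5] + n2l[, 6]) / 2
  expect_equal(ci$kernel[, 1], mu1_lag0 - mu0_lag0)
  mu1_lag2 <- (n1l[, 3] + n2r[, 4]) / 2
  mu0_lag2 <- (n1r[, 3] + n2l[, 4]) / 2
  expect_equal(ci$kernel[, 3], mu1_lag2 - mu0_lag2)
  expect_identical(ci$n_trials_per_lag, rep(2L, 3))
  expect_equal(ci$lag_ms, 0:2 * fm + 250)
})

test_that("the kernel estimator equals the brute-force per-cell oracle", {
  trials <- null_trials(18, n_bars = 5, n_frames = 25, seed = 3)
  got <- response_locked_kernel(trials, max_lag = 12, min_count = 3)
  want <- oracle_kernel(trials, max_lag = 12, min_count = 3)
  expect_identical(got$n_trials_per_lag, want$counts)
  expect_equal(got$kernel, want$kernel)
  # variance flavour against the same oracle on squared noise
  sq <- lapply(trials, function(tr) {
    tr$noise_left <- tr$noise_left^2
    tr$noise_right <- tr$noise_right^2
    tr
  })
  vk <- variance_kernel(trials, max_lag = 12, min_count = 3)
  expect_equal(vk$kernel, oracle_kernel(sq, 12, 3)$kernel)
})

test_that("per-lag counts shrink with look-back and sparse lags are masked", {
  fm <- 1000 / 30
  trials <- lapply(c(4, 6, 9, 9, 12), function(rf)
    make_trial(matrix(0.1, 2, 12), matrix(-0.1, 2, 12),
               choice = "left", rt = rf * fm + 250))
  ci <- response_locked_kernel(trials, max_lag = 11, min_count = 2)
  expect_identical(ci$n_trials_per_lag[1], 5L)
  expect_true(all(diff(ci$n_trials_per_lag) <= 0))
  # lags reachable only by the rt = 12 trial fall below min_count
  expect_identical(ci$n_trials_per_lag[12], 1L)
  expect_true(all(is.na(ci$kernel[, 12])))
  expect_true(all(!is.na(ci$kernel[, 1:6])))
  expect_equal(ci$kernel[1, 1], 0.2)   # constant-noise toy: mu1 - mu0
})

test_that("choices uncorrelated with the noise give a null kernel", {
  trials <- null_trials(600, n_bars = 4, n_frames = 30, seed = 9)
  ci <- response_locked_kernel(trials, max_lag = 8, min_count = 50)
  # each cell is a difference of two means of sd-0.1 draws
  se <- 0.1 * sqrt(2 / min(ci$n_trials_per_lag))
  expect_lt(max(abs(ci$kernel)), 5 * se)
  expect_gt(mean(abs(ci$kernel)), 0)   # but not degenerate zeros
})

test_that("mirroring every trial leaves the kernel identical", {
  trials <- null_trials(40, n_bars = 4, n_frames = 30, seed = 5)
  flipped <- lapply(trials, function(tr) {
    tmp <- tr$noise_left
    tr$noise_left <- tr$noise_right
    tr$noise_right <- tmp
    tr$choice <- if (tr$choice == "left") "right" else "left"
    tr$target_side <- tr$choice
    tr
  })
  a <- response_locked_kernel(trials, max_lag = 10, min_count = 5)
  b <- response_locked_kernel(flipped, max_lag = 10, min_count = 5)
  expect_identical(a$kernel, b$kernel)
  expect_identical(a$n_trials_per_lag, b$n_trials_per_lag)
})

test_that("kernel estimation rejects unusable trial sets", {
  expect_error(response_locked_kernel(list()), "empty")
  t1 <- null_trials(3, seed = 1)
  t1 <- lapply(t1, function(tr) { tr$timeout <- TRUE; tr$correct <- FALSE; tr })
  expect_error(response_locked_kernel(t1), "no usable")
})

test_that("impact curves average the designated bar sets", {
  trials <- null_trials(30, n_bars = 16, n_frames = 30, seed = 2)
  ci <- response_locked_kernel(trials, max_lag = 6, min_count = 5)
  ci$kernel[] <- 0
  ic0 <- impact_curves(ci)
  expect_true(all(ic0$central == 0) && all(ic0$adjacent == 0))
  expect_identical(ic0$central_bars, c(8L, 9L))
  expect_identical(ic0$adjacent_bars, c(7L, 10L))
  ci$kernel[8, 3] <- 0.4                      # one central bar, one lag
  ic <- impact_curves(ci)
  expect_equal(ic$central[3], 0.2)            # mean over the two central bars
  expect_true(all(ic$adjacent == 0))
  expect_error(impact_curves(ci, central_bars = c(8, 9),
                             adjacent_bars = c(9, 10)), "disjoint")
  expect_error(impact_curves(ci, central_bars = c(0, 1)), "range")
})

test_that("the variance kernel reports second-moment differences", {
  fm <- 1000 / 30
  # chosen-side values +-0.2 (second moment 0.04), unchosen +-0.1 (0.01)
  trials <- list(
    make_trial(matrix(0.2, 1, 4), matrix(0.1, 1, 4), "left", 3 * fm + 250),
    make_trial(matrix(-0.2, 1, 4), matrix(-0.1, 1, 4), "left", 3 * fm + 250)
  )
  vk <- variance_kernel(trials, max_lag = 1, min_count = 1)
  expect_equal(vk$kernel[1, ], c(0.03, 0.03))
  expect_identical(vk$statistic, "variance")
})

test_that("reaction-time groups span the documented percentile windows", {
  fm <- 1000 / 30
  trials <- lapply(1:100, function(i)
    make_trial(matrix(0, 1, 120), matrix(0, 1, 120), "left",
               rt = 400 + i * 10))
  short <- rt_split(trials, "short")
  inter <- rt_split(trials, "intermediate")
  long <- rt_split(trials, "long")
  expect_identical(length(short), 50L)
  expect_identical(length(inter), 50L)
  expect_identical(length(long), 50L)
  rt_of <- function(ts) sort(vapply(ts, `[[`, 0, "rt"))
  expect_identical(length(intersect(rt_of(short), rt_of(inter))), 25L)
  expect_identical(length(intersect(rt_of(inter), rt_of(long))), 25L)
  expect_identical(length(intersect(rt_of(short), rt_of(long))), 0L)
  # order invariance
  perm <- sample(seq_along(trials))
  expect_setequal(rt_of(rt_split(trials[perm], "short")), rt_of(short))
  expect_error(rt_split(trials[1:3], "short"), "at least 4")
})

test_that("the reaction-time split is computed within each ramp condition", {
  fm <- 1000 / 30
  slow <- lapply(1:20, function(i)
    make_trial(matrix(0, 1, 120), matrix(0, 1, 120), "left",
               rt = 3000 + i * 10, alpha = 0.05))
  fast <- lapply(1:20, function(i)
    make_trial(matrix(0, 1, 120), matrix(0, 1, 120), "left",
               rt = 500 + i * 10, alpha = 0.2))
  short <- rt_split(c(slow, fast), "short")
  alphas <- vapply(short, `[[`, 0, "alpha")
  # a pooled split would put every fast-condition trial in the short group
  expect_identical(sum(alphas == 0.05), 10L)
  expect_identical(sum(alphas == 0.2), 10L)
})

test_that("reaction-time summaries report log and linear means and an ecdf", {
  fm <- 1000 / 30
  trials <- list(
    make_trial(matrix(0, 1, 120), matrix(0, 1, 120), "left", 1000),
    make_trial(matrix(0, 1, 120), matrix(0, 1, 120), "left", 4000)
  )
  s <- rt_summary(trials)
  expect_equal(s$table$geo_mean_rt, 2000)       # exp(mean(log rt))
  expect_equal(s$table$mean_log_rt, log(2000))
  expect_equal(s$table$mean_rt, 2500)
  expect_equal(s$table$n, 2L)
  cum <- s$cumulative[, 1]
  expect_true(all(diff(cum) >= 0))
  expect_equal(cum[length(cum)], 1)
  expect_error(rt_summary(list()), "no usable")
})

test_that("across-observer averaging returns mean and standard error", {
  t1 <- null_trials(30, n_bars = 3, n_frames = 25, seed = 1)
  t2 <- null_trials(30, n_bars = 3, n_frames = 25, seed = 2)
  a <- response_locked_kernel(t1, max_lag = 5, min_count = 3)
  b <- response_locked_kernel(t2, max_lag = 5, min_count = 3)
  avg <- average_kernels(list(a, b))
  expect_equal(avg$kernel, (a$kernel + b$kernel) / 2)
  # sd of two values is |a - b| / sqrt(2); se divides by sqrt(2) again
  expect_equal(avg$se, abs(a$kernel - b$kernel) / 2)
})
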