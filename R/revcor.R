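#' Response-locked classification image
#'
#' Reverse correlation locked to the response: for each look-back lag, the
#' mean noise-only contrast on the chosen (target) side minus the mean on the
#' unchosen side, `mu1(x, lag) - mu0(x, lag)`, over correct non-timeout
#' trials. Right-target trials are mirrored onto a canonical orientation by
#' the chosen/unchosen assignment itself. Lag 0 is the noise frame during
#' which the decision was committed, recovered from the recorded reaction
#' time by subtracting the motor delay (`frame = round((rt - motor_delay) /
#' frame_ms)`); the lag axis is reported in ms before the button press,
#' `lag * frame_ms + motor_delay`. A trial contributes to a lag only if its
#' response frame is at least that many frames from onset, so per-lag trial
#' counts shrink as the look-back grows; cells with fewer than `min_count`
#' contributing trials are masked to `NA`.
#'
#' @param trials a `trial_set` (or plain list of `trial_record`s) carrying
#'   noise matrices.
#' @param max_lag largest look-back in frames; the kernel has `max_lag + 1`
#'   lag columns.
#' @param min_count minimum trials per lag; sparser lags are masked.
#' @param motor_delay ms subtracted from the reaction time to locate the
#'   decision frame (and added back on the reported lag axis).
#' @param statistic `"mean"` for the classification image proper,
#'   `"variance"` for the second-moment (contrast-variance) kernel.
#' @return an object of class `classification_image`: `kernel`
#'   (`n_bars x (max_lag + 1)`), `mu1`, `mu0`, `n_trials_per_lag`, `lag_ms`,
#'   `space_axis`, `statistic`, `n_trials_used`.
#' @export
response_locked_kernel <- function(trials, max_lag = 36L, min_count = 10L,
                                   motor_delay = 250,
                                   statistic = c("mean", "variance")) {
  statistic <- match.arg(statistic)
  if (length(trials) == 0L) stop("empty trial set")
  keep <- Filter(function(tr) isTRUE(tr$correct) && !tr$timeout, trials)
  if (length(keep) == 0L)
    stop("no usable trials (all are errors or timeouts)")
  if (is.null(keep[[1L]]$noise_left))
    stop("trials carry no noise record (simulate with keep_noise = TRUE)")
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop("'max_lag' must be at least 1")
  nb <- nrow(keep[[1L]]$noise_left)
  nf <- ncol(keep[[1L]]$noise_left)
  frame_ms <- keep[[1L]]$frame_ms
  nl <- max_lag + 1L
  sum1 <- matrix(0, nb, nl)
  sum0 <- matrix(0, nb, nl)
  count <- integer(nl)
  lags <- 0:max_lag
  sq <- statistic == "variance"
  for (tr in keep) {
    rf <- as.integer(round((tr$rt - motor_delay) / frame_ms))
    rf <- min(rf, nf)
    if (rf < 1L) next
    cols <- rf - lags
    ok <- cols >= 1L
    chosen <- if (tr$choice == "left") tr$noise_left else tr$noise_right
    unchosen <- if (tr$choice == "left") tr$noise_right else tr$noise_left
    c1 <- chosen[, cols[ok], drop = FALSE]
    c0 <- unchosen[, cols[ok], drop = FALSE]
    if (sq) {
      c1 <- c1^2
      c0 <- c0^2
    }
    sum1[, ok] <- sum1[, ok] + c1
    sum0[, ok] <- sum0[, ok] + c0
    count[ok] <- count[ok] + 1L
  }
  if (all(count == 0L)) stop("no trial contributed to any lag")
  mu1 <- sweep(sum1, 2L, pmax(count, 1L), "/")
  mu0 <- sweep(sum0, 2L, pmax(count, 1L), "/")
  masked <- count < min_count
  mu1[, masked] <- NA_real_
  mu0[, masked] <- NA_real_
  structure(list(
    kernel = mu1 - mu0, mu1 = mu1, mu0 = mu0,
    n_trials_per_lag = count,
    lag_ms = lags * frame_ms + motor_delay,
    space_axis = seq_len(nb),
    statistic = statistic,
    n_trials_used = length(keep),
    motor_delay = motor_delay, frame_ms = frame_ms
  ), class = "classification_image")
}

#' Contrast-variance kernel
#'
#' Response-locked kernel of second moments: mean squared noise contrast on
#' the chosen side minus the unchosen side, per bar per lag. A side analysis
#' probing sensitivity to local contrast energy rather than signed luminance.
#'
#' @inheritParams response_locked_kernel
#' @return a `classification_image` with `statistic = "variance"`.
#' @export
variance_kernel <- function(trials, max_lag = 36L, min_count = 10L,
                            motor_delay = 250) {
  response_locked_kernel(trials, max_lag, min_count, motor_delay,
                         statistic = "variance")
}

#' @export
print.classification_image <- function(x, ...) {
  cat(sprintf("response-locked %s kernel: %d bars x %d lags (%g-%g ms before response), %d trials\n",
              x$statistic, nrow(x$kernel), ncol(x$kernel), min(x$lag_ms),
              max(x$lag_ms), x$n_trials_used))
  invisible(x)
}

#' @export
plot.classification_image <- function(x, ...) {
  z <- t(x$kernel[, rev(seq_len(ncol(x$kernel))), drop = FALSE])
  graphics::image(x = rev(-x$lag_ms), y = x$space_axis, z = z,
                  col = grDevices::gray.colors(65, 0, 1),
                  xlab = "time from response (ms)", ylab = "bar", ...)
  invisible(x)
}

#' Impact curves
#'
#' Lag-wise means of the classification image over designated bar sets: the
#' central bars (where the target appears) and their immediate flankers. The
#' central curve of a detection observer is characteristically biphasic --
#' positive weight close to the response, negative weight further back.
#'
#' @param ci a [response_locked_kernel()] result.
#' @param central_bars,adjacent_bars disjoint 1-based bar index sets;
#'   defaults are the two central bars and their outer neighbors.
#' @return an object of class `impact_curves`: `central`, `adjacent`,
#'   `lag_ms`, plus the bar sets used.
#' @export
impact_curves <- function(ci, central_bars = NULL, adjacent_bars = NULL) {
  stopifnot(inherits(ci, "classification_image"))
  nb <- nrow(ci$kernel)
  if (is.null(central_bars)) central_bars <- c(nb %/% 2L, nb %/% 2L + 1L)
  if (is.null(adjacent_bars))
    adjacent_bars <- c(min(central_bars) - 1L, max(central_bars) + 1L)
  central_bars <- as.integer(central_bars)
  adjacent_bars <- as.integer(adjacent_bars)
  if (length(intersect(central_bars, adjacent_bars)) > 0L)
    stop("'central_bars' and 'adjacent_bars' must be disjoint")
  if (any(c(central_bars, adjacent_bars) < 1L) ||
      any(c(central_bars, adjacent_bars) > nb))
    stop("bar indices out of range")
  structure(list(
    central = colMeans(ci$kernel[central_bars, , drop = FALSE]),
    adjacent = colMeans(ci$kernel[adjacent_bars, , drop = FALSE]),
    lag_ms = ci$lag_ms,
    central_bars = central_bars, adjacent_bars = adjacent_bars
  ), class = "impact_curves")
}

#' @export
print.impact_curves <- function(x, ...) {
  i <- which.max(x$central)
  cat(sprintf("impact curves over %d lags; central peak %.4g at %.0f ms before response\n",
              length(x$lag_ms), x$central[i], x$lag_ms[i]))
  invisible(x)
}

#' @export
plot.impact_curves <- function(x, ...) {
  rng <- range(c(x$central, x$adjacent), na.rm = TRUE)
  graphics::plot(-x$lag_ms, x$central, type = "l", col = "red", ylim = rng,
                 xlab = "time from response (ms)", ylab = "weight", ...)
  graphics::lines(-x$lag_ms, x$adjacent, col = "blue")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", c("central", "adjacent"), lty = 1,
                   col = c("red", "blue"), bty = "n")
  invisible(x)
}

#' Reaction-time split
#'
#' Selects the trials in one of three overlapping reaction-time windows --
#' short (percentiles 0-50), intermediate (25-75) or long (50-100) -- so each
#' group holds 50% of the usable trials. The split is computed within each
#' ramp-rate (`alpha`) condition separately; ordering is by reaction time
#' with ties broken by trial position, so group membership is invariant to
#' input order.
#'
#' @param trials a `trial_set` or list of `trial_record`s.
#' @param group `"short"`, `"intermediate"` or `"long"`.
#' @param by_alpha split within each alpha condition (default) or pooled.
#' @return a `trial_set` containing the selected trials.
#' @export
rt_split <- function(trials, group = c("short", "intermediate", "long"),
                     by_alpha = TRUE) {
  group <- match.arg(group)
  usable <- which(vapply(trials, function(tr) !tr$timeout, TRUE))
  if (length(usable) < 4L) stop("need at least 4 usable trials to split")
  alphas <- vapply(trials, `[[`, 0, "alpha")
  rts <- vapply(trials, `[[`, 0, "rt")
  pick <- integer(0)
  conditions <- if (by_alpha) unique(alphas[usable]) else NA_real_
  for (a in conditions) {
    idx <- if (by_alpha) usable[alphas[usable] == a] else usable
    if (length(idx) < 4L)
      stop(sprintf("fewer than 4 usable trials in condition alpha = %g", a))
    ord <- idx[order(rts[idx], idx)]
    n <- length(ord)
    ns <- round(n / 2)
    window <- switch(group,
                     short = seq_len(ns),
                     long = (n - ns + 1L):n,
                     intermediate = (round(n / 4) + 1L):(round(n / 4) + ns))
    pick <- c(pick, ord[window])
  }
  as_trial_set(trials[sort(pick)])
}

#' Reaction-time summaries
#'
#' Per ramp-rate condition: trial counts, arithmetic mean of log reaction
#' time with its geometric-mean back-transform, linear-scale mean with
#' standard error, and an empirical cumulative RT distribution on a fixed
#' millisecond grid. Timeout trials are excluded.
#'
#' @param trials a `trial_set` or list of `trial_record`s.
#' @param grid evaluation grid (ms) for the cumulative distribution.
#' @return list with `table` (a data.frame: `alpha`, `n`, `mean_log_rt`,
#'   `geo_mean_rt`, `mean_rt`, `se_rt`) and `cumulative` (matrix of
#'   cumulative proportions, one column per alpha, rows on `grid`).
#' @export
rt_summary <- function(trials, grid = seq(0, 8000, by = 50)) {
  usable <- Filter(function(tr) !tr$timeout, trials)
  if (length(usable) == 0L) stop("no usable (non-timeout) trials")
  alphas <- vapply(usable, `[[`, 0, "alpha")
  rts <- vapply(usable, `[[`, 0, "rt")
  levels <- sort(unique(alphas))
  tab <- do.call(rbind, lapply(levels, function(a) {
    r <- rts[alphas == a]
    data.frame(alpha = a, n = length(r), mean_log_rt = mean(log(r)),
               geo_mean_rt = exp(mean(log(r))), mean_rt = mean(r),
               se_rt = stats::sd(r) / sqrt(length(r)))
  }))
  cum <- vapply(levels, function(a) {
    f <- stats::ecdf(rts[alphas == a])
    f(grid)
  }, numeric(length(grid)))
  cum <- matrix(cum, nrow = length(grid),
                dimnames = list(NULL, paste0("alpha_", levels)))
  list(table = tab, cumulative = cum, grid = grid)
}

#' Average kernels across observers
#'
#' Unweighted mean of per-observer classification images (lags must match),
#' with the across-observer standard error per cell.
#'
#' @param cis list of `classification_image`s with identical shapes.
#' @return a `classification_image` whose `kernel` is the across-observer
#'   mean, with an extra `se` matrix.
#' @export
average_kernels <- function(cis) {
  stopifnot(length(cis) >= 1L,
            all(vapply(cis, inherits, TRUE, "classification_image")))
  dims <- lapply(cis, function(ci) dim(ci$kernel))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("kernels must share a shape")
  arr <- simplify2array(lapply(cis, `[[`, "kernel"))
  out <- cis[[1L]]
  out$kernel <- apply(arr, c(1L, 2L), mean)
  out$se <- apply(arr, c(1L, 2L), stats::sd) / sqrt(length(cis))
  out$mu1 <- out$mu0 <- NULL
  out$n_trials_used <- sum(vapply(cis, `[[`, 0L, "n_trials_used"))
  out
}
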