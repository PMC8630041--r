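# small, fast study objects used across the suite

quick_config <- function(alpha = 0.2, duration = 3000, ...) {
  stimulus_config(alpha = alpha, duration = duration, ...)
}

# a hand-built trial record for kernel tests; noise matrices are bar x frame
make_trial <- function(noise_left, noise_right, choice, rt,
                       target_side = choice, alpha = 0.05,
                       frame_ms = 1000 / 30, timeout = FALSE) {
  structure(list(
    noise_left = noise_left, noise_right = noise_right, alpha = alpha,
    target_side = target_side, choice = choice,
    rt = if (timeout) NA_real_ else rt,
    correct = !timeout && choice == target_side, timeout = timeout,
    crossing_frame = NA_integer_, frame_ms = frame_ms,
    stimulus_seed = 0L, noise_seed = 0L
  ), class = "trial_record")
}

# random trial records whose choices are independent of the noise: the null
# case for classification images
null_trials <- function(n, n_bars = 4, n_frames = 30, seed = 1,
                        rt_frames = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    side <- sample(c("left", "right"), 1)
    rf <- if (is.null(rt_frames)) sample(10:n_frames, 1) else rt_frames
    make_trial(matrix(rnorm(n_bars * n_frames, 0, 0.1), n_bars),
               matrix(rnorm(n_bars * n_frames, 0, 0.1), n_bars),
               choice = side, rt = rf * 1000 / 30 + 250)
  })
}

# brute-force per-cell group-mean kernel: the independent oracle for
# response_locked_kernel, written as plain nested loops
oracle_kernel <- function(trials, max_lag, min_count, motor_delay = 250) {
  keep <- Filter(function(tr) isTRUE(tr$correct) && !tr$timeout, trials)
  nb <- nrow(keep[[1]]$noise_left)
  kernel <- matrix(NA_real_, nb, max_lag + 1)
  counts <- integer(max_lag + 1)
  for (lag in 0:max_lag) {
    vals1 <- NULL
    vals0 <- NULL
    for (tr in keep) {
      rf <- round((tr$rt - motor_delay) / tr$frame_ms)
      rf <- min(rf, ncol(tr$noise_left))
      col <- rf - lag
      if (col < 1) next
      ch <- if (tr$choice == "left") tr$noise_left else tr$noise_right
      un <- if (tr$choice == "left") tr$noise_right else tr$noise_left
      vals1 <- cbind(vals1, ch[, col])
      vals0 <- cbind(vals0, un[, col])
    }
    counts[lag + 1] <- if (is.null(vals1)) 0L else ncol(vals1)
    if (counts[lag + 1] >= min_count)
      kernel[, lag + 1] <- rowMeans(vals1) - rowMeans(vals0)
  }
  list(kernel = kernel, counts = counts)
}

# brute-force 2-D convolution of a field with the separable kernel: the
# independent O(N^2) oracle for filter_response
oracle_convolve <- function(field, params) {
  ns <- nrow(field)
  nf <- ncol(field)
  h <- temporal_kernel(params$n_stages, params$tau, params$B, max_len = nf)
  out <- matrix(0, ns, nf)
  for (x in seq_len(ns)) for (t in seq_len(nf)) {
    acc <- 0
    for (xs in seq_len(ns)) for (k in seq_along(h)) {
      ts <- t - (k - 1)
      if (ts >= 1)
        acc <- acc + field[xs, ts] *
          spatial_filter(x - xs, params$sigma_c, params$sigma_s) * h[k]
    }
    out[x, t] <- acc
  }
  out
}

# direct (non-recursive) evaluation of the leaky accumulator
oracle_accumulate <- function(delta_r, gamma, epsilon_draws,
                              leak_noise = TRUE) {
  n <- length(delta_r)
  vapply(seq_len(n), function(T) {
    w <- gamma^(T - seq_len(T))
    sum(w * delta_r[seq_len(T)]) +
      sum((if (leak_noise) w else 1) * epsilon_draws[seq_len(T)])
  }, 0)
}
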