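#' Model observer parameters
#'
#' The eight constants of the filter + leaky-accumulator observer, plus the
#' motor delay. The shipped defaults are fitted values for an observer performing the
#' detection task this package models. Spatial scales are in 0.04-deg
#' samples, temporal scales in 33.3-ms frames. The filters carry no free gain
#' (none appears in their definitions), so `bound` and `epsilon` are in
#' evidence units that are only interpretable relative to this fixed filter
#' normalization.
#'
#' @param sigma_c center SD of the spatial difference of Gaussians (samples).
#' @param sigma_s surround SD (samples); must exceed `sigma_c`.
#' @param n_stages integer order of the temporal filter cascade.
#' @param tau temporal filter time constant, in display-refresh units
#'   (16.7 ms; see [temporal_kernel()]).
#' @param B negative-phase amplitude ratio of the temporal filter (>= 0).
#' @param gamma per-frame leak rate of evidence integration, in `[0, 1)`:
#'   each frame the accumulated sensory evidence retains a fraction
#'   `1 - gamma`, so evidence of age `a` frames is weighted `(1 - gamma)^a`
#'   (0 = perfect integration; the default 0.046 gives a memory of about
#'   22 frames, 720 ms).
#' @param bound decision boundary `b` (> 0, evidence units); the observer
#'   chooses left/right when the accumulated evidence reaches `+b`/`-b`.
#' @param epsilon per-frame internal noise SD (evidence units).
#' @param motor_delay fixed non-decision time in ms added to the boundary
#'   crossing time to give the recorded reaction time.
#' @return an object of class `model_params`.
#' @export
model_params <- function(sigma_c = 4.15, sigma_s = 17.4, n_stages = 5L,
                         tau = 1.360, B = 0.47, gamma = 0.046,
                         bound = 496.5, epsilon = 49.6, motor_delay = 250) {
  p <- list(sigma_c = sigma_c, sigma_s = sigma_s,
            n_stages = as.integer(n_stages), tau = tau, B = B, gamma = gamma,
            bound = bound, epsilon = epsilon, motor_delay = motor_delay)
  msg <- validate_params(p)
  if (!is.null(msg)) stop(msg)
  structure(p, class = "model_params")
}

# returns NULL if valid, else a message; used both by the constructor and by
# the fitting objective (which penalizes rather than throws)
validate_params <- function(p) {
  if (!all(vapply(p, function(v) is.numeric(v) && all(is.finite(v)), TRUE)))
    return("all parameters must be finite numbers")
  if (!(p$sigma_c > 0 && p$sigma_s > p$sigma_c))
    return("require sigma_s > sigma_c > 0")
  if (!(p$tau > 0)) return("'tau' must be positive")
  if (p$B < 0) return("'B' must be nonnegative")
  if (!(p$gamma >= 0 && p$gamma < 1)) return("'gamma' must be in [0, 1)")
  if (!(p$bound > 0)) return("'bound' must be positive")
  if (p$epsilon < 0) return("'epsilon' must be nonnegative")
  if (p$n_stages < 1L) return("'n_stages' must be a positive integer")
  if (p$motor_delay < 0) return("'motor_delay' must be nonnegative")
  NULL
}

#' @export
print.model_params <- function(x, ...) {
  cat("Filter + leaky-accumulator observer parameters\n")
  cat(sprintf("  spatial DoG: sigma_c = %g, sigma_s = %g samples\n",
              x$sigma_c, x$sigma_s))
  cat(sprintf("  temporal: n = %d stages, tau = %g frames, B = %g\n",
              x$n_stages, x$tau, x$B))
  cat(sprintf("  decision: gamma = %g, bound = %g, epsilon = %g, motor delay %g ms\n",
              x$gamma, x$bound, x$epsilon, x$motor_delay))
  invisible(x)
}

#' Differential sensory evidence
#'
#' Momentary evidence for "target on the left": the difference between the
#' spatial sums of absolute filter responses in the two fields,
#' `sum_x |R_left(x, t)| - sum_x |R_right(x, t)|`.
#'
#' @param r_left,r_right response matrices of identical shape
#'   (space x frames).
#' @param t optional frame index (or vector of indices); default all frames.
#' @return evidence value(s) `dR(t)`.
#' @export
differential_evidence <- function(r_left, r_right, t = NULL) {
  if (!identical(dim(r_left), dim(r_right)))
    stop("'r_left' and 'r_right' must share a shape")
  dr <- colSums(abs(r_left)) - colSums(abs(r_right))
  if (is.null(t)) dr else dr[t]
}

#' Leaky accumulation of evidence
#'
#' Accumulated evidence
#' `S(T) = sum_{t=1}^{T} gamma^(T-t) (dR(t) + eps_t)`,
#' with `eps_t ~ Normal(0, epsilon^2)`: sensory evidence plus internal noise,
#' exponentially discounted with age. Computed by the equivalent recursion
#' `D(T) = gamma D(T-1) + dR(T)`, `N(T) = gamma N(T-1) + eps_T`, `S = D + N`.
#' Setting `leak_noise = FALSE` switches to the variant in which only the
#' evidence is discounted and the internal noise accumulates as an
#' undiscounted random walk, `S(T) = sum_t (gamma^(T-t) dR(t) + eps_t)`.
#'
#' Note the argument `gamma` here is the per-frame *retention* factor
#' appearing as `gamma^(T-t)`; the observer simulation passes
#' `1 - leak rate`, i.e. `1 -` the `gamma` field of [model_params()].
#'
#' @param delta_r per-frame evidence series `dR(t)`.
#' @param gamma retention factor in (0, 1].
#' @param epsilon internal noise SD per frame (>= 0).
#' @param seed integer seed for the noise draws; ignored when `noise` is
#'   supplied.
#' @param noise optional pre-drawn internal-noise vector (same length as
#'   `delta_r`), for mirrored or common-random-number simulations.
#' @param bound optional decision boundary; when given, the first frame at
#'   which `|S| >= bound` is reported.
#' @param leak_noise logical; discount the internal noise with the same leak
#'   as the evidence (default) or accumulate it as an undiscounted random
#'   walk.
#' @return an object of class `evidence_trace`: list with `delta_r`, `s`,
#'   `noise` and `crossing_frame` (`NA` if `bound` is `NULL` or never
#'   reached).
#' @export
accumulate_evidence <- function(delta_r, gamma, epsilon, seed = NULL,
                                noise = NULL, bound = NULL,
                                leak_noise = TRUE) {
  if (!(gamma > 0 && gamma <= 1)) stop("'gamma' must be in (0, 1]")
  if (epsilon < 0) stop("'epsilon' must be nonnegative")
  n <- length(delta_r)
  if (is.null(noise)) {
    if (!is.null(seed)) set.seed(seed)
    noise <- stats::rnorm(n, 0, epsilon)
  }
  if (length(noise) != n) stop("'noise' must match 'delta_r' in length")
  d <- as.numeric(stats::filter(delta_r, gamma, method = "recursive"))
  nn <- if (leak_noise)
    as.numeric(stats::filter(noise, gamma, method = "recursive"))
  else cumsum(noise)
  s <- d + nn
  crossing <- NA_integer_
  if (!is.null(bound)) {
    hit <- match(TRUE, abs(s) >= bound)
    if (!is.na(hit)) crossing <- hit
  }
  structure(list(delta_r = delta_r, s = s, noise = noise,
                 crossing_frame = crossing),
            class = "evidence_trace")
}

#' Simulate one trial of the model observer
#'
#' Runs the full front end (rasterization, separable spatiotemporal
#' filtering, absolute-value spatial pooling, left-minus-right differencing)
#' and the leaky accumulator on one stimulus movie. The observer commits to
#' "left" at the first frame `T` with `S(T) >= bound` and to "right" at
#' `S(T) <= -bound`; the recorded reaction time is
#' `T * (1000 / frame_rate) + motor_delay` ms. Trials with no crossing within
#' the stimulus, or whose reaction time would exceed the response deadline
#' (the stimulus duration), are timeouts and carry no reaction time.
#'
#' @param movie a [compose_trial_stimulus()] result.
#' @param params a [model_params()].
#' @param seed integer seed for the internal noise.
#' @param leak_noise see [accumulate_evidence()].
#' @param keep_noise logical; retain the bar-noise matrices in the record
#'   (required for classification-image analysis).
#' @return an object of class `trial_record`: `noise_left`, `noise_right`,
#'   `alpha`, `target_side`, `choice` (`"left"`, `"right"` or `"timeout"`),
#'   `rt` (ms, `NA` on timeout), `correct`, `timeout`, `crossing_frame`,
#'   `frame_ms`, `stimulus_seed`, `noise_seed`.
#' @export
simulate_trial <- function(movie, params, seed, leak_noise = TRUE,
                           keep_noise = TRUE) {
  stopifnot(inherits(movie, "stimulus_movie"))
  fields <- rasterize_to_samples(movie, "contrast")
  r_left <- filter_response(fields$left, params)
  r_right <- filter_response(fields$right, params)
  dr <- differential_evidence(r_left, r_right)
  set.seed(seed)
  eps <- stats::rnorm(length(dr), 0, params$epsilon)
  trace <- accumulate_evidence(dr, 1 - params$gamma, params$epsilon,
                               noise = eps, bound = params$bound,
                               leak_noise = leak_noise)
  finish_trial(movie, params, trace$crossing_frame,
               if (is.na(trace$crossing_frame)) NA_real_
               else trace$s[trace$crossing_frame],
               seed, keep_noise)
}

finish_trial <- function(movie, params, crossing, s_at_crossing, noise_seed,
                         keep_noise) {
  cfg <- movie$config
  rt <- NA_real_
  choice <- "timeout"
  if (!is.na(crossing)) {
    rt_cand <- crossing * cfg$frame_ms + params$motor_delay
    if (rt_cand <= cfg$duration) {
      rt <- rt_cand
      choice <- if (s_at_crossing >= params$bound) "left" else "right"
    }
  }
  timeout <- choice == "timeout"
  structure(list(
    noise_left = if (keep_noise) movie$noise_left else NULL,
    noise_right = if (keep_noise) movie$noise_right else NULL,
    alpha = movie$alpha, target_side = movie$target_side,
    choice = choice, rt = if (timeout) NA_real_ else rt,
    correct = !timeout && choice == movie$target_side,
    timeout = timeout,
    crossing_frame = if (timeout) NA_integer_ else as.integer(crossing),
    frame_ms = cfg$frame_ms,
    stimulus_seed = movie$seed, noise_seed = noise_seed
  ), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("trial: target %s, alpha %g -> %s%s\n", x$target_side, x$alpha,
              x$choice,
              if (x$timeout) "" else sprintf(" at %.0f ms (%s)", x$rt,
                                             if (x$correct) "correct" else "error")))
  invisible(x)
}

#' Simulate a full experiment
#'
#' Batch of independent trials with counterbalanced random target sides.
#' Per-trial stimulus and internal-noise seeds are derived deterministically
#' from the master seed, so the whole experiment is reproducible. Internally
#' the trials are filtered and accumulated in blocked matrix operations; the
#' result is identical (to floating-point roundoff) to running
#' [simulate_trial()] trial by trial.
#'
#' @param config a [stimulus_config()].
#' @param params a [model_params()].
#' @param n_trials number of trials (> 0).
#' @param seed master integer seed.
#' @param leak_noise see [accumulate_evidence()].
#' @param keep_noise retain bar-noise matrices per trial (needed for kernels).
#' @param chunk_size trials per internal block (memory/speed trade-off).
#' @return a `trial_set`: list of `trial_record`s with a `summary` attribute
#'   (trial, error, timeout counts and mean rt).
#' @export
simulate_experiment <- function(config, params, n_trials, seed,
                                leak_noise = TRUE, keep_noise = TRUE,
                                chunk_size = 256L) {
  stopifnot(inherits(config, "stimulus_config"), inherits(params, "model_params"))
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("'n_trials' must be positive")
  set.seed(seed)
  sides <- sample(rep(c("left", "right"), length.out = n_trials))
  stim_seeds <- sample.int(.Machine$integer.max, n_trials)
  noise_seeds <- sample.int(.Machine$integer.max, n_trials)
  trials <- vector("list", n_trials)
  for (start in seq(1L, n_trials, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n_trials)
    movies <- lapply(idx, function(i)
      compose_trial_stimulus(config, sides[i], stim_seeds[i]))
    eps <- internal_noise_matrix(noise_seeds[idx], config$n_frames,
                                 params$epsilon)
    res <- simulate_batch(movies, params, eps, leak_noise)
    for (j in seq_along(idx)) {
      trials[[idx[j]]] <- finish_trial(movies[[j]], params, res$crossing[j],
                                       res$s_at_crossing[j],
                                       noise_seeds[idx[j]], keep_noise)
    }
  }
  as_trial_set(trials)
}

as_trial_set <- function(trials) {
  structure(trials, class = "trial_set", summary = summarize_trials(trials))
}

summarize_trials <- function(trials) {
  choice <- vapply(trials, `[[`, "", "choice")
  correct <- vapply(trials, `[[`, TRUE, "correct")
  rt <- vapply(trials, `[[`, 0, "rt")
  data.frame(
    n_trials = length(trials),
    n_correct = sum(correct),
    n_error = sum(choice != "timeout" & !correct),
    n_timeout = sum(choice == "timeout"),
    mean_rt = mean(rt[choice != "timeout"])
  )
}

#' @export
print.trial_set <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("trial set: %d trials (%d correct, %d error, %d timeout), mean rt %.0f ms\n",
              s$n_trials, s$n_correct, s$n_error, s$n_timeout, s$mean_rt))
  invisible(x)
}

#' Coerce a trial set to a data frame
#'
#' One row per trial with the log columns (`trial_id`, `alpha`,
#' `target_side`, `choice`, `rt_ms`, `correct`, `timeout`, `stimulus_seed`,
#' `noise_seed`); noise matrices are dropped.
#' @param x a `trial_set`.
#' @param ... unused.
#' @export
as.data.frame.trial_set <- function(x, ...) {
  data.frame(
    trial_id = seq_along(x),
    alpha = vapply(x, `[[`, 0, "alpha"),
    target_side = vapply(x, `[[`, "", "target_side"),
    choice = vapply(x, `[[`, "", "choice"),
    rt_ms = vapply(x, `[[`, 0, "rt"),
    correct = vapply(x, `[[`, TRUE, "correct"),
    timeout = vapply(x, `[[`, TRUE, "timeout"),
    stimulus_seed = vapply(x, `[[`, 0, "stimulus_seed"),
    noise_seed = vapply(x, `[[`, 0, "noise_seed")
  )
}

internal_noise_matrix <- function(seeds, n_frames, epsilon) {
  vapply(seeds, function(s) {
    set.seed(s)
    stats::rnorm(n_frames, 0, epsilon)
  }, numeric(n_frames))
}

# Blocked simulation engine. movies: list of stimulus_movie sharing a config;
# eps: n_frames x n_trials internal-noise matrix. Stacks all fields of all
# trials into one matrix so spatial and temporal convolutions are single BLAS
# products, then accumulates and detects boundary crossings per trial.
simulate_batch <- function(movies, params, eps, leak_noise = TRUE) {
  cfg <- movies[[1L]]$config
  nt <- length(movies)
  nf <- cfg$n_frames
  ns <- cfg$n_samples
  a <- spatial_conv_matrix(ns, params$sigma_c, params$sigma_s) %*%
    bar_sample_matrix(cfg$n_bars, ns)
  h <- temporal_kernel(params$n_stages, params$tau, params$B, max_len = nf)
  bt <- temporal_conv_operator(h, nf)
  # columns: trial 1 left frames, trial 1 right frames, trial 2 left, ...
  cbig <- matrix(unlist(lapply(movies, function(m)
    c(m$contrast_left, m$contrast_right))), nrow = cfg$n_bars)
  sp <- a %*% cbig                         # ns x (nf * 2nt)
  dim(sp) <- c(ns, nf, 2L * nt)
  sp <- aperm(sp, c(1L, 3L, 2L))           # ns x 2nt x nf
  dim(sp) <- c(ns * 2L * nt, nf)
  r <- abs(sp %*% bt)
  pooled <- rowsum(r, rep(seq_len(2L * nt), each = ns))  # 2nt x nf
  dr <- t(pooled[seq(1L, 2L * nt, by = 2L), , drop = FALSE] -
            pooled[seq(2L, 2L * nt, by = 2L), , drop = FALSE])  # nf x nt
  retention <- 1 - params$gamma
  d <- stats::filter(dr, retention, method = "recursive")
  nn <- if (leak_noise) stats::filter(eps, retention, method = "recursive")
  else apply(eps, 2L, cumsum)
  s <- matrix(as.numeric(d), nf) + matrix(as.numeric(nn), nf)
  hit <- abs(s) >= params$bound
  crossing <- first_crossing(hit)
  s_at <- ifelse(is.na(crossing), NA_real_,
                 s[cbind(pmax(crossing, 1L), seq_len(nt))])
  list(crossing = crossing, s_at_crossing = s_at)
}

# first TRUE row index per column of a logical matrix, NA if none
first_crossing <- function(hit) {
  idx <- max.col(t(hit), ties.method = "first")
  idx[!hit[cbind(idx, seq_len(ncol(hit)))]] <- NA_integer_
  as.integer(idx)
}
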