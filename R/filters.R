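#' Difference-of-Gaussians spatial filter
#'
#' Center-surround spatial weighting function
#' `exp(-x^2 / (2 sigma_c^2)) - (sigma_c^2 / sigma_s^2) * exp(-x^2 / (2 sigma_s^2))`,
#' the standard first-order approximation of a contrast detector's receptive
#' field. `x` is in spatial samples (0.04 deg per unit at the default
#' sampling density). The surround weight `sigma_c^2 / sigma_s^2` equalizes
#' the integrals of center and surround, so the filter has zero DC response
#' in the continuum limit.
#'
#' @param x spatial offset in samples; vectorized.
#' @param sigma_c center standard deviation (samples).
#' @param sigma_s surround standard deviation (samples); must exceed
#'   `sigma_c`.
#' @return filter weights; even in `x`, negative in the far surround.
#' @export
spatial_filter <- function(x, sigma_c, sigma_s) {
  if (!(sigma_c > 0) || !(sigma_s > sigma_c))
    stop("require sigma_s > sigma_c > 0")
  exp(-x^2 / (2 * sigma_c^2)) -
    (sigma_c^2 / sigma_s^2) * exp(-x^2 / (2 * sigma_s^2))
}

#' Biphasic temporal impulse response
#'
#' Cascaded-integrator impulse response
#' `(1/n! - B (t/tau)^2 / (n+2)!) * (t/tau)^n * exp(-t/tau)`,
#' a standard model of the transient temporal channel of early vision: an
#' early positive lobe followed, for `B > 0`, by a slower negative lobe. `t`
#' is in frames (33.3 ms per unit at 30 Hz).
#'
#' @param t time since impulse in frames (>= 0, causal); vectorized.
#' @param n_stages integer number of integration stages `n`.
#' @param tau time constant in frames.
#' @param B amplitude ratio of negative to positive phase (>= 0; 0 gives a
#'   monophasic gamma-shaped response).
#' @return filter weights; `temporal_filter(0, ...)` is 0.
#' @export
temporal_filter <- function(t, n_stages = 5L, tau, B) {
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be nonnegative (causal filter)")
  if (!(tau > 0)) stop("'tau' must be positive")
  if (B < 0) stop("'B' must be nonnegative")
  n <- as.integer(n_stages)
  if (n < 1L) stop("'n_stages' must be a positive integer")
  u <- t / tau
  (1 / factorial(n) - B * u^2 / factorial(n + 2)) * u^n * exp(-u)
}

#' Discrete temporal kernel, truncated where negligible
#'
#' Samples [temporal_filter()] at the noise-frame grid and truncates the
#' tail once all remaining weights fall below `rel_tol` of the peak
#' magnitude, bounding convolution cost.
#'
#' Two conventions of this package are applied here. First, the impulse
#' response is parameterized on the display-refresh time base (16.7 ms per
#' unit at the 60 Hz refresh the stimuli are shown at), while the noise --
#' and hence the evidence -- updates at 30 Hz, so the kernel takes every
#' `step = 2`nd refresh: tap `k` is `temporal_filter(step * k, ...)`.
#' Second, the kernel is normalized to unit peak gain (the peak of the
#' continuous impulse response, which is independent of `tau`), so filter
#' outputs are on the stimulus-contrast scale and the decision parameters
#' `bound` and `epsilon` are interpretable on that fixed scale.
#'
#' @inheritParams temporal_filter
#' @param max_len maximum kernel length in noise frames.
#' @param rel_tol relative truncation threshold.
#' @param step refresh units per noise frame.
#' @param normalize divide by the continuous response's peak magnitude.
#' @return numeric vector of taps, first element `t = 0` (always 0).
#' @export
temporal_kernel <- function(n_stages = 5L, tau, B, max_len = 240L,
                            rel_tol = 1e-6, step = 2, normalize = TRUE) {
  h <- temporal_filter(step * (seq_len(max_len) - 1), n_stages, tau, B)
  if (normalize) {
    peak <- max(temporal_filter(seq(0, (n_stages + 30) * tau, by = tau / 200),
                                n_stages, tau, B))
    h <- h / peak
  }
  keep <- which(abs(h) >= rel_tol * max(abs(h)))
  h[seq_len(if (length(keep)) max(keep) else 1L)]
}

spatial_conv_matrix <- function(n, sigma_c, sigma_s) {
  idx <- seq_len(n)
  spatial_filter(outer(idx, idx, "-"), sigma_c, sigma_s)
}

#' Space-time separable filter response
#'
#' Convolves a sample-contrast field with the separable spatiotemporal filter
#' (spatial difference of Gaussians times biphasic temporal impulse
#' response): zero-padded discrete convolution in space, causal convolution
#' in time. By separability this equals the full 2-D convolution. The
#' temporal kernel follows the conventions of [temporal_kernel()]
#' (refresh-unit parameterization sampled at noise frames, unit peak gain).
#'
#' @param field `n_samples x n_frames` contrast matrix (rows = space,
#'   columns = frames).
#' @param params a [model_params()] (or any list carrying `sigma_c`,
#'   `sigma_s`, `n_stages`, `tau`, `B`).
#' @return response matrix `R(x, t)` of the same shape.
#' @export
filter_response <- function(field, params) {
  if (!is.matrix(field)) stop("'field' must be a matrix (space x frames)")
  ts <- spatial_conv_matrix(nrow(field), params$sigma_c, params$sigma_s)
  h <- temporal_kernel(params$n_stages, params$tau, params$B,
                       max_len = ncol(field))
  temporal_convolve(ts %*% field, h)
}

# causal FIR convolution along columns: out[, t] = sum_k h[k+1] * x[, t - k]
temporal_convolve <- function(x, h) {
  nc <- ncol(x)
  out <- matrix(0, nrow(x), nc)
  for (k in seq_along(h)) {
    if (h[k] != 0)
      out[, k:nc] <- out[, k:nc] + h[k] * x[, seq_len(nc - k + 1L), drop = FALSE]
  }
  out
}

# banded lower-triangular temporal convolution operator, for the batched
# engine: (X %*% temporal_conv_operator(h, nf))[i, t] = sum_k h[k] X[i, t-k+1]
temporal_conv_operator <- function(h, n_frames) {
  b <- matrix(0, n_frames, n_frames)
  for (k in seq_along(h)) {
    if (h[k] != 0) {
      idx <- seq_len(n_frames - k + 1L)
      b[cbind(idx, idx + k - 1L)] <- h[k]
    }
  }
  b
}
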