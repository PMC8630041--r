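#' Stimulus configuration
#'
#' Describes one dynamic 1-D noise detection stimulus: two adjacent fields of
#' vertical bars whose contrasts refresh as independent Gaussian noise, one
#' field additionally carrying a luminance target whose log10 contrast ramps
#' linearly up to full contrast.
#'
#' @param n_bars number of vertical bars per field.
#' @param bar_width bar width in degrees of visual angle.
#' @param field_size side length of each square field in degrees; must equal
#'   `n_bars * bar_width`.
#' @param noise_rms RMS contrast of the bar noise (standard deviation of the
#'   Gaussian contrast draws).
#' @param frame_rate noise refresh rate in Hz.
#' @param duration stimulus duration in ms; `duration * frame_rate / 1000`
#'   must be a whole number of frames.
#' @param alpha ramp rate of the target's log10 contrast per frame.
#' @param mean_luminance mean background luminance in cd/m^2 (metadata only;
#'   all computation is on contrast).
#' @param samples_per_degree spatial sampling density used when rasterizing
#'   bars onto the pixel grid the filters are parameterized on.
#' @param target_bars 1-based indices of the bars carrying the target
#'   increment; defaults to the two central bars.
#'
#' @return an object of class `stimulus_config`.
#' @seealso [compose_trial_stimulus()], [simulate_experiment()]
#' @export
stimulus_config <- function(n_bars = 16L, bar_width = 0.3, field_size = 4.8,
                            noise_rms = 0.1, frame_rate = 30, duration = 8000,
                            alpha = 0.05, mean_luminance = 88.9,
                            samples_per_degree = 25, target_bars = NULL) {
  n_bars <- as.integer(n_bars)
  if (n_bars < 2L) stop("'n_bars' must be at least 2")
  if (!isTRUE(all.equal(n_bars * bar_width, field_size)))
    stop("'n_bars' * 'bar_width' must equal 'field_size'")
  if (noise_rms <= 0) stop("'noise_rms' must be positive")
  if (alpha <= 0) stop("'alpha' must be positive")
  n_frames <- duration * frame_rate / 1000
  if (!isTRUE(all.equal(n_frames, round(n_frames))))
    stop("'duration' must correspond to a whole number of frames")
  n_samples <- field_size * samples_per_degree
  if (!isTRUE(all.equal(n_samples, round(n_samples))))
    stop("'field_size' * 'samples_per_degree' must be a whole number")
  if (is.null(target_bars)) target_bars <- c(n_bars %/% 2L, n_bars %/% 2L + 1L)
  target_bars <- as.integer(target_bars)
  if (any(target_bars < 1L | target_bars > n_bars))
    stop("'target_bars' out of range")
  structure(list(
    n_bars = n_bars, bar_width = bar_width, field_size = field_size,
    noise_rms = noise_rms, frame_rate = frame_rate, duration = duration,
    alpha = alpha, mean_luminance = mean_luminance,
    samples_per_degree = samples_per_degree, target_bars = target_bars,
    n_frames = as.integer(round(n_frames)),
    n_samples = as.integer(round(n_samples)),
    frame_ms = 1000 / frame_rate
  ), class = "stimulus_config")
}

#' @export
print.stimulus_config <- function(x, ...) {
  cat("Dynamic 1-D noise stimulus configuration\n")
  cat(sprintf("  %d bars x %d frames (%g ms at %g Hz), field %g deg\n",
              x$n_bars, x$n_frames, x$duration, x$frame_rate, x$field_size))
  cat(sprintf("  noise RMS contrast %g, ramp rate alpha %g/frame, target bars %s\n",
              x$noise_rms, x$alpha, paste(x$target_bars, collapse = ",")))
  invisible(x)
}

#' Target contrast ramp
#'
#' Michelson contrast of the ramping target at frame `t` (0-based, counted
#' from stimulus onset): `10^min(alpha * t - 3, 0)`. The target starts at
#' contrast 1e-3 and saturates at 1 for `t >= 3 / alpha`.
#'
#' @param t frame index (>= 0); vectorized.
#' @param alpha ramp rate of log10 contrast per frame (> 0).
#' @return contrast values in (0, 1].
#' @export
target_contrast <- function(t, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number")
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be nonnegative")
  10^pmin(alpha * t - 3, 0)
}

#' Generate one field of bar noise
#'
#' Independent Gaussian contrast draws per bar per frame, mean 0, standard
#' deviation `config$noise_rms`, clipped to \[-1, 1\] (at the default RMS of
#' 0.1 the clip is never active in practice).
#'
#' @param config a [stimulus_config()].
#' @param seed integer seed; the same seed reproduces the field exactly.
#' @return a `n_bars x n_frames` contrast matrix.
#' @export
generate_noise_field <- function(config, seed) {
  stopifnot(inherits(config, "stimulus_config"))
  set.seed(seed)
  m <- matrix(stats::rnorm(config$n_bars * config$n_frames, 0, config$noise_rms),
              config$n_bars, config$n_frames)
  clip_contrast(m)
}

clip_contrast <- function(x) pmin(pmax(x, -1), 1)

#' Compose one trial's stimulus movie
#'
#' Draws two independent noise fields and adds the ramping target increment
#' to the designated target bars of the target side. The combined contrast is
#' clipped to \[-1, 1\]; the noise-only record is retained untouched, since
#' the reverse-correlation analysis correlates recorded noise (not
#' noise-plus-target) with responses.
#'
#' @param config a [stimulus_config()].
#' @param target_side `"left"` or `"right"`.
#' @param seed integer seed. Both fields' noise derives from this seed, so
#'   swapping `target_side` leaves the noise unchanged.
#' @return an object of class `stimulus_movie` with elements
#'   `contrast_left`, `contrast_right`, `noise_left`, `noise_right`,
#'   `target_side`, `alpha`, `seed`, `config`.
#' @export
compose_trial_stimulus <- function(config, target_side = c("left", "right"),
                                   seed) {
  stopifnot(inherits(config, "stimulus_config"))
  target_side <- match.arg(target_side)
  set.seed(seed)
  field_seeds <- sample.int(.Machine$integer.max, 2L)
  noise_left <- generate_noise_field(config, field_seeds[1L])
  noise_right <- generate_noise_field(config, field_seeds[2L])
  inc <- target_contrast(seq_len(config$n_frames) - 1, config$alpha)
  target <- matrix(0, config$n_bars, config$n_frames)
  target[config$target_bars, ] <- rep(inc, each = length(config$target_bars))
  if (target_side == "left") {
    contrast_left <- clip_contrast(noise_left + target)
    contrast_right <- noise_right
  } else {
    contrast_left <- noise_left
    contrast_right <- clip_contrast(noise_right + target)
  }
  structure(list(
    contrast_left = contrast_left, contrast_right = contrast_right,
    noise_left = noise_left, noise_right = noise_right,
    target_side = target_side, alpha = config$alpha, seed = seed,
    config = config
  ), class = "stimulus_movie")
}

#' Bar-to-sample rasterization matrix
#'
#' 0/1 matrix mapping `n_bars` bar contrasts onto `n_samples` equally spaced
#' spatial samples: sample `i` (0-based) takes the contrast of bar
#' `floor(i / (n_samples / n_bars))`. With 16 bars on 120 samples the bars
#' alternate between 7- and 8-sample widths.
#'
#' @param n_bars number of bars.
#' @param n_samples number of spatial samples across the field.
#' @return an `n_samples x n_bars` indicator matrix.
#' @export
bar_sample_matrix <- function(n_bars, n_samples) {
  ratio <- n_samples / n_bars
  bar_of <- pmin(floor((seq_len(n_samples) - 1) / ratio), n_bars - 1) + 1L
  m <- matrix(0, n_samples, n_bars)
  m[cbind(seq_len(n_samples), bar_of)] <- 1
  m
}

#' Rasterize a stimulus movie onto the sample grid
#'
#' Expands the bar-contrast matrices of both fields onto the spatial sample
#' grid the filters are parameterized on (0.04 deg per sample by default).
#' Averaging the samples within a bar returns the bar contrast exactly.
#'
#' @param movie a [compose_trial_stimulus()] result.
#' @param component `"contrast"` (noise + target, clipped) or `"noise"`
#'   (noise-only record).
#' @return list with `left` and `right` sample-contrast matrices
#'   (`n_samples x n_frames`).
#' @export
rasterize_to_samples <- function(movie, component = c("contrast", "noise")) {
  stopifnot(inherits(movie, "stimulus_movie"))
  component <- match.arg(component)
  cfg <- movie$config
  m <- bar_sample_matrix(cfg$n_bars, cfg$n_samples)
  if (component == "contrast")
    list(left = m %*% movie$contrast_left, right = m %*% movie$contrast_right)
  else
    list(left = m %*% movie$noise_left, right = m %*% movie$noise_right)
}
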