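test_that("differential evidence is the difference of absolute-response sums", {
  r_left <- matrix(c(3, -1), 2, 1)
  r_right <- matrix(c(1, 1), 2, 1)
  expect_equal(differential_evidence(r_left, r_right), 2)
  expect_equal(differential_evidence(r_right, r_left), -2)   # antisymmetry
  expect_equal(differential_evidence(r_left, r_left), 0)
  set.seed(4)
  a <- matrix(rnorm(12), 3)
  b <- matrix(rnorm(12), 3)
  expect_equal(differential_evidence(a, b), -differential_evidence(b, a))
  expect_equal(differential_evidence(a, b, t = 2),
               differential_evidence(a, b)[2])
  expect_error(differential_evidence(a, matrix(0, 2, 2)), "shape")
})

test_that("accumulation limit cases match closed forms", {
  set.seed(1)
  dr <- rnorm(40)
  # no leak, no noise: plain cumulative sum
  expect_equal(accumulate_evidence(dr, gamma = 1, epsilon = 0, seed = 1)$s,
               cumsum(dr))
  # constant input, geometric series: S(T) = c (1 - gamma^T) / (1 - gamma)
  for (g in c(0.3, 0.8, 0.954)) {
    s <- accumulate_evidence(rep(2.5, 30), gamma = g, epsilon = 0, seed = 1)$s
    expect_equal(s, 2.5 * (1 - g^seq_len(30)) / (1 - g))
  }
  expect_error(accumulate_evidence(dr, gamma = 0, epsilon = 1), "gamma")
  expect_error(accumulate_evidence(dr, gamma = 1.2, epsilon = 1), "gamma")
  expect_error(accumulate_evidence(dr, gamma = 0.5, epsilon = -1), "epsilon")
})

test_that("recursive accumulation equals the direct-sum oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    dr <- rnorm(50, sd = 3)
    eps <- rnorm(50)
    for (ln in c(TRUE, FALSE)) {
      got <- accumulate_evidence(dr, gamma = 0.954, epsilon = 1, noise = eps,
                                 leak_noise = ln)$s
      expect_equal(got, oracle_accumulate(dr, 0.954, eps, leak_noise = ln))
    }
  }
})

test_that("crossing detection reports the first boundary passage", {
  tr <- accumulate_evidence(c(1, 2, 4, -20, 1), gamma = 1, epsilon = 0,
                            seed = 1, bound = 5)
  expect_identical(tr$crossing_frame, 3L)      # s = 1, 3, 7, -13, -12
  tr2 <- accumulate_evidence(c(1, 1), gamma = 1, epsilon = 0, seed = 1,
                             bound = 50)
  expect_identical(tr2$crossing_frame, NA_integer_)
})

test_that("a zero-contrast stimulus with no internal noise times out", {
  cfg <- quick_config()
  mv <- compose_trial_stimulus(cfg, "left", seed = 2)
  mv$contrast_left[] <- 0
  mv$contrast_right[] <- 0
  rec <- simulate_trial(mv, model_params(epsilon = 0, bound = 1e6), seed = 1)
  expect_true(rec$timeout)
  expect_identical(rec$choice, "timeout")
  expect_true(is.na(rec$rt))
})

test_that("a strong target with no internal noise drives the correct choice", {
  # near-zero stimulus noise isolates the deterministic ramp drive
  cfg <- quick_config(alpha = 0.2, noise_rms = 1e-5)
  pars <- model_params(epsilon = 0, bound = 100)
  for (side in c("left", "right")) {
    rec <- simulate_trial(compose_trial_stimulus(cfg, side, seed = 5),
                          pars, seed = 1)
    expect_identical(rec$choice, side)
    expect_true(rec$correct)
  }
})

test_that("reaction time is the crossing frame plus the motor delay", {
  cfg <- quick_config()
  mv <- compose_trial_stimulus(cfg, "left", seed = 3)
  # near-zero bound: the first internal-noise draw crosses at frame 1
  rec <- simulate_trial(mv, model_params(bound = 1e-9), seed = 2)
  expect_identical(rec$crossing_frame, 1L)
  expect_equal(rec$rt, 1000 / 30 + 250)
  rec2 <- simulate_trial(mv, model_params(), seed = 2)
  if (!rec2$timeout)
    expect_equal(rec2$rt, rec2$crossing_frame * 1000 / 30 + 250)
})

test_that("late crossings beyond the response deadline become timeouts", {
  cfg <- quick_config()
  mv <- compose_trial_stimulus(cfg, "left", seed = 4)
  crossing <- cfg$n_frames  # worst case: crossing on the last frame
  expect_gt(crossing * cfg$frame_ms + 250, cfg$duration)
  rec <- rlci:::finish_trial(mv, model_params(), crossing, 500, 1L, TRUE)
  expect_true(rec$timeout)
  expect_true(is.na(rec$rt))
})

test_that("mirroring the stimulus flips the choice and preserves the rt", {
  cfg <- quick_config(alpha = 0.1)
  pars <- model_params()
  mv <- compose_trial_stimulus(cfg, "left", seed = 8)
  mirrored <- mv
  mirrored$contrast_left <- mv$contrast_right
  mirrored$contrast_right <- mv$contrast_left
  mirrored$noise_left <- mv$noise_right
  mirrored$noise_right <- mv$noise_left
  mirrored$target_side <- "right"
  # internal noise off so the (unmirrored) noise stream cannot break the
  # left/right antisymmetry of the evidence
  pars0 <- model_params(epsilon = 0, bound = 200)
  a <- simulate_trial(mv, pars0, seed = 1)
  b <- simulate_trial(mirrored, pars0, seed = 1)
  expect_false(a$timeout)
  expect_false(b$timeout)
  expect_identical(b$choice, setdiff(c("left", "right"), a$choice))
  expect_identical(a$rt, b$rt)
  expect_identical(a$correct, b$correct)
})

test_that("experiments are reproducible and counterbalanced", {
  cfg <- quick_config()
  pars <- model_params()
  tr1 <- simulate_experiment(cfg, pars, 10, seed = 6)
  tr2 <- simulate_experiment(cfg, pars, 10, seed = 6)
  expect_equal(tr1, tr2)
  sides <- vapply(tr1, `[[`, "", "target_side")
  expect_identical(sum(sides == "left"), 5L)
  df <- as.data.frame(tr1)
  expect_identical(nrow(df), 10L)
  expect_identical(df$target_side, sides)
})

test_that("the batched engine matches trial-by-trial simulation", {
  cfg <- quick_config(alpha = 0.1)
  pars <- model_params()
  n <- 8L
  batch <- simulate_experiment(cfg, pars, n, seed = 12, chunk_size = 3L)
  # rebuild the same per-trial seed stream and run the reference path
  set.seed(12)
  sides <- sample(rep(c("left", "right"), length.out = n))
  stim_seeds <- sample.int(.Machine$integer.max, n)
  noise_seeds <- sample.int(.Machine$integer.max, n)
  for (i in seq_len(n)) {
    ref <- simulate_trial(compose_trial_stimulus(cfg, sides[i], stim_seeds[i]),
                          pars, seed = noise_seeds[i])
    expect_identical(batch[[i]]$choice, ref$choice)
    expect_identical(batch[[i]]$crossing_frame, ref$crossing_frame)
    expect_equal(batch[[i]]$rt, ref$rt)
    expect_identical(batch[[i]]$noise_left, ref$noise_left)
  }
})

test_that("timeout probability is monotone in the decision bound", {
  cfg <- quick_config()
  huge <- simulate_experiment(cfg, model_params(bound = 1e12), 6, seed = 2)
  expect_true(all(vapply(huge, `[[`, TRUE, "timeout")))
  tiny <- simulate_experiment(cfg, model_params(bound = 1e-9), 6, seed = 2)
  expect_true(all(!vapply(tiny, `[[`, TRUE, "timeout")))
  expect_true(all(vapply(tiny, `[[`, 0L, "crossing_frame") == 1L))
})

test_that("parameter validation rejects inconsistent observers", {
  expect_error(model_params(sigma_c = 20), "sigma_s > sigma_c")
  expect_error(model_params(gamma = 1), "gamma")
  expect_error(model_params(gamma = -0.1), "gamma")
  expect_error(model_params(bound = 0), "bound")
  expect_error(model_params(epsilon = -1), "epsilon")
  expect_error(model_params(tau = 0), "tau")
  expect_error(model_params(B = -0.2), "B")
  expect_silent(model_params(gamma = 0))
})
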