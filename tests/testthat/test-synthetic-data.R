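test_that("a generated session satisfies the trial-table invariants", {
  cfg <- session_config(seed = 42)
  trials <- fixture_session(42)

  expect_equal(nrow(trials), 1024L)
  expect_equal(trials$trial_index, 0:1023)

  # counterbalancing: equal counts per (mu, sigma, duration) cell per block
  counts <- table(trials$block, trials$mu_deg, trials$sigma_deg,
                  trials$duration_ms)
  expect_true(all(counts == 4L))

  X <- feature_matrix(trials)
  expect_true(all(X > -pi / 2 & X <= pi / 2))

  # per-trial tolerance on mean and (population) SD, in degrees
  tilt <- X * 180 / pi
  m <- rowMeans(tilt)
  s <- sqrt(rowSums((tilt - m)^2) / 8)
  expect_true(all(abs(m - trials$mu_deg) <= cfg$tolerance_deg + 1e-9))
  expect_true(all(abs(s - trials$sigma_deg) <= cfg$tolerance_deg + 1e-9))

  expect_equal(trials$correct_category, ifelse(rowSums(X) > 0, "CW", "CCW"))
  expect_equal(trials$wraparound, rowSums(abs(X) > 0.79) > 0)

  # features are the signed acute difference of orientation from reference
  ori <- as.matrix(trials[, paste0("ori", 1:8, "_deg")])
  d <- ((ori - trials$reference_deg + 90) %% 180) - 90
  d[d == -90] <- 90
  expect_equal(X, unname(d * pi / 180), ignore_attr = TRUE)
})

test_that("generation is deterministic given a seed", {
  a <- generate_session(session_config(seed = 7, n_blocks = 2L,
                                       trials_per_block = 32L))
  b <- generate_session(session_config(seed = 7, n_blocks = 2L,
                                       trials_per_block = 32L))
  expect_identical(a, b)
})

test_that("fixed and variable reference sessions differ as designed", {
  fixed <- fixture_session(42)
  varied <- generate_session(session_config("variable_reference", seed = 43,
                                            n_blocks = 2L,
                                            trials_per_block = 64L))
  per_block_fixed <- tapply(fixed$reference_deg, fixed$block,
                            function(r) length(unique(r)))
  expect_true(all(per_block_fixed == 1L))
  per_block_var <- tapply(varied$reference_deg, varied$block,
                          function(r) length(unique(r)))
  expect_true(all(per_block_var == 64L))
})

test_that("invalid session configurations are rejected", {
  expect_error(session_config(sigma_levels_deg = c(8, -1)), "positive")
  expect_error(session_config(mu_levels_deg = numeric(0)), "non-empty")
  expect_error(session_config(trials_per_block = 100L), "multiple")
})

test_that("sample_trial enforces the tolerance and the category rule", {
  tr <- sample_trial(10, 8, reference_deg = 90, seed = 1)
  tilt <- feature_matrix(tr) * 180 / pi
  expect_lte(abs(mean(tilt) - 10), 1)
  expect_lte(abs(sqrt(mean((tilt - mean(tilt))^2)) - 8), 1)

  tr2 <- sample_trial(20, 16, reference_deg = 10, seed = 2)
  expect_identical(tr2$correct_category, "CW")

  # an infeasible tolerance hits the resample cap
  expect_error(sample_trial(10, 8, 0, tolerance_deg = 1e-6,
                            max_resample = 10L, seed = 3),
               "resampling cap")
})

test_that("tolerance resampling preserves the nominal tilt distribution", {
  # one (mu, sigma) cell, 10,000 trials: pooled mean and SD within 0.2 deg
  cfg <- session_config(mu_levels_deg = 10, sigma_levels_deg = 8,
                        duration_levels_ms = 500, n_blocks = 1L,
                        trials_per_block = 10000L, seed = 99)
  tilt <- feature_matrix(generate_session(cfg)) * 180 / pi
  expect_lt(abs(mean(tilt) - 10), 0.2)
  expect_lt(abs(sd(tilt) - 8), 0.2)
})

test_that("simulated choices follow the model's choice probabilities", {
  trials <- fixture_session(42)
  # deterministic limit: tiny late noise picks the dv sign
  ch <- simulate_observer(trials[1:64, ],
                          observer_params("power_late", k = 1, s = 1e-9),
                          seed = 1)
  expect_identical(ch$choice, trials$correct_category[1:64])
  expect_true(all(ch$correct))

  # accuracy matches the analytic Bernoulli mean within 3 Monte-Carlo SE
  params <- observer_params("power_late", k = 1, s = 0.5)
  big <- uniform_feature_design(10000, seed = 11)
  ch2 <- simulate_observer(big, params, seed = 12)
  cp <- choice_probability(power_dv(feature_matrix(big), 1), 0.5)
  p_correct <- ifelse(big$correct_category == "CW", cp, 1 - cp)
  oracle <- mean(p_correct)
  se <- sqrt(sum(p_correct * (1 - p_correct))) / nrow(big)
  expect_lt(abs(mean(ch2$correct) - oracle), 3 * se)

  # cp column stores the generating probability
  expect_equal(ch2$cp, cp)
  expect_error(simulate_observer(big, structure(list(model = "nope"),
                                               class = "observer_params")),
               "model")
})
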