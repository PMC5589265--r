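test_that("power transducer dv matches direct evaluation and a loop oracle", {
  x <- c(0.5, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(power_dv(x, 2), 0.25)
  expect_equal(power_dv(-x, 2), -0.25)

  set.seed(1)
  X <- random_features(1000, scale = 0.7)
  k <- 0.61
  oracle <- apply(X, 1, function(r) {
    acc <- 0
    for (v in r) acc <- acc + sign(v) * abs(v)^k
    acc
  })
  expect_equal(power_dv(X, k), oracle, tolerance = 1e-15)
  # linear special case: plain sum
  expect_identical(power_dv(X, 1), rowSums(X))
})

test_that("the logistic choice function behaves as a late-noise channel", {
  expect_equal(choice_probability(0, 0.3), 0.5)
  expect_equal(choice_probability(0.5, 0.5), 1 / (1 + exp(-1)))
  expect_equal(choice_probability(1e6, 1), 1)
  dv <- seq(-2, 2, by = 0.5)
  expect_true(all(diff(choice_probability(dv, 0.7)) > 0))
  # more late noise pulls cp towards 0.5
  expect_lt(abs(choice_probability(1, 2) - 0.5),
            abs(choice_probability(1, 0.5) - 0.5))
  expect_error(choice_probability(1, 0), "positive")
})

test_that("equivalent gain equals the flat-feature-space magnification", {
  k <- seq(0.02, 2, length.out = 100)
  expect_equal(equivalent_gain(k) * (1 + k), rep(2, 100), tolerance = 1e-14)
  expect_equal(equivalent_gain(1), 1)
  expect_equal(equivalent_gain(0.5), 4 / 3)
  # quadrature oracle on a dense positive unit feature space:
  # mean(F^k) / mean(F) -> g for every k
  F <- seq(1e-6, 1, length.out = 2e5)
  for (kk in c(0.25, 0.5, 1, 1.7)) {
    expect_equal(mean(F^kk) / mean(F), equivalent_gain(kk), tolerance = 1e-3)
  }
  expect_error(equivalent_gain(-1), "exceed")
})

test_that("linear-equivalent and constant-gain variants relate to the power model", {
  set.seed(2)
  X <- random_features(200)
  # at k = 1 all three decision variables coincide bitwise
  expect_identical(power_dv(X, 1), linear_equivalent_dv(X, 1))
  expect_identical(power_dv(X, 1), constant_gain_dv(X, 1))
  # multiplicative structure
  x0 <- c(0.3, -0.3, 0.2, -0.2, 0.1, -0.1, 0.05, -0.05)
  expect_equal(linear_equivalent_dv(x0, 0.5), 0)
  expect_equal(linear_equivalent_dv(c(0.3, rep(0, 7)), 0.5), 4 / 3 * 0.3)
  expect_equal(constant_gain_dv(c(0.5, rep(0, 7)), 0.5),
               sqrt(0.5) / (4 / 3))
  expect_equal(constant_gain_dv(X, 0.7),
               power_dv(X, 0.7) / equivalent_gain(0.7))
})

test_that("every decision variable is odd-symmetric in the features", {
  set.seed(3)
  X <- random_features(50, scale = 0.6)
  spec <- population_spec(eps = 0.5, k = 0.5)
  for (f in list(function(Z) power_dv(Z, 0.4),
                 function(Z) linear_equivalent_dv(Z, 0.4),
                 function(Z) constant_gain_dv(Z, 1.6),
                 function(Z) popcode_dv(Z, spec))) {
    expect_equal(f(-X), -f(X), tolerance = 1e-10)
  }
  # hence cp(-X) = 1 - cp(X)
  expect_equal(choice_probability(power_dv(-X, 0.4), 0.8),
               1 - choice_probability(power_dv(X, 0.4), 0.8))
})

test_that("early-noise step choice is deterministic without noise and random with much", {
  X <- matrix(rep(c(0.2, 0.1, 0.05, 0.15, -0.1, 0.2, 0.1, 0.05), 4), 4,
              byrow = TRUE)
  expect_identical(early_noise_choice(X, 1, 0, seed = 1),
                   rep("CW", 4))
  # two independent Monte-Carlo streams agree on P(CW | X) within 3 SE
  x <- c(0.15, -0.05, 0.1, -0.2, 0.05, 0.1, -0.1, 0.05)
  Xrep <- matrix(x, 10000, 8, byrow = TRUE)
  p1 <- mean(early_noise_choice(Xrep, 0.8, 0.5, seed = 100) == "CW")
  p2 <- mean(early_noise_choice(Xrep, 0.8, 0.5, seed = 200) == "CW")
  se <- sqrt(p1 * (1 - p1) / 10000 + p2 * (1 - p2) / 10000)
  expect_lt(abs(p1 - p2), 3 * se)
  # overwhelming noise drives P(CW) to one half
  p3 <- mean(early_noise_choice(Xrep, 1, 500, seed = 300) == "CW")
  expect_lt(abs(p3 - 0.5), 0.02)
})

test_that("population read-out matches a per-neuron summation oracle", {
  spec <- population_spec(eps = 0.5, k = 0.5)
  expect_lt(abs(popcode_estimate(0, spec)), 1e-10)

  xs <- seq(-2, 2, length.out = 21)
  oracle <- vapply(xs, function(x) {
    tot <- 0
    for (j in seq_len(spec$M)) {
      r <- stats::dnorm(x, spec$f[j], spec$sd) * abs(spec$f[j])^(spec$k - 1) *
        spec$rho / spec$M
      tot <- tot + r * spec$f[j]
    }
    tot
  }, numeric(1))
  expect_equal(popcode_estimate(xs, spec), oracle, tolerance = 1e-12)

  # linear gain (k = 1) read-out is proportional to x in the interior
  lin <- population_spec(eps = 0.5, k = 1)
  xin <- seq(-1, 1, length.out = 11)
  th <- popcode_estimate(xin, lin)
  slope <- th[xin == 1] / 1
  expect_equal(th, slope * xin, tolerance = 1e-3)

  # transfer family over the stimulus-relevant range: monotone in x and
  # compressive (concave on x > 0) for k < 1
  for (kk in c(0.02, 0.3, 0.7)) {
    sp <- population_spec(eps = 0.5, k = kk)
    th <- popcode_estimate(seq(0.05, 1, length.out = 40), sp)
    expect_true(all(diff(th) > 0))
    expect_true(all(diff(diff(th)) < 1e-8))
  }
  expect_error(popcode_estimate(5, spec), "feature space")
})

test_that("population dv sums the per-sample estimates", {
  set.seed(4)
  X <- random_features(30, scale = 0.6)
  spec <- population_spec(eps = 0.5, k = 1)
  dv <- popcode_dv(X, spec)
  oracle <- apply(X, 1, function(r) sum(popcode_estimate(r, spec)))
  expect_equal(dv, oracle, tolerance = 1e-12)
  # k = 1 population dv is (approximately) proportional to the plain sum
  expect_gt(cor(dv, rowSums(X)), 0.9999)
  expect_equal(popcode_dv(matrix(0, 3, 8), spec), rep(0, 3),
               tolerance = 1e-10)
})
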