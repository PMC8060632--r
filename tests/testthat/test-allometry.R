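test_that("noiseless power-law data are recovered exactly in both spaces", {
  x <- seq(0.1, 2, length.out = 10)
  y <- 2 * x^1.5
  for (space in c("log-linear", "nonlinear")) {
    fit <- suppressWarnings(fit_allometric(x, y, space = space))
    expect_equal(fit$a, 2, tolerance = 1e-6)
    expect_equal(fit$b, 1.5, tolerance = 1e-6)
    expect_equal(fit$r2, 1, tolerance = 1e-8)
    expect_equal(fit$space, space)
  }
  ident <- suppressWarnings(fit_allometric(x, x))
  expect_equal(unname(coef(ident)), c(1, 1), tolerance = 1e-9)
})

test_that("input validation names offending rows and degenerate designs", {
  expect_error(fit_allometric(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_allometric(c(1, -2, 3), c(1, 2, 3)),
               "offending rows: 2")
  expect_error(fit_allometric(c(1, 2, 3), c(1, 0, 3)),
               "offending rows: 2")
  expect_error(fit_allometric(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("predict evaluates a*x^b and rejects non-positive x", {
  fit <- list(a = 2.92, b = 1.04, x = 1)
  class(fit) <- "allometric_fit"
  expect_equal(predict(fit, 1), 2.92)
  fit2 <- list(a = 2, b = 3, x = 1)
  class(fit2) <- "allometric_fit"
  expect_equal(predict(fit2, 2), 16)
  expect_error(predict(fit2, 0), "positive")
})

test_that("log-linear fit matches an independent normal-equations solution", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- exp(rnorm(n))
    y <- exp(rnorm(n, 0.5 + 1.3 * log(x), 0.3))
    fit <- fit_allometric(x, y)
    lx <- log(x); ly <- log(y)
    n1 <- length(lx)
    sxx <- sum(lx^2) - sum(lx)^2 / n1
    sxy <- sum(lx * ly) - sum(lx) * sum(ly) / n1
    b_hat <- sxy / sxx
    a_hat <- exp(mean(ly) - b_hat * mean(lx))
    expect_equal(fit$b, b_hat, tolerance = 1e-12)
    expect_equal(fit$a, a_hat, tolerance = 1e-12)
  }
})

test_that("scale equivariance: x -> c*x multiplies a by c^(-b), b unchanged", {
  set.seed(6)
  x <- runif(25, 0.2, 0.9)
  y <- 5 * x^1.7 * exp(rnorm(25, 0, 0.1))
  f1 <- fit_allometric(x, y)
  for (c_ in c(0.5, 3, 10)) {
    f2 <- fit_allometric(c_ * x, y)
    expect_equal(f2$b, f1$b, tolerance = 1e-10)
    expect_equal(f2$a, f1$a * c_^(-f1$b), tolerance = 1e-10)
  }
})

test_that("nonlinear and log-linear estimates converge as noise vanishes", {
  x <- seq(0.2, 0.9, length.out = 60)
  gap <- vapply(c(0.2, 0.05, 0.01), function(cv) {
    set.seed(7)
    y <- 4.87 * x^1.92 * exp(rnorm(60, 0, cv))
    f_log <- fit_allometric(x, y)
    f_nl <- fit_allometric(x, y, space = "nonlinear")
    max(abs(f_log$a - f_nl$a), abs(f_log$b - f_nl$b))
  }, 0)
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 0.01)
})

test_that("confidence intervals bracket the estimate and a's CI is asymmetric", {
  set.seed(8)
  x <- runif(40, 0.2, 0.9)
  y <- 4 * x^1.5 * exp(rnorm(40, 0, 0.2))
  fit <- fit_allometric(x, y)
  expect_lt(fit$ci_a[1], fit$a); expect_gt(fit$ci_a[2], fit$a)
  expect_lt(fit$ci_b[1], fit$b); expect_gt(fit$ci_b[2], fit$b)
  # back-transformed log-scale CI: upper gap exceeds lower gap
  expect_gt(fit$ci_a[2] - fit$a, fit$a - fit$ci_a[1])
  ci <- confint(fit)
  expect_equal(unname(ci["a", ]), unname(fit$ci_a))
})

test_that("simulate() round-trips the fitted error model", {
  x <- seq(0.2, 0.9, length.out = 50)
  set.seed(9)
  y <- 3 * x^1.2 * exp(rnorm(50, 0, 0.15))
  fit <- fit_allometric(x, y)
  sims <- simulate(fit, nsim = 200, seed = 10)
  refit_b <- vapply(sims, function(ys) fit_allometric(x, ys)$b, 0)
  expect_equal(mean(refit_b), fit$b, tolerance = 0.02)
})

test_that("grouped fitting returns pooled plus per-group rows", {
  trial <- simulate_trial(trial_config(noise_cv = 0, seed = 11))
  tab <- fit_allometric_by_group(trial, "sdm_t_ha", "cc", "cultivar")
  expect_equal(nrow(tab), 5L)  # pooled + 4 cultivars
  ak <- tab[tab$group == "AK58", ]
  expect_equal(ak$a, 4.87, tolerance = 1e-6)
  expect_equal(ak$b, 1.92, tolerance = 1e-6)
  expect_s3_class(attr(tab, "fits")$AK58, "allometric_fit")
})

test_that("formula interface agrees with the default interface", {
  trial <- simulate_trial(trial_config(seed = 12))
  f1 <- fit_allometric_formula(sdm_t_ha ~ cc, trial)
  f2 <- fit_allometric(trial$cc, trial$sdm_t_ha)
  expect_equal(coef(f1), coef(f2))
})
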