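test_that("grenander density matches hand-derived least concave majorants", {
  g <- grenander_density(0.5)
  expect_equal(g$breaks, c(0, 0.5, 1))
  expect_equal(g$heights, c(2, 0))
  expect_equal(density_at(g, c(0.2, 0.5, 0.7)), c(2, 2, 0))

  # ECDF exactly on the diagonal: the majorant is the identity
  g2 <- grenander_density(c(0.25, 0.5, 0.75, 1))
  expect_equal(g2$breaks, c(0, 1))
  expect_equal(g2$heights, 1)

  expect_error(grenander_density(numeric(0)), "no P-values")
})

test_that("grenander density agrees with the PAVA oracle on random instances", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    p <- switch(sample(3, 1),
                runif(n),
                round(runif(n), 1),          # heavy ties
                rbeta(n, 0.5, 1))
    p[p <= 0] <- 0.05
    g <- grenander_density(p)
    o <- grenander_oracle(p)
    expect_lt(max(abs(density_at(g, o$midpoints) - o$heights)), 1e-10)
    # unit mass and monotone steps
    expect_equal(sum(g$heights * diff(g$breaks)), 1, tolerance = 1e-12)
    expect_true(all(diff(g$heights) < 1e-12))
  }
})

test_that("storey smoother matches its closed-form ingredients", {
  # all p = 1: pi0_hat(lambda) = 1/(1-lambda) >= 1, clipped to 1
  expect_equal(estimate_pi0_storey(rep(1, 500))$pi0, 1)

  # ideal uniform p-values: estimate close to 1
  G <- 10000
  p <- (seq_len(G) - 0.5) / G
  est <- estimate_pi0_storey(p)
  expect_gte(est$pi0, 0.95)
  expect_lte(est$pi0, 1)

  # plug-in values on the grid are exact
  expect_equal(est$diagnostics$pi0_lambda[est$diagnostics$lambda == 0.5],
               sum(p > 0.5) / (0.5 * G))

  # half spike at 1e-6, half ideal uniform: pi0 near 0.5
  p2 <- c(rep(1e-6, G / 2), (seq_len(G / 2) - 0.5) / (G / 2))
  est2 <- estimate_pi0_storey(p2)
  expect_gte(est2$pi0, 0.45)
  expect_lte(est2$pi0, 0.60)

  expect_error(estimate_pi0_storey(runif(100), lambda_grid = c(0, 0.5),
                                   spline_df = 3), "grid points")
})

test_that("convex NPMLE is exact on degenerate input and calibrated on uniform", {
  expect_equal(estimate_pi0_convest(rep(1, 200))$pi0, 1)
  expect_error(estimate_pi0_convest(c(0.5, 0)), "strictly positive")

  # uniform draws: pi0 close to 1 (scaled-down replicate count)
  hits <- sum(vapply(1:6, function(s) {
    set.seed(s)
    pi0 <- estimate_pi0_convest(runif(4000))$pi0
    pi0 >= 0.97 && pi0 <= 1
  }, logical(1)))
  expect_gte(hits, 5)
})

test_that("convex NPMLE recovers the null weight of a signal mixture", {
  # 0.9 uniform + 0.1 Beta(0.1, 1): true density at 1 is 0.9 + 0.1*0.1
  hits <- vapply(1:6, function(s) {
    set.seed(s)
    p <- c(runif(9000), rbeta(1000, 0.1, 1))
    p[p <= 0] <- 1e-12
    estimate_pi0_convest(p)$pi0
  }, numeric(1))
  expect_gte(sum(hits >= 0.88 & hits <= 0.95), 5)
})

test_that("convex NPMLE fit is a convex decreasing density of unit mass", {
  set.seed(21)
  p <- c(runif(2000), rbeta(400, 0.3, 1))
  p[p <= 0] <- 1e-9
  est <- estimate_pi0_convest(p)
  fit <- est$diagnostics$fit
  grid <- seq(0, 1, length.out = 1001)
  f <- density_at(fit, grid)
  expect_true(all(diff(f) <= 1e-10))                     # nonincreasing
  expect_true(all(diff(diff(f)) >= -1e-8))               # convex
  expect_equal(fit$uniform_weight + sum(fit$weights), 1, tolerance = 1e-8)
  expect_true(all(diff(est$diagnostics$loglik) >= -1e-9))  # ll nondecreasing
  expect_equal(est$pi0, density_at(fit, 1), tolerance = 1e-12)
})

test_that("convex NPMLE agrees with an independent reference implementation", {
  skip_if_not_installed("limma")
  set.seed(33)
  p <- c(runif(3000), rbeta(600, 0.2, 1))
  p[p <= 0] <- 1e-9
  mine <- estimate_pi0_convest(p)$pi0
  ref <- limma::convest(p)
  # same estimator class, independent implementations (different line
  # search and density book-keeping): agreement to a few percent
  expect_lt(abs(mine - ref), 0.04)
})

test_that("empirical null recovers scale and pi0 on pure null statistics", {
  # scaled-down replicate counts; the full calibration runs in the
  # acceptance suite
  res <- t(vapply(1:6, function(s) {
    set.seed(s)
    fit <- estimate_pi0_empirical_null(rnorm(10000), "z")
    c(fit$pi0, fit$diagnostics$null_scale)
  }, numeric(2)))
  expect_gte(sum(res[, 1] >= 0.95 & res[, 1] <= 1), 5)
  expect_gte(sum(res[, 2] >= 0.95 & res[, 2] <= 1.05), 5)

  set.seed(101)
  fit_t <- estimate_pi0_empirical_null(rt(10000, 12), "t", df = 12)
  expect_gte(fit_t$pi0, 0.95)
  expect_lte(fit_t$pi0, 1)
})

test_that("empirical null separates a contaminating signal component", {
  res <- vapply(1:6, function(s) {
    set.seed(s)
    v <- ifelse(runif(10000) < 0.9, rnorm(10000), rnorm(10000, 4))
    estimate_pi0_empirical_null(v, "z")$pi0
  }, numeric(1))
  expect_gte(sum(res >= 0.85 & res <= 0.95), 4)
})

test_that("empirical null refuses unstable inputs", {
  expect_error(estimate_pi0_empirical_null(rnorm(100), "z"), "fewer than 200")
  expect_error(estimate_pi0_empirical_null(rnorm(500), "t"), "df")
})

test_that("FDR estimator follows the mixture-model identity", {
  p <- c(rep(0.001, 50), runif(950, 0.02, 1))
  f <- fdr_hat(0.01, 0.9, p)
  expect_equal(f$F_hat, 0.05)
  expect_equal(f$fdr, 0.01 * 0.9 / 0.05)

  # complete-null fixed point: F_hat(alpha) = alpha and pi0 = 1 -> FDR = 1
  G <- 1000
  p_unif <- (seq_len(G) - 0.5) / G
  f1 <- fdr_hat(0.1005, 1, p_unif)  # 100 of 1000 below threshold
  expect_equal(f1$F_hat, 0.1)
  expect_equal(f1$fdr, min(1, 0.1005 / 0.1))

  expect_equal(fdr_hat(0.05, 0, p)$fdr, 0)

  nd <- fdr_hat(1e-9, 0.9, runif(100, 0.5, 1))
  expect_true(nd$no_discoveries)
  expect_true(is.na(nd$fdr))

  # strict "<" versus "<=" at a tied threshold
  p_tie <- c(0.01, 0.01, 0.5, 0.9)
  expect_equal(fdr_hat(0.01, 1, p_tie)$no_discoveries, TRUE)
  expect_equal(fdr_hat(0.01, 1, p_tie, strict = FALSE)$F_hat, 0.5)

  # monotone in F_hat, linear in alpha * pi0
  set.seed(2)
  for (i in 1:20) {
    alpha <- runif(1, 0.01, 0.2)
    pi0 <- runif(1)
    p_a <- runif(500)
    f_a <- fdr_hat(alpha, pi0, p_a)
    if (!f_a$no_discoveries && f_a$fdr < 1) {
      expect_equal(f_a$fdr, alpha * pi0 / f_a$F_hat, tolerance = 1e-12)
    }
  }
})

test_that("all pi0 estimates live in [0,1] with pi1 the exact complement", {
  set.seed(55)
  p <- c(runif(500), rbeta(100, 0.2, 1))
  p[p <= 0] <- 1e-9
  fits <- list(estimate_pi0_storey(p), estimate_pi0_convest(p))
  for (f in fits) {
    expect_gte(f$pi0, 0)
    expect_lte(f$pi0, 1)
    expect_identical(f$pi1, 1 - f$pi0)
  }
})
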