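test_that("group summaries give the hand-computed means and variances", {
  x <- expression_matrix(rbind(g1 = c(1, 2, 3, 3, 4, 5)),
                         group = rep(c("A", "B"), each = 3))
  s <- group_summaries(x)
  expect_equal(s$mean1, c(g1 = 2))
  expect_equal(s$mean2, c(g1 = 4))
  expect_equal(s$var1, c(g1 = 1))
  expect_equal(s$var2, c(g1 = 1))

  const <- expression_matrix(rbind(c(5, 5, 5, 5)), group = c(1, 1, 2, 2))
  sc <- group_summaries(const)
  expect_equal(unname(c(sc$mean1, sc$mean2, sc$var1, sc$var2)),
               c(5, 5, 0, 0))

  zero <- expression_matrix(rbind(c(0, 0, 1, 1)), group = c(1, 1, 2, 2))
  sz <- group_summaries(zero)
  expect_equal(unname(c(sz$mean1, sz$mean2, sz$var1, sz$var2)),
               c(0, 1, 0, 0))
})

test_that("groups with fewer than two samples are rejected", {
  expect_error(expression_matrix(matrix(1:6, 2), group = c("A", "A", "B")),
               "at least 2 samples")
})

test_that("t-statistic matches hand arithmetic and flags zero denominators", {
  x <- expression_matrix(rbind(a = c(1, 2, 3, 3, 4, 5),
                               b = c(2, 2, 2, 2, 2, 2),
                               c = c(0, 0, 0, 1, 1, 1)),
                         group = rep(c("A", "B"), each = 3))
  expect_warning(tt <- t_statistics(group_summaries(x)), "zero denominator")
  expect_equal(tt$values[["a"]], -2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_true(is.nan(tt$values[["b"]]))  # mean1 == mean2, zero variance
  expect_true(is.nan(tt$values[["c"]]))  # means differ, zero variance
  expect_equal(tt$family, "t")
  expect_equal(tt$delta, 0)
})

test_that("delta_from_percentile follows the interpolation convention", {
  expect_equal(delta_from_percentile(c(1, 2, 3, 4, 5), 50), 3)
  expect_equal(delta_from_percentile(c(1, 2, 3, 4, 5), 90), 4.6)
  expect_equal(delta_from_percentile(rep(2.5, 10), 37), 2.5)
  expect_error(delta_from_percentile(numeric(0), 50), "no finite")
  # agreement with a from-first-principles oracle on random draws,
  # and monotonicity in the percentile
  set.seed(7)
  for (i in 1:10) {
    d <- rexp(sample(5:40, 1))
    pcts <- sort(runif(5, 1, 99))
    vals <- vapply(pcts, function(q) delta_from_percentile(d, q),
                   numeric(1))
    expect_equal(vals, vapply(pcts, function(q) interp_percentile(d, q),
                              numeric(1)), tolerance = 1e-12)
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("s-statistic matches hand arithmetic and shrinks toward zero", {
  x <- expression_matrix(rbind(a = c(1, 2, 3, 3, 4, 5)),
                         group = rep(c("A", "B"), each = 3))
  s <- group_summaries(x)
  d0 <- sqrt(2 / 3)
  st <- s_statistics(s, delta = d0)
  expect_equal(st$values[["a"]], -2 / (2 * d0), tolerance = 1e-12)

  # delta = 0 reduces to t; delta > 0 shrinks magnitude, never flips sign
  ds <- make_dataset(G = 200, seed = 42)
  summ <- group_summaries(ds)
  tt <- t_statistics(summ)
  s0 <- s_statistics(summ, delta = 0)
  expect_equal(s0$values, tt$values, tolerance = 1e-14)
  delta <- delta_from_percentile(tt$denominators, 50)
  s1 <- s_statistics(summ, delta = delta, family = "s50")
  expect_true(all(abs(s1$values) <= abs(tt$values)))
  expect_true(all(sign(s1$values) == sign(tt$values)))
})

test_that("rescaling matches the worked factor and restores the t spread", {
  s <- new_stat <- structure(list(values = c(-1, 0, 1),
                                  denominators = rep(1, 3), family = "s50",
                                  delta = 1, rescaled_by = "none",
                                  rescale_factor = 1, gene_ids = NULL),
                             class = "stat_vector")
  t <- structure(list(values = c(-2, 0, 2), denominators = rep(1, 3),
                      family = "t", delta = 0, rescaled_by = "none",
                      rescale_factor = 1, gene_ids = NULL),
                 class = "stat_vector")
  r <- rescale_statistics(s, t, "SD")
  expect_equal(r$rescale_factor, 2)
  expect_equal(r$values, c(-2, 0, 2))

  ident <- rescale_statistics(t, t, "SD")
  expect_equal(ident$rescale_factor, 1)
  expect_equal(ident$values, t$values)

  ds <- make_dataset(G = 300, seed = 3, delta_mean = 0.3)
  summ <- group_summaries(ds)
  tt <- t_statistics(summ)
  ss <- compute_statistics(summ, "s70")
  for (m in c("SD", "IQR")) {
    r <- rescale_statistics(ss, tt, m)
    spread <- if (m == "SD") sd else function(v) IQR(v, type = 7)
    expect_equal(spread(r$values), spread(tt$values), tolerance = 1e-10)
    expect_identical(rank(r$values), rank(ss$values))  # Spearman rho = 1
  }
})

test_that("statistics are computed gene-wise: permuting genes permutes output", {
  ds <- make_dataset(G = 60, seed = 9)
  perm <- sample(60)
  ds_p <- expression_matrix(ds$values[perm, ], group = ds$group,
                            gene_ids = ds$gene_ids[perm])
  for (fam in c("t", "s50", "s90")) {
    a <- compute_statistics(ds, fam)
    b <- compute_statistics(ds_p, fam)
    expect_equal(unname(b$values), unname(a$values[perm]), tolerance = 1e-12)
  }
})

test_that("degenerate rescaling input is rejected", {
  z <- structure(list(values = rep(1, 5), denominators = rep(1, 5),
                      family = "s50", delta = 1, rescaled_by = "none",
                      rescale_factor = 1, gene_ids = NULL),
                 class = "stat_vector")
  t <- structure(list(values = rnorm(5), denominators = rep(1, 5),
                      family = "t", delta = 0, rescaled_by = "none",
                      rescale_factor = 1, gene_ids = NULL),
                 class = "stat_vector")
  expect_error(rescale_statistics(z, t, "SD"), "zero spread")
})
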