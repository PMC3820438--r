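#' Grenander density estimate for P-values
#'
#' The nonparametric MLE of a nonincreasing density on [0, 1]: the left
#' derivative of the least concave majorant (LCM) of the empirical CDF.
#' The result is a nonincreasing step function that integrates to 1
#' exactly.
#'
#' @param pvals P-values in (0, 1] (a \code{pvalue_vector} or numeric).
#' @return An object of class \code{"grenander"}: list with \code{breaks}
#'   (LCM knots, starting at 0 and ending at 1), \code{heights} (step
#'   heights on the intervals between consecutive breaks), \code{cdf}
#'   (LCM values at the breaks), and \code{n}.  Evaluate with
#'   \code{\link{density_at}}.
#' @examples
#' g <- grenander_density(c(0.25, 0.5, 0.75, 1))
#' density_at(g, c(0.1, 0.9))
#' @export
grenander_density <- function(pvals) {
  p <- .as_pvalues(pvals, require_positive = FALSE)
  if (length(p) == 0L) stop("empty input")
  if (any(p <= 0)) stop("P-values must be in (0, 1]")
  n <- length(p)
  tab <- table(p)
  x <- c(0, as.numeric(names(tab)))
  y <- c(0, cumsum(as.integer(tab)) / n)
  if (x[length(x)] < 1) {
    x <- c(x, 1)
    y <- c(y, 1)
  }
  # least concave majorant: upper hull by monotone chain
  hull <- c(1L, 2L)
  for (i in seq_along(x)[-(1:2)]) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]
      b <- hull[length(hull)]
      # pop b if it lies on or below chord a -> i
      if ((y[b] - y[a]) * (x[i] - x[b]) <= (y[i] - y[b]) * (x[b] - x[a])) {
        hull <- hull[-length(hull)]
      } else break
    }
    hull <- c(hull, i)
  }
  breaks <- x[hull]
  cdf <- y[hull]
  heights <- diff(cdf) / diff(breaks)
  structure(list(breaks = breaks, heights = heights, cdf = cdf, n = n),
            class = "grenander")
}

#' Evaluate a fitted density
#'
#' @param fit A \code{grenander} or \code{convex_density_fit} object.
#' @param p Points in (0, 1] at which to evaluate the density.
#' @return Numeric vector of density values.
#' @export
density_at <- function(fit, p) UseMethod("density_at")

#' @export
density_at.grenander <- function(fit, p) {
  stopifnot(all(p >= 0), all(p <= 1))
  idx <- findInterval(p, fit$breaks, left.open = TRUE)
  idx[idx == 0L] <- 1L  # value at p = 0: height of the first step
  fit$heights[idx]
}

#' @export
print.grenander <- function(x, ...) {
  cat(sprintf("Grenander density: %d P-values, %d steps\n", x$n,
              length(x$heights)))
  invisible(x)
}

#' @keywords internal
#' @noRd
new_pi1_estimate <- function(pi0, method, diagnostics = list()) {
  pi0 <- min(1, max(0, pi0))
  structure(list(pi0 = pi0, pi1 = 1 - pi0, method = method,
                 diagnostics = diagnostics),
            class = "pi1_estimate")
}

#' @export
print.pi1_estimate <- function(x, ...) {
  cat(sprintf("pi0 estimate (%s): pi0 = %.4f, pi1 = %.4f\n",
              x$method, x$pi0, x$pi1))
  invisible(x)
}

#' Smoothing-spline mixture-model estimate of pi0
#'
#' Storey-type estimator: on a grid of tuning values \eqn{\lambda},
#' compute \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / ((1-\lambda) G)},
#' fit a cubic smoothing spline with \code{spline_df} degrees of freedom to
#' the \eqn{(\lambda, \hat\pi_0(\lambda))} points, and take the spline
#' value at the largest \eqn{\lambda}, clipped to [0, 1].
#'
#' @param pvals P-values (a \code{pvalue_vector} or numeric in [0, 1]).
#' @param lambda_grid Grid of \eqn{\lambda} values in [0, 1); default
#'   0, 0.05, ..., 0.90; needs at least \code{spline_df + 1} points.
#' @param spline_df Degrees of freedom of the smoothing spline (default 3).
#' @return A \code{pi1_estimate} with \code{method = "storey_smoother"};
#'   diagnostics hold the grid, the raw \eqn{\hat\pi_0(\lambda)} values and
#'   the spline fit.
#' @export
estimate_pi0_storey <- function(pvals, lambda_grid = seq(0, 0.90, by = 0.05),
                                spline_df = 3) {
  p <- .as_pvalues(pvals, require_positive = FALSE)
  stopifnot(all(lambda_grid >= 0), all(lambda_grid < 1))
  lambda_grid <- sort(unique(lambda_grid))
  if (length(lambda_grid) < spline_df + 1)
    stop("need at least spline_df + 1 = ", spline_df + 1, " grid points")
  G <- length(p)
  pi0_lambda <- vapply(lambda_grid,
                       function(l) sum(p > l) / ((1 - l) * G), numeric(1L))
  if (pi0_lambda[length(pi0_lambda)] == 0)
    warning("no P-values above max(lambda); pi0 estimate driven to 0")
  fit <- stats::smooth.spline(lambda_grid, pi0_lambda, df = spline_df)
  pi0 <- stats::predict(fit, x = max(lambda_grid))$y
  new_pi1_estimate(pi0, "storey_smoother",
                   diagnostics = list(lambda = lambda_grid,
                                      pi0_lambda = pi0_lambda,
                                      spline = fit,
                                      pi0_raw = pi0))
}

#' Convex decreasing density NPMLE estimate of pi0
#'
#' Nonparametric maximum-likelihood estimation of the P-value density under
#' the constraint that it is convex and decreasing on [0, 1].  The density
#' is a mixture of the uniform and triangular components
#' \eqn{f_\theta(p) = 2(\theta - p)/\theta^2} for \eqn{p < \theta} (0
#' otherwise).  Starting from the uniform, each iteration selects the
#' support point \eqn{\theta^*} maximizing the mean ratio
#' \eqn{\sum_i f_\theta(p_i)/f(p_i)} and mixes it in,
#' \eqn{f \leftarrow (1-\varepsilon) f + \varepsilon f_{\theta^*}}, with
#' \eqn{\varepsilon} chosen by golden-section search maximizing the
#' log-likelihood.  Ties in \eqn{\theta^*} are broken toward the smaller
#' \eqn{\theta}.  Returns \eqn{\hat\pi_0 = \hat f(1)} (the residual
#' uniform weight).
#'
#' Support points are restricted to a 1\%-resolution grid
#' (\code{theta_grid}).  The resolution limit regularizes the boundary
#' value \eqn{\hat f(1)}: with arbitrarily small support points the
#' unrestricted NPMLE absorbs part of the near-zero P-value spike into
#' steep triangles and systematically under-estimates \eqn{\pi_0} at the
#' boundary.
#'
#' @param pvals P-values strictly in (0, 1].
#' @param max_iter Maximum number of support-point insertions (default
#'   100); iteration stops early once the log-likelihood no longer
#'   improves.
#' @param theta_grid Candidate support points in (0, 1].
#' @return A \code{pi1_estimate} with \code{method = "convest"};
#'   \code{diagnostics$fit} is a \code{convex_density_fit} (support points,
#'   weights, evaluable via \code{\link{density_at}}) and
#'   \code{diagnostics$loglik} the nondecreasing log-likelihood trace.
#' @export
estimate_pi0_convest <- function(pvals, max_iter = 100,
                                 theta_grid = seq(0.01, 1, by = 0.01)) {
  p <- .as_pvalues(pvals, require_positive = TRUE)
  ps <- sort(p)
  G <- length(ps)
  theta_grid <- sort(unique(theta_grid))
  stopifnot(all(theta_grid > 0), all(theta_grid <= 1))
  n_less <- findInterval(theta_grid, ps, left.open = TRUE)  # #{p_i < theta}

  w0 <- 1
  thetas <- numeric(0)
  weights <- numeric(0)
  f <- rep(1, G)
  ll <- 0
  ll_trace <- numeric(0)
  eps_max <- 1 - 1e-10

  for (it in seq_len(max_iter)) {
    u <- 1 / f
    cu <- c(0, cumsum(u))
    cpu <- c(0, cumsum(ps * u))
    score <- 2 * (theta_grid * cu[n_less + 1L] - cpu[n_less + 1L]) /
      theta_grid^2
    best <- which(score == max(score))[1L]  # grid ascending: smallest theta
    theta_star <- theta_grid[best]
    f_star <- ifelse(ps < theta_star,
                     2 * (theta_star - ps) / theta_star^2, 0)
    ll_of <- function(eps) {
      sum(log(pmax((1 - eps) * f + eps * f_star, 1e-300)))
    }
    opt <- stats::optimize(ll_of, interval = c(0, eps_max), maximum = TRUE,
                           tol = 1e-6)
    eps <- opt$maximum
    ll_new <- opt$objective
    if (ll_of(0) >= ll_new) {  # epsilon = 0 is at the interval boundary
      eps <- 0
      ll_new <- ll
    }
    if (eps > 0) {
      f <- (1 - eps) * f + eps * f_star
      w0 <- w0 * (1 - eps)
      weights <- weights * (1 - eps)
      hit <- which(thetas == theta_star)
      if (length(hit) == 1L) {
        weights[hit] <- weights[hit] + eps
      } else {
        thetas <- c(thetas, theta_star)
        weights <- c(weights, eps)
      }
    }
    ll_trace <- c(ll_trace, ll_new)
    if (it > 1L && ll_new - ll < 1e-12) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }

  keep <- weights > 0
  fit <- structure(
    list(support_points = thetas[keep], weights = weights[keep],
         uniform_weight = w0),
    class = "convex_density_fit")
  new_pi1_estimate(w0, "convest",
                   diagnostics = list(fit = fit, loglik = ll_trace,
                                      n_iter = length(ll_trace)))
}

#' @export
density_at.convex_density_fit <- function(fit, p) {
  stopifnot(all(p >= 0), all(p <= 1))
  out <- rep(fit$uniform_weight, length(p))
  for (j in seq_along(fit$support_points)) {
    th <- fit$support_points[j]
    out <- out + fit$weights[j] * ifelse(p < th, 2 * (th - p) / th^2, 0)
  }
  out
}

#' @export
print.convex_density_fit <- function(x, ...) {
  cat(sprintf(
    "Convex decreasing density: uniform weight %.4f, %d support points\n",
    x$uniform_weight, length(x$support_points)))
  invisible(x)
}

#' Empirical-null estimate of pi0 from test statistics
#'
#' Estimates \eqn{\pi_0} directly from a vector of test statistics, without
#' permutation P-values, in the spirit of empirical-null / local-fdr
#' methodology.  The algorithm:
#' \enumerate{
#'   \item Fit the null scale \eqn{\hat\sigma} by truncated maximum
#'     likelihood on the central portion of the absolute statistics — a
#'     half-normal(\eqn{\sigma}) null for \code{input_family = "z"}, a
#'     scaled t(\code{df}) null for \code{input_family = "t"}.  The
#'     truncation point is chosen adaptively from a quantile grid of the
#'     absolute statistics (10\%, 20\%, ..., 90\%, 99\%), searched from the
#'     largest candidate downward (a wide truncation region makes the
#'     scale identifiable; a narrow one degenerates to a flat likelihood),
#'     stopping at the first quantile at which the truncated fit is
#'     self-consistent.  Self-consistency requires (a) the observed
#'     central fraction not to exceed the fitted-null central probability
#'     beyond a 95\% binomial band (the null component of a mixture can
#'     only lose central mass to the alternative, so a fitted null
#'     predicting too few central statistics signals a failed scale fit),
#'     and (b) the count below the fitted-null conditional median of the
#'     truncation region to sit within its 95\% binomial band (a shape
#'     check with power against contamination by true signal).
#'   \item Convert all statistics to two-sided P-values under the fitted
#'     null.
#'   \item Estimate \eqn{\hat\eta_0} as the Grenander density of those
#'     P-values evaluated in the flat tail near 1 (at \code{tail_point}),
#'     capped at 1.  Return \eqn{\hat\pi_0 = \hat\eta_0}.
#' }
#'
#' Statistics from an s-family should first be rescaled to t-statistic
#' spread with \code{\link{rescale_statistics}}.
#'
#' @param stats A \code{stat_vector} (or numeric vector) of statistics; at
#'   least 200 finite values are required.
#' @param input_family Declared input specification: \code{"t"} or
#'   \code{"z"}.
#' @param df Degrees of freedom of the null t distribution (required for
#'   \code{input_family = "t"}); a single value for the whole vector,
#'   conventionally \eqn{n_1 + n_2 - 2}.
#' @param quantile_grid Candidate truncation quantiles.
#' @param tail_point Where in (0, 1) the Grenander density is read off as
#'   the null mass (default 0.9).
#' @return A \code{pi1_estimate} with method \code{"empirical_null_t"} or
#'   \code{"empirical_null_z"}; diagnostics hold the fitted
#'   \code{null_scale}, the censoring quantile and point, the null
#'   P-values and the Grenander fit.
#' @export
estimate_pi0_empirical_null <- function(stats, input_family = c("t", "z"),
                                        df = NULL,
                                        quantile_grid = c(seq(0.1, 0.9, 0.1),
                                                          0.99),
                                        tail_point = 0.9) {
  input_family <- match.arg(input_family)
  v <- if (inherits(stats, "stat_vector")) stats$values else as.numeric(stats)
  v <- v[is.finite(v)]
  N <- length(v)
  if (N < 200L)
    stop("refusing to fit an empirical null to fewer than 200 statistics")
  if (input_family == "t" && (is.null(df) || df <= 0))
    stop("df must be supplied (positive) for input_family = \"t\"")

  pnull <- switch(input_family,
                  z = function(q, s) 2 * stats::pnorm(q / s) - 1,
                  t = function(q, s) 2 * stats::pt(q / s, df) - 1)
  dnull <- switch(input_family,
                  z = function(q, s) 2 * stats::dnorm(q / s) / s,
                  t = function(q, s) 2 * stats::dt(q / s, df) / s)
  qnull <- switch(input_family,
                  z = function(pr, s) s * stats::qnorm((pr + 1) / 2),
                  t = function(pr, s) s * stats::qt((pr + 1) / 2, df))

  a <- abs(v)
  s_upper <- 50 * max(stats::sd(a), 1e-8)
  chosen <- NULL
  tried <- list()
  for (q in sort(quantile_grid, decreasing = TRUE)) {
    x0 <- stats::quantile(a, q, type = 7, names = FALSE)
    if (x0 <= 0) next
    sub <- a[a <= x0]
    n0 <- length(sub)
    if (n0 < 25L) next
    nll <- function(s) -sum(log(dnull(sub, s))) + n0 * log(pnull(x0, s))
    opt <- stats::optimize(nll, interval = c(x0 / 1000, s_upper))
    sigma <- opt$minimum
    F0 <- pnull(x0, sigma)
    # (a) one-sided count check: null must cover the observed centre
    ok_count <- (n0 / N) <= F0 + 1.96 * sqrt(F0 * (1 - F0) / N)
    # (b) shape check at the conditional median of the region
    x_med <- qnull(F0 / 2, sigma)
    m <- sum(sub <= x_med)
    ok_shape <- abs(m - n0 / 2) <= 1.96 * sqrt(n0) / 2
    tried[[length(tried) + 1L]] <-
      list(q = q, x0 = x0, sigma = sigma, F0 = F0,
           ok_count = ok_count, ok_shape = ok_shape)
    if (ok_count && ok_shape) {
      chosen <- tried[[length(tried)]]
      break
    }
  }
  if (is.null(chosen)) {
    stop("empirical-null scale fit did not converge: no truncation ",
         "quantile gave a self-consistent fit (tried ",
         paste(vapply(tried, function(t) sprintf("%g", t$q), character(1L)),
               collapse = ", "), ")")
  }
  sigma <- chosen$sigma
  p <- pmax(1 - pnull(a, sigma), 1e-300)  # two-sided null P-values
  gren <- grenander_density(p)
  eta0 <- min(1, density_at(gren, tail_point))
  method <- paste0("empirical_null_", input_family)
  new_pi1_estimate(
    eta0, method,
    diagnostics = list(input_family = input_family, df = df,
                       null_scale = sigma,
                       censoring_quantile = chosen$q,
                       censoring_point = chosen$x0,
                       eta0 = eta0, pvalues = p, grenander = gren,
                       search = tried))
}

#' Mixture-model FDR estimate at a P-value threshold
#'
#' The standard mixture-model form
#' \deqn{\widehat{FDR}(\alpha) = \alpha \hat\pi_0 / \hat F_p(\alpha),}
#' with \eqn{\hat F_p(\alpha) = \#\{p < \alpha\}/G} (strict inequality:
#' genes with \eqn{p < \alpha} are called significant) and the result
#' capped at 1.  When there are no discoveries the estimate is flagged
#' rather than divided by zero.
#'
#' @param alpha P-value threshold in (0, 1).
#' @param pi0 Estimated null proportion in [0, 1] (number or
#'   \code{pi1_estimate}).
#' @param pvals P-values.
#' @param strict Use strict \code{<} (default); set \code{FALSE} for
#'   \code{<=}, which matters only for discrete P-values tied at
#'   \code{alpha}.
#' @return An object of class \code{"fdr_estimate"}: list with
#'   \code{alpha}, \code{pi0}, \code{F_hat}, \code{fdr} (NA when flagged),
#'   \code{n_discoveries}, \code{no_discoveries}.
#' @export
fdr_hat <- function(alpha, pi0, pvals, strict = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  if (inherits(pi0, "pi1_estimate")) pi0 <- pi0$pi0
  stopifnot(pi0 >= 0, pi0 <= 1)
  p <- .as_pvalues(pvals, require_positive = FALSE)
  G <- length(p)
  n_disc <- if (strict) sum(p < alpha) else sum(p <= alpha)
  F_hat <- n_disc / G
  if (F_hat == 0) {
    out <- list(alpha = alpha, pi0 = pi0, F_hat = 0, fdr = NA_real_,
                n_discoveries = 0L, no_discoveries = TRUE)
  } else {
    out <- list(alpha = alpha, pi0 = pi0, F_hat = F_hat,
                fdr = min(1, alpha * pi0 / F_hat),
                n_discoveries = n_disc, no_discoveries = FALSE)
  }
  class(out) <- "fdr_estimate"
  out
}

#' @export
print.fdr_estimate <- function(x, ...) {
  if (x$no_discoveries) {
    cat(sprintf("FDR at alpha = %g: no discoveries\n", x$alpha))
  } else {
    cat(sprintf("FDR at alpha = %g: %.4f (%d discoveries, pi0 = %.3f)\n",
                x$alpha, x$fdr, x$n_discoveries, x$pi0))
  }
  invisible(x)
}
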