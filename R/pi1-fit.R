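#' Fit the proportion of differentially expressed genes
#'
#' The front door of the package: from a two-group expression matrix,
#' computes the chosen test statistic for every gene and estimates
#' \eqn{\pi_1}, the proportion of differentially expressed genes, by one of
#' three routes:
#' \describe{
#'   \item{\code{"convest"}}{pooled permutation null P-values, then the
#'     convex decreasing density NPMLE
#'     (\code{\link{estimate_pi0_convest}}).}
#'   \item{\code{"storey"}}{pooled permutation null P-values, then the
#'     smoothing-spline mixture-model estimator
#'     (\code{\link{estimate_pi0_storey}}).}
#'   \item{\code{"empirical_null"}}{no permutations: s-statistics are
#'     rescaled to t-statistic spread and the empirical-null scale is
#'     fitted directly to the statistics
#'     (\code{\link{estimate_pi0_empirical_null}}).}
#' }
#'
#' @param x An \code{\link{expression_matrix}}, a
#'   \code{simulated_dataset}, or a numeric genes x samples matrix (then
#'   \code{group} is required).
#' @param group Two-level group factor over samples (ignored when \code{x}
#'   carries one).
#' @param method Estimation route (see above).
#' @param statistic Statistic family: \code{"t"}, \code{"s30"},
#'   \code{"s50"} (default), \code{"s70"}, \code{"s90"}.
#' @param rescale Spread measure used to rescale s-statistics for the
#'   empirical-null route: \code{"IQR"} (default), \code{"SD"} or
#'   \code{"none"}.
#' @param input_spec Input specification for the empirical-null route:
#'   treat the statistics as \code{"t"}- or \code{"z"}-statistics.
#' @param df Null degrees of freedom for \code{input_spec = "t"}; defaults
#'   to \eqn{n_1 + n_2 - 2}.
#' @param B Number of label permutations for the pooled null (default
#'   100).
#' @param seed Seed for the permutation draw.
#' @param ... Passed on to the chosen estimator.
#' @return An object of class \code{"pi1_fit"}: list with \code{pi0},
#'   \code{pi1}, \code{method}, \code{statistic} (the \code{stat_vector}
#'   actually handed to the estimator), \code{pvalues} (\code{NULL} for
#'   the empirical-null route), \code{estimate} (the underlying
#'   \code{pi1_estimate} with diagnostics), \code{n1}, \code{n2},
#'   \code{call}.
#' @examples
#' params <- synth_parameter_table(500, pi1 = 0.1, seed = 1)
#' cfg <- scenario_config("EV", 8, 6, pi1 = 0.1, G = 500, seed = 1)
#' ds <- simulate_dataset(params, cfg)
#' fit <- pi1_fit(ds, method = "convest", statistic = "s50", B = 50,
#'                seed = 1)
#' fit
#' coef(fit)
#' @export
pi1_fit <- function(x, group = NULL,
                    method = c("convest", "storey", "empirical_null"),
                    statistic = c("s50", "t", "s30", "s70", "s90"),
                    rescale = c("IQR", "SD", "none"),
                    input_spec = c("t", "z"), df = NULL, B = 100L,
                    seed = 1L, ...) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  rescale <- match.arg(rescale)
  input_spec <- match.arg(input_spec)
  cl <- match.call()
  if (is.matrix(x)) {
    if (is.null(group)) stop("group is required for a plain matrix")
    x <- expression_matrix(x, group = group)
  }
  data <- as_expression_matrix(x)
  summ <- group_summaries(data)
  st <- compute_statistics(summ, family = statistic)
  pvalues <- NULL
  if (method == "empirical_null") {
    st_in <- st
    if (statistic != "t" && rescale != "none") {
      st_in <- rescale_statistics(st, t_statistics(summ),
                                  measure = rescale)
    }
    if (is.null(df)) df <- summ$n1 + summ$n2 - 2
    est <- estimate_pi0_empirical_null(st_in, input_family = input_spec,
                                       df = df, ...)
    st <- st_in
  } else {
    labels <- permutation_labels(summ$n1, summ$n2, B, seed = seed)
    null <- pooled_null_statistics(data, family = statistic,
                                   labels = labels)
    pvalues <- pooled_null_pvalues(st, null)
    est <- switch(method,
                  convest = estimate_pi0_convest(pvalues, ...),
                  storey = estimate_pi0_storey(pvalues, ...))
  }
  structure(
    list(pi0 = est$pi0, pi1 = est$pi1, method = method,
         statistic = st, pvalues = pvalues, estimate = est,
         n1 = summ$n1, n2 = summ$n2, G = length(st$values), call = cl),
    class = "pi1_fit")
}

#' @export
print.pi1_fit <- function(x, digits = 4, ...) {
  cat("Call:\n  ")
  print(x$call)
  cat(sprintf("\n%d genes, groups of %d and %d; statistic %s%s\n",
              x$G, x$n1, x$n2, x$statistic$family,
              if (x$statistic$rescaled_by != "none")
                paste0(" (", x$statistic$rescaled_by, "-rescaled)") else ""))
  cat(sprintf("pi1 = %.*f  (pi0 = %.*f, method %s)\n", digits, x$pi1,
              digits, x$pi0, x$estimate$method))
  invisible(x)
}

#' @export
coef.pi1_fit <- function(object, ...) {
  c(pi0 = object$pi0, pi1 = object$pi1)
}

#' @export
summary.pi1_fit <- function(object, alpha = c(0.001, 0.01, 0.05), ...) {
  fdr <- NULL
  if (!is.null(object$pvalues)) {
    fdr <- do.call(rbind, lapply(alpha, function(a) {
      f <- fdr_hat(a, object$pi0, object$pvalues)
      data.frame(alpha = a, n_discoveries = f$n_discoveries,
                 F_hat = f$F_hat, fdr = f$fdr)
    }))
  }
  structure(list(fit = object, fdr = fdr), class = "summary.pi1_fit")
}

#' @export
print.summary.pi1_fit <- function(x, ...) {
  print(x$fit)
  d <- x$fit$estimate$diagnostics
  if (!is.null(d$null_scale))
    cat(sprintf("empirical null: scale %.4f fitted below the %.0f%% ",
                d$null_scale, 100 * d$censoring_quantile),
        "quantile of |statistic|\n", sep = "")
  if (!is.null(d$n_iter))
    cat(sprintf("convex NPMLE: %d iterations, %d support points\n",
                d$n_iter, length(d$fit$support_points)))
  if (!is.null(x$fdr)) {
    cat("\nEstimated FDR at P-value thresholds:\n")
    print(x$fdr, row.names = FALSE)
  }
  invisible(x)
}

#' Predict the FDR of a P-value threshold from a fitted model
#'
#' @param object A \code{pi1_fit} whose method produced P-values
#'   (\code{"convest"} or \code{"storey"}).
#' @param alpha P-value threshold(s) in (0, 1).
#' @param ... Unused.
#' @return A data frame with one row per threshold: \code{alpha},
#'   \code{n_discoveries}, \code{F_hat}, \code{fdr}.
#' @export
predict.pi1_fit <- function(object, alpha = 0.001, ...) {
  if (is.null(object$pvalues))
    stop("no P-values in this fit (empirical-null route); ",
         "refit with method \"convest\" or \"storey\"")
  do.call(rbind, lapply(alpha, function(a) {
    f <- fdr_hat(a, object$pi0, object$pvalues)
    data.frame(alpha = a, n_discoveries = f$n_discoveries, F_hat = f$F_hat,
               fdr = f$fdr)
  }))
}

#' @export
plot.pi1_fit <- function(x, breaks = 40, ...) {
  if (!is.null(x$pvalues)) {
    p <- x$pvalues$values
    graphics::hist(p, breaks = breaks, freq = FALSE,
                   main = "P-values with fitted mixture density",
                   xlab = "P-value", ...)
    grid_p <- seq(0.001, 1, length.out = 401)
    d <- x$estimate$diagnostics
    if (!is.null(d$fit)) {
      graphics::lines(grid_p, density_at(d$fit, grid_p), lwd = 2)
    }
    graphics::abline(h = x$pi0, lty = 2)
  } else {
    d <- x$estimate$diagnostics
    graphics::hist(d$pvalues, breaks = breaks, freq = FALSE,
                   main = "Null P-values under the fitted empirical null",
                   xlab = "P-value", ...)
    graphics::lines(sort(unique(c(d$grenander$breaks, seq(0, 1, 0.01)))),
                    density_at(d$grenander,
                               sort(unique(c(d$grenander$breaks,
                                             seq(0, 1, 0.01))))),
                    type = "s", lwd = 2)
    graphics::abline(h = x$pi0, lty = 2)
  }
  invisible(x)
}
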