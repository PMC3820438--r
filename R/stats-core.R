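#' Per-gene group summaries
#'
#' Computes, for every gene, the sample mean and the unbiased (n - 1
#' denominator) sample variance of the expression level within each of the
#' two groups.
#'
#' @param data An \code{\link{expression_matrix}} object (or anything
#'   accepted by \code{\link{as_expression_matrix}}).
#' @return A list of class \code{"gene_summary"} with components
#'   \code{mean1}, \code{mean2}, \code{var1}, \code{var2} (numeric vectors,
#'   one entry per gene), \code{n1}, \code{n2} and \code{gene_ids}.
#' @examples
#' x <- expression_matrix(rbind(g1 = c(1, 2, 3, 3, 4, 5)),
#'                        group = rep(c("A", "B"), each = 3))
#' group_summaries(x)
#' @export
group_summaries <- function(data) {
  data <- as_expression_matrix(data)
  idx1 <- data$group == levels(data$group)[1L]
  n1 <- sum(idx1)
  n2 <- sum(!idx1)
  if (n1 < 2L || n2 < 2L) {
    stop("invalid design: each group needs at least 2 samples (got ",
         n1, " and ", n2, ")")
  }
  x1 <- data$values[, idx1, drop = FALSE]
  x2 <- data$values[, !idx1, drop = FALSE]
  out <- list(
    mean1 = rowMeans(x1),
    mean2 = rowMeans(x2),
    var1  = .row_vars(x1),
    var2  = .row_vars(x2),
    n1 = n1, n2 = n2,
    gene_ids = data$gene_ids
  )
  class(out) <- "gene_summary"
  out
}

# unbiased row variances without apply() overhead
.row_vars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  (rowSums(x * x) - n * m * m) / (n - 1)
}

#' Construct a test-statistic vector
#'
#' Internal constructor shared by \code{\link{t_statistics}} and
#' \code{\link{s_statistics}}.
#'
#' @keywords internal
#' @noRd
new_stat_vector <- function(values, denominators, family, delta,
                            rescaled_by = "none", rescale_factor = 1,
                            gene_ids = NULL) {
  structure(
    list(values = values, denominators = denominators, family = family,
         delta = delta, rescaled_by = rescaled_by,
         rescale_factor = rescale_factor, gene_ids = gene_ids),
    class = "stat_vector"
  )
}

#' @export
print.stat_vector <- function(x, ...) {
  n_bad <- sum(!is.finite(x$values))
  cat(sprintf("Test statistics: family %s, %d genes", x$family,
              length(x$values)))
  if (x$delta > 0) cat(sprintf(", delta = %.4g", x$delta))
  if (x$rescaled_by != "none")
    cat(sprintf(", rescaled by %s (factor %.4g)", x$rescaled_by,
                x$rescale_factor))
  cat("\n")
  if (n_bad > 0L) cat(sprintf("  (%d non-finite, excluded downstream)\n",
                              n_bad))
  print(summary(x$values[is.finite(x$values)]))
  invisible(x)
}

#' Classical two-sample t-statistics
#'
#' The Welch (unequal-variance) two-sample t-statistic per gene:
#' \deqn{t = (\bar X_1 - \bar X_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}.}
#' Genes whose denominator is exactly zero (both sample variances zero)
#' receive a non-finite statistic (\code{NaN}) and are counted in a warning;
#' downstream percentile, spread and estimation steps exclude them.
#'
#' @param summ A \code{gene_summary} from \code{\link{group_summaries}}, or
#'   an \code{expression_matrix} (summaries are computed on the fly).
#' @param n1,n2 Group sizes; defaulted from \code{summ} when available.
#' @return A \code{stat_vector} with \code{family = "t"}, \code{delta = 0}
#'   and the raw denominators stored.
#' @seealso \code{\link{s_statistics}}, \code{\link{rescale_statistics}}
#' @export
t_statistics <- function(summ, n1 = summ$n1, n2 = summ$n2) {
  summ <- .as_gene_summary(summ)
  if (n1 < 2L || n2 < 2L) stop("invalid design: need n1 >= 2 and n2 >= 2")
  denom <- sqrt(summ$var1 / n1 + summ$var2 / n2)
  num <- summ$mean1 - summ$mean2
  vals <- num / denom
  vals[denom == 0] <- NaN
  n_bad <- sum(denom == 0)
  if (n_bad > 0L) {
    warning(n_bad, " gene(s) with zero denominator; statistic set to NaN")
  }
  new_stat_vector(vals, denom, family = "t", delta = 0,
                  gene_ids = summ$gene_ids)
}

.as_gene_summary <- function(x) {
  if (inherits(x, "gene_summary")) return(x)
  group_summaries(x)
}

#' Stabilizing constant from a percentile of the t-denominators
#'
#' Returns the requested percentile of the per-gene t-statistic denominators
#' \eqn{\sqrt{s_1^2/n_1 + s_2^2/n_2}}, used as the stabilizing constant
#' \eqn{\delta} of the s-statistic.  The linear-interpolation percentile
#' convention is used (the p-th percentile of n points interpolates at rank
#' \eqn{1 + (n-1)p/100}, \code{\link[stats]{quantile}} type 7).  Non-finite
#' denominators are excluded.
#'
#' @param denominators Numeric vector of t-statistic denominators, or a
#'   \code{stat_vector} (its \code{denominators} are used).
#' @param percentile Percentile in (0, 100).
#' @return A single nonnegative number.
#' @examples
#' delta_from_percentile(c(1, 2, 3, 4, 5), 50)  # 3
#' delta_from_percentile(c(1, 2, 3, 4, 5), 90)  # 4.6
#' @export
delta_from_percentile <- function(denominators, percentile) {
  if (inherits(denominators, "stat_vector"))
    denominators <- denominators$denominators
  stopifnot(is.numeric(percentile), length(percentile) == 1L,
            percentile > 0, percentile < 100)
  d <- denominators[is.finite(denominators)]
  if (length(d) == 0L) stop("no finite denominators")
  unname(stats::quantile(d, percentile / 100, type = 7, names = FALSE))
}

#' SAM s-statistics
#'
#' The SAM statistic adds a nonnegative stabilizing constant \eqn{\delta}
#' to the t-statistic denominator:
#' \deqn{s = (\bar X_1 - \bar X_2) / (\delta + \sqrt{s_1^2/n_1 + s_2^2/n_2}).}
#' With \code{delta = 0} it is elementwise identical to
#' \code{\link{t_statistics}}.
#'
#' @inheritParams t_statistics
#' @param delta Nonnegative stabilizing constant, typically from
#'   \code{\link{delta_from_percentile}}.
#' @param family Label for the statistic family, one of \code{"s30"},
#'   \code{"s50"}, \code{"s70"}, \code{"s90"} (or \code{"t"} when
#'   \code{delta = 0}); purely descriptive.
#' @return A \code{stat_vector}; \code{denominators} holds the raw
#'   (pre-delta) denominators.
#' @export
s_statistics <- function(summ, n1 = summ$n1, n2 = summ$n2, delta,
                         family = "s50") {
  summ <- .as_gene_summary(summ)
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0)
  denom <- sqrt(summ$var1 / n1 + summ$var2 / n2)
  full <- delta + denom
  num <- summ$mean1 - summ$mean2
  vals <- num / full
  vals[full == 0] <- NaN
  n_bad <- sum(full == 0)
  if (n_bad > 0L) {
    warning(n_bad, " gene(s) with zero denominator; statistic set to NaN")
  }
  new_stat_vector(vals, denom, family = family, delta = delta,
                  gene_ids = summ$gene_ids)
}

#' Compute a statistic family on an expression matrix
#'
#' Convenience wrapper: \code{"t"} gives the Welch t-statistic; \code{"s30"},
#' \code{"s50"}, \code{"s70"}, \code{"s90"} give the SAM statistic with
#' \eqn{\delta} at the 30/50/70/90th percentile of the t-denominators.
#'
#' @param data An \code{expression_matrix} or \code{gene_summary}.
#' @param family One of \code{"t"}, \code{"s30"}, \code{"s50"},
#'   \code{"s70"}, \code{"s90"}.
#' @return A \code{stat_vector}.
#' @export
compute_statistics <- function(data,
                               family = c("t", "s30", "s50", "s70", "s90")) {
  family <- match.arg(family)
  summ <- .as_gene_summary(data)
  if (family == "t") return(t_statistics(summ))
  pct <- as.numeric(sub("^s", "", family))
  tt <- suppressWarnings(t_statistics(summ))
  delta <- delta_from_percentile(tt$denominators, pct)
  s_statistics(summ, delta = delta, family = family)
}

#' Rescale s-statistics to the spread of the t-statistics
#'
#' The stabilizing constant pulls s-statistics toward zero, so their spread
#' across genes is smaller than that of the t-statistics computed on the
#' same data.  This transformation multiplies the s-statistics by the factor
#' spread(t)/spread(s), where spread is the standard deviation (\code{"SD"})
#' or interquartile range (\code{"IQR"}) across genes of the signed
#' statistics.  Rescaling preserves the rank order of the statistics.
#' Non-finite entries in either vector are excluded from the spread
#' computation (with a warning) but retained, rescaled, in the output.
#'
#' @param s_stats,t_stats \code{stat_vector}s of equal length computed on
#'   the same data.
#' @param measure Spread measure, \code{"SD"} or \code{"IQR"}.
#' @return A \code{stat_vector} like \code{s_stats} with rescaled values,
#'   \code{rescaled_by} and \code{rescale_factor} recorded.
#' @export
rescale_statistics <- function(s_stats, t_stats, measure = c("SD", "IQR")) {
  measure <- match.arg(measure)
  stopifnot(inherits(s_stats, "stat_vector"),
            inherits(t_stats, "stat_vector"),
            length(s_stats$values) == length(t_stats$values))
  keep <- is.finite(s_stats$values) & is.finite(t_stats$values)
  if (!all(keep)) {
    warning(sum(!keep), " non-finite statistic(s) excluded from spread")
  }
  spread <- switch(measure,
                   SD  = function(v) stats::sd(v),
                   IQR = function(v) stats::IQR(v, type = 7))
  sp_s <- spread(s_stats$values[keep])
  sp_t <- spread(t_stats$values[keep])
  if (!is.finite(sp_s) || sp_s <= 0) {
    stop("degenerate input: zero spread of s-statistics")
  }
  factor <- sp_t / sp_s
  out <- s_stats
  out$values <- s_stats$values * factor
  out$rescaled_by <- measure
  out$rescale_factor <- factor
  out
}
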