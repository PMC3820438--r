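#' Group-label arrangements for permutation
#'
#' Produces \code{B} distinct, non-identity arrangements of the group
#' labels over \code{n1 + n2} sample positions, each encoded as the set of
#' positions assigned to group 1.  The identity arrangement is the first
#' \code{n1} positions (\code{\link{pooled_null_statistics}} orders samples
#' group-1-first before applying labels).  When \code{B} equals the number
#' of available arrangements, \eqn{C(n_1+n_2, n_1) - 1}, all of them are
#' enumerated; otherwise \code{B} are drawn uniformly without replacement,
#' reproducibly from \code{seed}.
#'
#' @param n1,n2 Group sizes.
#' @param B Number of arrangements requested.
#' @param seed Integer seed.
#' @return A list of \code{B} integer vectors (group-1 positions), with
#'   attributes \code{n1}, \code{n2}, \code{seed}.
#' @export
permutation_labels <- function(n1, n2, B, seed = 1L) {
  stopifnot(n1 >= 1L, n2 >= 1L, B >= 1L)
  n <- n1 + n2
  total <- choose(n, n1)
  n_avail <- total - 1
  if (B > n_avail) {
    stop("B = ", B, " exceeds the number of distinct non-identity ",
         "arrangements, C(", n, ",", n1, ") - 1 = ", n_avail)
  }
  set.seed(seed)
  if (total <= 2e5) {
    all_combos <- utils::combn(n, n1, simplify = FALSE)
    identity_key <- paste(seq_len(n1), collapse = ",")
    keys <- vapply(all_combos, paste, character(1L), collapse = ",")
    all_combos <- all_combos[keys != identity_key]
    if (B == n_avail) {
      labels <- all_combos
    } else {
      labels <- all_combos[sample.int(length(all_combos), B)]
    }
  } else {
    # sample distinct random n1-subsets; collision probability is tiny
    labels <- vector("list", B)
    seen <- new.env(hash = TRUE)
    identity_key <- paste(seq_len(n1), collapse = ",")
    assign(identity_key, TRUE, envir = seen)
    i <- 0L
    while (i < B) {
      cand <- sort(sample.int(n, n1))
      key <- paste(cand, collapse = ",")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        i <- i + 1L
        labels[[i]] <- cand
      }
    }
  }
  attr(labels, "n1") <- n1
  attr(labels, "n2") <- n2
  attr(labels, "seed") <- seed
  labels
}

#' Pooled permutation null statistics
#'
#' Recomputes the chosen statistic for every gene under each group-label
#' arrangement and pools all \eqn{G \times B} null values into a single
#' empirical null distribution.  For s-statistic families the stabilizing
#' constant \eqn{\delta} is recomputed within each permutation from the
#' permuted t-denominators.  Samples are ordered group-1-first internally so
#' the identity arrangement equals the observed labeling.
#'
#' @param data An \code{\link{expression_matrix}}.
#' @param family Statistic family (\code{"t"}, \code{"s30"}, \code{"s50"},
#'   \code{"s70"}, \code{"s90"}).
#' @param labels Arrangements from \code{\link{permutation_labels}}; must
#'   match the design of \code{data}.
#' @return An object of class \code{"pooled_null"}: list with
#'   \code{null_values} (length \eqn{G \times B}, non-finite values
#'   dropped and counted in \code{n_nonfinite}), \code{B}, \code{family},
#'   \code{G}, \code{seed}.
#' @export
pooled_null_statistics <- function(data,
                                   family = c("t", "s30", "s50", "s70",
                                              "s90"),
                                   labels) {
  family <- match.arg(family)
  data <- as_expression_matrix(data)
  n1 <- attr(labels, "n1")
  n2 <- attr(labels, "n2")
  if (is.null(n1)) stop("labels must come from permutation_labels()")
  if (n1 != data$n1 || n2 != data$n2)
    stop("labels design (", n1, ",", n2, ") does not match data (",
         data$n1, ",", data$n2, ")")
  ord <- order(data$group != levels(data$group)[1L])  # group 1 first
  x <- data$values[, ord, drop = FALSE]
  B <- length(labels)
  n <- n1 + n2
  G <- nrow(x)

  x2 <- x * x
  tot <- rowSums(x)
  tot2 <- rowSums(x2)
  ind <- matrix(0, n, B)
  for (b in seq_len(B)) ind[labels[[b]], b] <- 1
  s1 <- x %*% ind          # G x B group-1 sums
  ss1 <- x2 %*% ind
  m1 <- s1 / n1
  m2 <- (tot - s1) / n2
  v1 <- (ss1 - n1 * m1 * m1) / (n1 - 1)
  v2 <- ((tot2 - ss1) - n2 * m2 * m2) / (n2 - 1)
  v1[v1 < 0] <- 0          # guard against tiny negative rounding
  v2[v2 < 0] <- 0
  denom <- sqrt(v1 / n1 + v2 / n2)
  num <- m1 - m2
  if (family == "t") {
    vals <- num / denom
    vals[denom == 0] <- NaN
  } else {
    pct <- as.numeric(sub("^s", "", family))
    deltas <- apply(denom, 2L, function(d) {
      d <- d[is.finite(d) & d > 0]
      if (length(d) == 0L) return(0)
      stats::quantile(d, pct / 100, type = 7, names = FALSE)
    })
    full <- sweep(denom, 2L, deltas, `+`)
    vals <- num / full
    vals[full == 0] <- NaN
  }
  vals <- as.vector(vals)
  n_bad <- sum(!is.finite(vals))
  if (n_bad > 0L) vals <- vals[is.finite(vals)]
  structure(
    list(null_values = vals, B = B, family = family, G = G,
         n_nonfinite = n_bad, seed = attr(labels, "seed")),
    class = "pooled_null"
  )
}

#' @export
print.pooled_null <- function(x, ...) {
  cat(sprintf(
    "Pooled permutation null: %d genes x %d permutations (%s family)\n",
    x$G, x$B, x$family))
  if (x$n_nonfinite > 0L)
    cat(sprintf("  %d non-finite null value(s) dropped\n", x$n_nonfinite))
  invisible(x)
}

#' Pooled-null P-values
#'
#' Two-sided P-values from the pooled permutation null:
#' \deqn{p_g = (\#\{|null| \ge |obs_g|\} + 1) / (N_{null} + 1),}
#' where ties count against significance and the add-one correction keeps
#' every P-value strictly positive (as required by the mixture-model
#' estimators).  P-values are a nonincreasing function of the absolute
#' statistic.  Ties are detected with a small relative tolerance
#' (\code{1e-9}) so that mathematically exact ties — e.g. the negated
#' statistics produced by complementary label arrangements in balanced
#' designs — count as ties despite floating-point noise between
#' computation routes.
#'
#' @param observed A \code{stat_vector} of observed statistics.
#' @param null A \code{pooled_null} of the same statistic family.
#' @return An object of class \code{"pvalue_vector"}: list with
#'   \code{values} in (0, 1] (\code{NA} for non-finite observed
#'   statistics), \code{source = "pooled_null"}, \code{two_sided = TRUE}.
#' @export
pooled_null_pvalues <- function(observed, null) {
  stopifnot(inherits(observed, "stat_vector"), inherits(null, "pooled_null"))
  if (observed$family != null$family)
    stop("statistic family mismatch: observed ", observed$family,
         ", null ", null$family)
  if (length(null$null_values) == 0L) stop("empty null distribution")
  a <- sort(abs(null$null_values))
  n_null <- length(a)
  obs <- abs(observed$values)
  ok <- is.finite(obs)
  # #{|null| < |obs|}, with near-equal values (relative 1e-9) as ties
  thr <- obs[ok] * (1 - 1e-9) - 1e-300
  n_less <- findInterval(thr, a, left.open = TRUE)
  p <- rep(NA_real_, length(obs))
  p[ok] <- (n_null - n_less + 1) / (n_null + 1)
  if (any(!ok)) warning(sum(!ok), " non-finite statistic(s): P-value NA")
  new_pvalue_vector(p, source = "pooled_null")
}

#' @keywords internal
#' @noRd
new_pvalue_vector <- function(values, source, two_sided = TRUE) {
  structure(list(values = values, source = source, two_sided = two_sided),
            class = "pvalue_vector")
}

#' @export
print.pvalue_vector <- function(x, ...) {
  cat(sprintf("P-values: %d genes, source %s%s\n", length(x$values),
              x$source, if (x$two_sided) " (two-sided)" else ""))
  print(summary(x$values))
  invisible(x)
}

# internal: accept pvalue_vector or plain numeric in (0,1]
.as_pvalues <- function(p, require_positive = TRUE) {
  if (inherits(p, "pvalue_vector")) p <- p$values
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no P-values")
  if (any(!is.finite(p)) || any(p > 1) || any(p < 0))
    stop("P-values must be finite and in [0, 1]")
  if (require_positive && any(p == 0))
    stop("P-values must be strictly positive (use add-one pooled-null or ",
         "parametric P-values)")
  p
}
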