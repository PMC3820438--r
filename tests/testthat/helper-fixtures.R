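# small random two-group datasets used across tests
make_dataset <- function(G = 50, n1 = 5, n2 = 4, seed = 1,
                         delta_mean = 0) {
  set.seed(seed)
  vals <- matrix(rnorm(G * (n1 + n2)), G, n1 + n2)
  vals[, seq_len(n1)] <- vals[, seq_len(n1)] + delta_mean
  expression_matrix(vals, group = rep(c("A", "B"), c(n1, n2)))
}

# linear-interpolation percentile computed from first principles
interp_percentile <- function(x, pct) {
  x <- sort(x)
  h <- 1 + (length(x) - 1) * pct / 100
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force weighted pool-adjacent-violators for a nonincreasing fit
pava_nonincreasing <- function(y, w) {
  vals <- as.list(y)
  wts <- as.list(w)
  i <- 1L
  while (i < length(vals)) {
    if (vals[[i]] < vals[[i + 1L]] - 1e-15) {
      merged_w <- wts[[i]] + wts[[i + 1L]]
      merged_v <- (vals[[i]] * wts[[i]] + vals[[i + 1L]] * wts[[i + 1L]]) /
        merged_w
      vals[[i]] <- merged_v
      wts[[i]] <- merged_w
      vals[[i + 1L]] <- NULL
      wts[[i + 1L]] <- NULL
      i <- max(1L, i - 1L)
    } else {
      i <- i + 1L
    }
  }
  list(values = unlist(vals), weights = unlist(wts))
}

# Grenander-density oracle via PAVA on the raw ECDF slopes; returns the raw
# partition (right endpoints and per-interval step heights), the standard
# dual route to the least-concave-majorant construction
grenander_oracle <- function(p) {
  n <- length(p)
  tab <- table(p)
  x <- c(0, as.numeric(names(tab)))
  y <- c(0, cumsum(as.integer(tab)) / n)
  if (max(x) < 1) { x <- c(x, 1); y <- c(y, 1) }
  dx <- diff(x)
  fit <- pava_nonincreasing(diff(y) / dx, dx)
  n_merged <- integer(length(fit$weights))
  j <- 1L
  for (i in seq_along(fit$weights)) {
    acc <- 0
    k <- 0L
    while (acc < fit$weights[i] - 1e-12) {
      acc <- acc + dx[j]
      j <- j + 1L
      k <- k + 1L
    }
    n_merged[i] <- k
  }
  list(right = x[-1L], heights = rep(fit$values, times = n_merged),
       midpoints = (x[-1L] + x[-length(x)]) / 2)
}
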