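#' Synthetic gene-parameter table
#'
#' Emulates the per-gene parameter source of a two-population expression
#' study: for each gene a pair of group means (rounded to the nearest 0.1,
#' so equality of means is exact) and a pair of positive standard
#' deviations (the "observed" group-A-like and group-B-like SDs).  Exactly
#' \code{round(pi1 * G)} genes are flagged differentially expressed and
#' given a nonzero rounded mean shift.
#'
#' Defaults: baseline means Normal(7, 1.5) (log2-expression-like scale),
#' SDs log-normal with log-mean -0.7 and log-SD 0.6 drawn independently
#' per gene and group source, DE shifts \eqn{\Delta \sim N(0,
#' \code{effect_scale})} re-drawn until the rounded means differ.
#'
#' @param G Number of genes.
#' @param pi1 Target proportion of DE genes in [0, 1).
#' @param seed Integer seed.
#' @param effect_scale SD of the mean-shift distribution (default 0.5).
#' @param mean_loc,mean_scale Baseline mean distribution parameters.
#' @param sd_meanlog,sd_sdlog Log-normal SD distribution parameters.
#' @return A data frame of class \code{"gene_parameter_table"} with columns
#'   \code{gene_id}, \code{mu1}, \code{mu2}, \code{sd_A}, \code{sd_B},
#'   \code{is_de}.
#' @export
synth_parameter_table <- function(G, pi1, seed = 1L, effect_scale = 0.5,
                                  mean_loc = 7, mean_scale = 1.5,
                                  sd_meanlog = -0.7, sd_sdlog = 0.6) {
  stopifnot(G >= 1L, pi1 >= 0, pi1 < 1)
  n_de <- round(pi1 * G)
  if (n_de >= G) stop("pi1 * G rounds to G; must leave null genes")
  set.seed(seed)
  mu1 <- round(stats::rnorm(G, mean_loc, mean_scale), 1)
  sd_A <- stats::rlnorm(G, sd_meanlog, sd_sdlog)
  sd_B <- stats::rlnorm(G, sd_meanlog, sd_sdlog)
  mu2 <- mu1
  is_de <- rep(FALSE, G)
  if (n_de > 0L) {
    de_idx <- sample.int(G, n_de)
    is_de[de_idx] <- TRUE
    for (i in de_idx) {
      repeat {
        cand <- round(mu1[i] + stats::rnorm(1L, 0, effect_scale), 1)
        if (cand != mu1[i]) break
      }
      mu2[i] <- cand
    }
  }
  out <- data.frame(gene_id = paste0("gene", seq_len(G)),
                    mu1 = mu1, mu2 = mu2, sd_A = sd_A, sd_B = sd_B,
                    is_de = is_de, stringsAsFactors = FALSE)
  class(out) <- c("gene_parameter_table", "data.frame")
  out
}

#' Scenario configuration
#'
#' One cell of the simulation factorial.
#'
#' @param sim_type Variance regime: \code{"EV"} (both groups use the
#'   group-A SD), \code{"UV1"} (each group its own SD), \code{"UV2"}
#'   (roles swapped).
#' @param n1,n2 Group sample sizes.
#' @param pi1 Proportion of DE genes.
#' @param G Number of genes (default 10000).
#' @param rescale Spread measure for s-statistic rescaling.
#' @param input_spec Declared input family for the empirical-null
#'   estimator.
#' @param replicate Replicate index.
#' @param seed Integer seed.
#' @return A list of class \code{"scenario_config"}.
#' @export
scenario_config <- function(sim_type = c("EV", "UV1", "UV2"), n1, n2, pi1,
                            G = 10000L, rescale = c("SD", "IQR"),
                            input_spec = c("t", "z"), replicate = 1L,
                            seed = 1L) {
  sim_type <- match.arg(sim_type)
  rescale <- match.arg(rescale)
  input_spec <- match.arg(input_spec)
  stopifnot(n1 >= 2L, n2 >= 2L, pi1 >= 0, pi1 < 1, G >= 1L)
  structure(list(sim_type = sim_type, n1 = as.integer(n1),
                 n2 = as.integer(n2), pi1 = pi1, G = as.integer(G),
                 rescale = rescale, input_spec = input_spec,
                 replicate = as.integer(replicate),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a two-group expression dataset
#'
#' Draws all values from independent normal distributions: group-1 samples
#' from Normal(\code{mu1}, \eqn{\sigma_1}) and group-2 samples from
#' Normal(\code{mu2}, \eqn{\sigma_2}) per gene, with the SD pair set by the
#' variance regime: EV uses (\code{sd_A}, \code{sd_A}), UV1 uses
#' (\code{sd_A}, \code{sd_B}), UV2 uses (\code{sd_B}, \code{sd_A}).
#'
#' @param params A \code{\link{synth_parameter_table}} (or any data frame
#'   with columns \code{mu1}, \code{mu2}, \code{sd_A}, \code{sd_B},
#'   \code{is_de}).
#' @param config A \code{\link{scenario_config}}; \code{config$G} genes are
#'   used (the first \code{G} rows of \code{params} must exist).
#' @return A list of class \code{"simulated_dataset"}: \code{data} (an
#'   \code{\link{expression_matrix}}), \code{truth} (logical DE vector),
#'   \code{config}.
#' @export
simulate_dataset <- function(params, config) {
  stopifnot(inherits(config, "scenario_config"),
            all(c("mu1", "mu2", "sd_A", "sd_B", "is_de") %in% names(params)))
  G <- config$G
  if (nrow(params) < G) stop("parameter table has fewer than G rows")
  params <- params[seq_len(G), , drop = FALSE]
  sd1 <- switch(config$sim_type, EV = params$sd_A, UV1 = params$sd_A,
                UV2 = params$sd_B)
  sd2 <- switch(config$sim_type, EV = params$sd_A, UV1 = params$sd_B,
                UV2 = params$sd_A)
  set.seed(config$seed)
  n1 <- config$n1
  n2 <- config$n2
  x1 <- matrix(stats::rnorm(G * n1, mean = params$mu1, sd = sd1), G, n1)
  x2 <- matrix(stats::rnorm(G * n2, mean = params$mu2, sd = sd2), G, n2)
  vals <- cbind(x1, x2)
  colnames(vals) <- c(paste0("A", seq_len(n1)), paste0("B", seq_len(n2)))
  ids <- if ("gene_id" %in% names(params)) params$gene_id else NULL
  data <- expression_matrix(vals, group = rep(c("A", "B"), c(n1, n2)),
                            gene_ids = ids)
  structure(list(data = data, truth = params$is_de, config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated dataset: %s, %d genes x (%d + %d) samples, pi1 = %g\n",
    x$config$sim_type, x$config$G, x$config$n1, x$config$n2,
    x$config$pi1))
  invisible(x)
}

#' Simulation scenario grid
#'
#' The benchmark factorial.  The initial stage crosses three sample sizes
#' (60, 45), (16, 12), (8, 6) — all keeping the 4:3 ratio — with
#' \eqn{\pi_1 \in \{0.01, 0.05, 0.10, 0.25\}}, three variance regimes
#' (EV, UV1, UV2), two rescaling factors (SD, IQR) and two input
#' specifications (t, z): 144 scenarios.  The extended stage adds EV-only
#' scenarios at \eqn{\pi_1 \in \{0.005, 0.02, 0.03, 0.04\}}: 48 more, so
#' the full grid has 192.  Replicate expansion (20 per scenario in the
#' benchmark design) is left to \code{\link{run_study}}.
#'
#' @param stage \code{"initial"}, \code{"extended"} or \code{"full"}.
#' @param G Number of genes per dataset (default 10000).
#' @return A data frame with one row per scenario (columns
#'   \code{sim_type}, \code{n1}, \code{n2}, \code{pi1}, \code{G},
#'   \code{rescale}, \code{input_spec}).
#' @export
scenario_grid <- function(stage = c("initial", "extended", "full"),
                          G = 10000L) {
  stage <- match.arg(stage)
  sizes <- data.frame(n1 = c(60L, 16L, 8L), n2 = c(45L, 12L, 6L))
  make <- function(pi1s, sim_types) {
    g <- expand.grid(size = seq_len(nrow(sizes)), pi1 = pi1s,
                     sim_type = sim_types, rescale = c("SD", "IQR"),
                     input_spec = c("t", "z"), stringsAsFactors = FALSE)
    data.frame(sim_type = g$sim_type, n1 = sizes$n1[g$size],
               n2 = sizes$n2[g$size], pi1 = g$pi1, G = G,
               rescale = g$rescale, input_spec = g$input_spec,
               stringsAsFactors = FALSE)
  }
  initial <- make(c(0.01, 0.05, 0.10, 0.25), c("EV", "UV1", "UV2"))
  extended <- make(c(0.005, 0.02, 0.03, 0.04), "EV")
  switch(stage, initial = initial, extended = extended,
         full = rbind(initial, extended))
}

#' Derive a per-replicate seed
#'
#' Deterministic derivation master seed -> scenario -> replicate, so any
#' single result row can be regenerated in isolation.  Kept below 2^31.
#'
#' @param master Master seed.
#' @param scenario_index Scenario row number (1-based).
#' @param replicate Replicate index (1-based).
#' @return An integer seed.
#' @export
derive_seed <- function(master, scenario_index, replicate) {
  as.integer((as.numeric(master) * 48271 + scenario_index * 69621 +
                replicate * 16807) %% 2147483647)
}
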