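#' Empirical ROC curve for ranking genes by absolute statistic
#'
#' Genes are ranked by \eqn{|statistic|} descending; all genes tied at one
#' value advance together (one threshold step per distinct absolute
#' value).  The curve starts at (0, 0) and ends at (1, 1); the AUC is the
#' trapezoidal integral of the true-positive fraction over the
#' false-positive fraction.  AUC is invariant under any strictly
#' increasing transform of the absolute statistic.
#'
#' @param stats A \code{stat_vector} or numeric vector.
#' @param truth Logical vector: \code{TRUE} for truly DE genes.
#' @return An object of class \code{"roc_curve"}: list with
#'   \code{thresholds} (descending distinct absolute values), \code{fpf},
#'   \code{tpf} (each starting at 0) and \code{auc}.
#' @export
roc_curve <- function(stats, truth) {
  v <- if (inherits(stats, "stat_vector")) stats$values else as.numeric(stats)
  truth <- as.logical(truth)
  stopifnot(length(v) == length(truth))
  keep <- is.finite(v) & !is.na(truth)
  v <- abs(v[keep])
  truth <- truth[keep]
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stop("truth must contain at least one DE and one non-DE gene")
  ord <- order(v, decreasing = TRUE)
  v <- v[ord]
  truth <- truth[ord]
  # group ties into single steps
  grp <- cumsum(!duplicated(v))
  tp <- cumsum(truth)
  fp <- cumsum(!truth)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpf <- c(0, tp[last] / n_pos)
  fpf <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpf) * (utils::head(tpf, -1) + utils::tail(tpf, -1)) / 2)
  structure(list(thresholds = v[last], fpf = fpf, tpf = tpf, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d threshold steps, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpf, x$tpf, type = "l", xlab = "False positive fraction",
       ylab = "True positive fraction", xlim = c(0, 1), ylim = c(0, 1),
       ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

.stat_families <- c("t", "s30", "s50", "s70", "s90")

# all five statistic families from one set of group summaries
.all_family_stats <- function(summ) {
  tt <- suppressWarnings(t_statistics(summ))
  out <- list(t = tt)
  for (fam in c("s30", "s50", "s70", "s90")) {
    pct <- as.numeric(sub("^s", "", fam))
    delta <- delta_from_percentile(tt$denominators, pct)
    out[[fam]] <- suppressWarnings(
      s_statistics(summ, delta = delta, family = fam))
  }
  out
}

#' Run the simulation benchmark
#'
#' For each scenario and replicate: simulate a dataset, compute the
#' t-statistic and the four s-statistics, rescale the s-statistics per the
#' scenario's spread measure, and estimate \eqn{\pi_1} with the three
#' estimators — the empirical-null fit on the (rescaled) statistics using
#' the scenario's input specification, and the Storey smoother and convex
#' NPMLE on pooled permutation null P-values.  One result row is appended
#' per (statistic family, estimator).  Individual estimator failures are
#' recorded as \code{NA} with the error message in \code{note}, never
#' aborting the grid.
#'
#' @param grid A scenario data frame from \code{\link{scenario_grid}} (any
#'   subset of rows / custom rows with the same columns).
#' @param replicates Replicates per scenario.
#' @param B Number of label permutations for the pooled null.
#' @param master_seed Master seed; per-replicate seeds derive from it via
#'   \code{\link{derive_seed}}.
#' @param estimators Subset of \code{c("empirical_null", "storey",
#'   "convest")} to run.
#' @param families Subset of statistic families to evaluate.
#' @param verbose Print one progress line per scenario/replicate.
#' @return A data frame of study result rows (see
#'   \code{\link{write_results_csv}} for the schema).
#' @export
run_study <- function(grid, replicates = 5L, B = 100L, master_seed = 1L,
                      estimators = c("empirical_null", "storey", "convest"),
                      families = .stat_families, verbose = FALSE) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  families <- match.arg(families, .stat_families, several.ok = TRUE)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    sc <- grid[i, ]
    for (r in seq_len(replicates)) {
      seed <- derive_seed(master_seed, i, r)
      cfg <- scenario_config(sc$sim_type, sc$n1, sc$n2, sc$pi1, sc$G,
                             sc$rescale, sc$input_spec, replicate = r,
                             seed = seed)
      if (verbose)
        message(sprintf("scenario %d/%d replicate %d (seed %d)",
                        i, nrow(grid), r, seed))
      params <- synth_parameter_table(cfg$G, cfg$pi1, seed = seed)
      ds <- simulate_dataset(params, cfg)
      summ <- group_summaries(ds$data)
      all_stats <- .all_family_stats(summ)

      need_pooled <- any(c("storey", "convest") %in% estimators)
      labels <- if (need_pooled)
        permutation_labels(cfg$n1, cfg$n2, B, seed = seed) else NULL

      for (fam in families) {
        st <- all_stats[[fam]]
        if ("empirical_null" %in% estimators) {
          st_in <- if (fam == "t") st else
            rescale_statistics(st, all_stats$t, measure = cfg$rescale)
          fit <- tryCatch(
            estimate_pi0_empirical_null(
              st_in, input_family = cfg$input_spec,
              df = cfg$n1 + cfg$n2 - 2),
            error = function(e) e)
          rows[[length(rows) + 1L]] <-
            .result_row(cfg, fam, "empirical_null", fit)
        }
        if (need_pooled) {
          pv <- tryCatch({
            null <- pooled_null_statistics(ds$data, family = fam,
                                           labels = labels)
            pooled_null_pvalues(st, null)
          }, error = function(e) e)
          if ("storey" %in% estimators) {
            fit <- if (inherits(pv, "error")) pv else
              tryCatch(estimate_pi0_storey(pv), error = function(e) e)
            rows[[length(rows) + 1L]] <-
              .result_row(cfg, fam, "storey", fit)
          }
          if ("convest" %in% estimators) {
            fit <- if (inherits(pv, "error")) pv else
              tryCatch(estimate_pi0_convest(pv), error = function(e) e)
            rows[[length(rows) + 1L]] <-
              .result_row(cfg, fam, "convest", fit)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' @keywords internal
#' @noRd
.result_row <- function(cfg, family, estimator, fit) {
  failed <- inherits(fit, "error")
  data.frame(sim_type = cfg$sim_type, n1 = cfg$n1, n2 = cfg$n2,
             pi1 = cfg$pi1, G = cfg$G, rescale = cfg$rescale,
             input_spec = cfg$input_spec, replicate = cfg$replicate,
             seed = cfg$seed, family = family, estimator = estimator,
             pi1_hat = if (failed) NA_real_ else fit$pi1,
             note = if (failed) conditionMessage(fit) else "",
             stringsAsFactors = FALSE)
}

#' Summarize estimator bias and variability
#'
#' Robust per-cell summaries of the study results: the median and IQR of
#' \eqn{\hat\pi_1} over replicates and the bias (median minus true
#' \eqn{\pi_1}), labelled conservative (\eqn{\hat\pi_1 < \pi_1}) or
#' anticonservative.  Quantiles use the linear-interpolation convention
#' (type 7).
#'
#' @param results A result table from \code{\link{run_study}}.
#' @param group_by Columns defining a summary cell.
#' @return A data frame with one row per cell: the grouping columns plus
#'   \code{n_replicates}, \code{median_pi1_hat}, \code{iqr_pi1_hat},
#'   \code{bias}, \code{direction}.
#' @export
summarize_bias <- function(results,
                           group_by = c("sim_type", "n1", "n2", "pi1",
                                        "rescale", "input_spec", "family",
                                        "estimator")) {
  stopifnot(all(group_by %in% names(results)),
            all(c("pi1", "pi1_hat") %in% names(results)))
  ok <- !is.na(results$pi1_hat)
  if (!all(ok)) {
    warning(sum(!ok), " failed estimate(s) omitted from summaries")
    results <- results[ok, , drop = FALSE]
  }
  if (nrow(results) == 0L) {
    warning("no successful estimates; empty summary")
    return(results[, group_by, drop = FALSE])
  }
  key <- interaction(results[group_by], drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(results, key), function(cell) {
    est <- cell$pi1_hat
    med <- stats::median(est)
    bias <- med - cell$pi1[1L]
    out <- cell[1L, group_by, drop = FALSE]
    out$n_replicates <- nrow(cell)
    out$median_pi1_hat <- med
    out$iqr_pi1_hat <- stats::IQR(est, type = 7)
    out$bias <- bias
    out$direction <- if (bias < 0) "conservative" else
      if (bias > 0) "anticonservative" else "unbiased"
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
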