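#' Two-group expression matrix
#'
#' Container for a genes x samples expression matrix (possibly
#' log-transformed values) with a two-level group factor over the samples.
#' All downstream statistics treat the first factor level as group 1.
#'
#' @param values Numeric matrix, genes in rows, samples in columns; no
#'   missing values.
#' @param group Factor (or coercible) of length \code{ncol(values)} with
#'   exactly two levels; each level must occur at least twice.
#' @param gene_ids Unique gene identifiers; defaults to rownames or
#'   \code{gene1..geneG}.
#' @return An object of class \code{"expression_matrix"}: a list with
#'   \code{values}, \code{gene_ids}, \code{group}, \code{n1}, \code{n2}.
#' @examples
#' m <- matrix(rnorm(20), nrow = 5)
#' expression_matrix(m, group = rep(c("A", "B"), each = 2))
#' @export
expression_matrix <- function(values, group, gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("missing values in expression matrix")
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) != 2L)
    stop("group must have exactly two levels, got ", nlevels(group))
  if (length(group) != ncol(values))
    stop("group length (", length(group), ") != number of samples (",
         ncol(values), ")")
  if (any(table(group) < 2L))
    stop("invalid design: each group needs at least 2 samples")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length != number of genes")
  structure(
    list(values = values, gene_ids = gene_ids, group = group,
         n1 = sum(group == levels(group)[1L]),
         n2 = sum(group == levels(group)[2L])),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s: %d, %s: %d)\n",
              nrow(x$values), ncol(x$values),
              levels(x$group)[1L], x$n1, levels(x$group)[2L], x$n2))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x Object to coerce.
#' @export
as_expression_matrix <- function(x) {
  if (inherits(x, "expression_matrix")) return(x)
  if (is.list(x) && !is.null(x$data) &&
      inherits(x$data, "expression_matrix")) return(x$data)
  stop("cannot coerce object of class '", class(x)[1L],
       "' to expression_matrix")
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Group membership comes either from a two-column (sample, group) TSV via
#' \code{groups}, or from \code{group_sizes = c(n1, n2)} applied to the
#' columns in order.
#'
#' @param path Path to the expression TSV.
#' @param groups Path to a sample-to-group TSV (two columns, no header
#'   needed; a header line is auto-detected), or \code{NULL}.
#' @param group_sizes Integer vector \code{c(n1, n2)}; used when
#'   \code{groups} is \code{NULL}.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression_tsv <- function(path, groups = NULL, group_sizes = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("expected gene-id column plus >= 2 samples")
  gene_ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1L)))
    stop("non-numeric expression column(s): ",
         paste(colnames(tab)[-1L][bad], collapse = ", "))
  }
  if (anyNA(vals)) {
    bad_rows <- which(rowSums(is.na(vals)) > 0)
    stop("missing value(s) in data row(s): ",
         paste(utils::head(bad_rows, 5L), collapse = ", "))
  }
  sample_ids <- colnames(vals)
  if (!is.null(groups)) {
    g <- utils::read.delim(groups, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
    # drop an optional header line
    if (nrow(g) == length(sample_ids) + 1L &&
        !g[1L, 1L] %in% sample_ids) g <- g[-1L, , drop = FALSE]
    if (ncol(g) < 2L) stop("group file needs two columns: sample, group")
    idx <- match(sample_ids, as.character(g[[1L]]))
    if (anyNA(idx)) {
      stop("unresolved sample(s) in group file: ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    }
    group <- as.character(g[[2L]])[idx]
  } else if (!is.null(group_sizes)) {
    stopifnot(length(group_sizes) == 2L,
              sum(group_sizes) == length(sample_ids))
    group <- rep(c("group1", "group2"), times = group_sizes)
  } else {
    stop("provide either `groups` or `group_sizes`")
  }
  expression_matrix(vals, group = group, gene_ids = gene_ids)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are serialized at full precision (round-trips exactly through
#' \code{\link{read_expression_tsv}}).
#'
#' @param x An \code{expression_matrix} or \code{simulated_dataset}.
#' @param path Output TSV path.
#' @param groups_path Optional path for a companion (sample, group) TSV.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(x, path, groups_path = NULL) {
  x <- as_expression_matrix(x)
  sample_ids <- colnames(x$values)
  if (is.null(sample_ids))
    sample_ids <- paste0("sample", seq_len(ncol(x$values)))
  header <- paste(c("gene_id", sample_ids), collapse = "\t")
  body <- paste(x$gene_ids,
                apply(x$values, 1L, function(r)
                  paste(format(r, digits = 17, trim = TRUE,
                               scientific = FALSE), collapse = "\t")),
                sep = "\t")
  writeLines(c(header, body), path)
  if (!is.null(groups_path)) {
    writeLines(paste(sample_ids, as.character(x$group), sep = "\t"),
               groups_path)
  }
  invisible(path)
}

# fixed schema for study result tables
.result_columns <- c("sim_type", "n1", "n2", "pi1", "G", "rescale",
                     "input_spec", "replicate", "seed", "family",
                     "estimator", "pi1_hat", "note")

#' Write / read study result tables
#'
#' Study results (one row per scenario x replicate x statistic family x
#' estimator) round-trip losslessly through CSV with a fixed, documented
#' header.  Unknown extra columns are preserved with a warning on read;
#' missing schema columns are an error.
#'
#' @param rows A data frame of study results (see \code{\link{run_study}}).
#' @param path CSV path.
#' @return \code{write_results_csv}: \code{path} invisibly;
#'   \code{read_results_csv}: the data frame.
#' @export
write_results_csv <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  missing_cols <- setdiff(.result_columns, names(rows))
  if (length(missing_cols) > 0L)
    stop("result table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("note" %in% names(tab)) {
    tab$note <- as.character(tab$note)
    tab$note[is.na(tab$note)] <- ""
  }
  missing_cols <- setdiff(.result_columns, names(tab))
  if (length(missing_cols) > 0L)
    stop("result file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(tab), .result_columns)
  if (length(extra) > 0L)
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "))
  tab
}
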