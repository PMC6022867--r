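# Co-expression ranking and fold-change tables ---------------------------
#
# ECG ("expression-correlated genes") lists rank every gene by the Pearson
# correlation of its expression profile with a query gene across all
# samples; ECG200 is the top-200 list. Condition contrasts are summarized
# as log2 fold changes of group means, the quantity condition heatmaps
# display.

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, genes in rows, samples in columns; finite,
#'   non-negative.
#' @param gene_ids,sample_ids Row and column identifiers; must be unique.
#'   Default to the dimnames of `values`.
#' @param group_labels Optional named character vector mapping sample id to
#'   condition label.
#' @return An `acscan_expression` with fields `values` (dimnamed matrix)
#'   and `group_labels`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              group_labels = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample ids are required", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!is.null(group_labels)) {
    group_labels <- unlist(group_labels)
    unknown <- setdiff(names(group_labels), sample_ids)
    if (length(unknown) > 0L)
      stop("group labels for unknown sample(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  em <- list(values = values, group_labels = group_labels)
  class(em) <- "acscan_expression"
  em
}

#' @export
print.acscan_expression <- function(x, ...) {
  cat("<expression matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples", sep = "")
  if (!is.null(x$group_labels))
    cat("; conditions: ",
        paste(unique(x$group_labels), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Dialect: tab-separated, header row of sample ids, first column gene ids.
#' An optional two-column group-label TSV (`sample`, `condition`) attaches
#' condition labels.
#'
#' @param path Path to the expression TSV.
#' @param groups_path Optional path to the group-label TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, groups_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs gene ids plus >= 1 sample",
                          call. = FALSE)
  genes <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  groups <- NULL
  if (!is.null(groups_path)) {
    g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
    if (ncol(g) < 2L) stop("group TSV needs sample and condition columns",
                           call. = FALSE)
    groups <- stats::setNames(as.character(g[[2]]), as.character(g[[1]]))
  }
  expression_matrix(vals, gene_ids = genes, sample_ids = colnames(vals),
                    group_labels = groups)
}

#' Write an expression matrix to TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output TSV path.
#' @param groups_path Optional path for the group-label TSV.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(em, path, groups_path = NULL) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path) && !is.null(em$group_labels)) {
    g <- data.frame(sample = names(em$group_labels),
                    condition = unname(em$group_labels))
    utils::write.table(g, groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Pearson product-moment correlation with strict input checks
#'
#' @param x,y Numeric vectors of equal length >= 3, each with non-zero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 3, 2))  # 0.5
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Rank genes by correlation with a query gene (ECG list)
#'
#' Computes the Pearson correlation of every other gene's profile with the
#' query gene across all samples and returns the top `k` (the ECG-k list).
#' The query gene is excluded; genes with zero variance (undefined r) are
#' dropped with a warning. Ties in r are broken by gene id so the ranking
#' is deterministic.
#'
#' @param em An [expression_matrix()].
#' @param query_gene Gene id to rank against.
#' @param k List size (default 200, the conventional ECG200); clipped to
#'   the number of eligible genes.
#' @return Data frame `gene_id`, `r`, `rank`, sorted by descending `r`,
#'   with attribute `min_r` (smallest correlation in the returned list).
#' @export
top_correlated <- function(em, query_gene, k = 200L) {
  stopifnot(inherits(em, "acscan_expression"))
  if (!query_gene %in% rownames(em$values))
    stop("query gene '", query_gene, "' not in matrix", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  q <- em$values[query_gene, ]
  if (stats::sd(q) == 0)
    stop("query gene has zero variance; correlation undefined", call. = FALSE)
  others <- setdiff(rownames(em$values), query_gene)
  sds <- apply(em$values[others, , drop = FALSE], 1, stats::sd)
  degenerate <- others[sds == 0]
  if (length(degenerate) > 0L)
    warning(length(degenerate),
            " gene(s) with zero variance excluded from ranking: ",
            paste(utils::head(degenerate, 5), collapse = ", "), call. = FALSE)
  eligible <- setdiff(others, degenerate)
  r <- as.numeric(stats::cor(t(em$values[eligible, , drop = FALSE]), q))
  ord <- order(-r, eligible)
  n_out <- min(as.integer(k), length(eligible))
  idx <- ord[seq_len(n_out)]
  out <- data.frame(gene_id = eligible[idx], r = r[idx],
                    rank = seq_len(n_out), stringsAsFactors = FALSE)
  attr(out, "min_r") <- if (n_out > 0L) min(out$r) else NA_real_
  out
}

#' Log2 fold change of group means between two conditions
#'
#' For each selected gene, `log2(mean(treatment) / mean(control))` over the
#' samples labelled with each condition. Intensities are assumed positive
#' (microarray-style); a non-positive group mean is an error rather than
#' being pseudocounted.
#'
#' @param em An [expression_matrix()] with `group_labels`.
#' @param treatment,control Condition labels.
#' @param genes Genes to report; defaults to all.
#' @return Data frame `gene_id`, `mean_treatment`, `mean_control`,
#'   `log2fc`, in input gene order.
#' @export
log2_fold_change <- function(em, treatment, control,
                             genes = rownames(em$values)) {
  stopifnot(inherits(em, "acscan_expression"))
  if (is.null(em$group_labels))
    stop("expression matrix has no condition labels", call. = FALSE)
  labs <- em$group_labels
  t_samples <- names(labs)[labs == treatment]
  c_samples <- names(labs)[labs == control]
  if (length(t_samples) == 0L)
    stop("no samples labelled '", treatment, "'", call. = FALSE)
  if (length(c_samples) == 0L)
    stop("no samples labelled '", control, "'", call. = FALSE)
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing) > 0L)
    stop("gene(s) not in matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  mt <- rowMeans(em$values[genes, t_samples, drop = FALSE])
  mc <- rowMeans(em$values[genes, c_samples, drop = FALSE])
  bad <- genes[mt <= 0 | mc <= 0]
  if (length(bad) > 0L)
    stop("non-positive group mean for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; fold change requires positive intensities", call. = FALSE)
  data.frame(gene_id = genes, mean_treatment = unname(mt),
             mean_control = unname(mc), log2fc = unname(log2(mt / mc)),
             stringsAsFactors = FALSE)
}
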