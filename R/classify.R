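#' Classify genes as upregulated / non-responsive / unclassified
#'
#' Applies the expression cutoffs used to build the two gene groups for
#' promoter enrichment: a gene is `upregulated` when its treatment-vs-mock
#' p-value is below `p_up` at both timepoints, and `non_responsive` when the
#' p-value exceeds `p_nr` at both timepoints and its normalized read counts
#' stay above `min_count` (evidence of expression, so "no change" is not
#' just "not expressed"). All inequalities are strict. Everything else is
#' `unclassified`. No multiple-testing correction is applied; the cutoffs
#' act on raw p-values.
#'
#' @param stats A data.frame with columns `gene_id`, two p-value columns
#'   (defaults `p_10h`, `p_3d`) and one or more numeric count columns (all
#'   remaining numeric columns unless `count_cols` is given).
#' @param p_up Upregulation cutoff (default 0.01).
#' @param p_nr Non-responsiveness cutoff (default 0.9).
#' @param min_count Floor on summarized normalized counts (default 100).
#' @param p_cols Names of the two p-value columns.
#' @param count_cols Optional explicit count column names.
#' @param count_summary How to summarize counts across samples before the
#'   `min_count` comparison: `"mean"` (default) or `"min"`.
#' @return `stats` with an appended factor column `label` with levels
#'   `upregulated`, `non_responsive`, `unclassified`; the labels partition
#'   the input genes.
#' @export
classify_genes <- function(stats, p_up = 0.01, p_nr = 0.9, min_count = 100,
                           p_cols = c("p_10h", "p_3d"), count_cols = NULL,
                           count_summary = c("mean", "min")) {
  count_summary <- match.arg(count_summary)
  stopifnot(is.data.frame(stats), "gene_id" %in% names(stats),
            all(p_cols %in% names(stats)), length(p_cols) == 2L)
  p1 <- stats[[p_cols[1]]]
  p2 <- stats[[p_cols[2]]]
  bad <- is.na(p1) | is.na(p2)
  if (any(bad))
    stop("missing p-value for gene(s): ",
         paste(utils::head(stats$gene_id[bad], 5), collapse = ", "))
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1))
    stop("p-values must lie in [0, 1]")
  if (is.null(count_cols)) {
    count_cols <- setdiff(names(stats)[vapply(stats, is.numeric, logical(1))],
                          p_cols)
  }
  if (length(count_cols) == 0L)
    stop("no count columns found")
  cm <- as.matrix(stats[, count_cols, drop = FALSE])
  csum <- switch(count_summary,
                 mean = rowMeans(cm),
                 min = apply(cm, 1, min))
  up <- p1 < p_up & p2 < p_up
  nr <- !up & p1 > p_nr & p2 > p_nr & csum > min_count
  label <- factor(ifelse(up, "upregulated",
                         ifelse(nr, "non_responsive", "unclassified")),
                  levels = c("upregulated", "non_responsive", "unclassified"))
  out <- stats
  out$label <- label
  out
}

#' Read / write a per-gene expression statistics table
#'
#' Tab-separated with header; columns `gene_id`, `p_10h`, `p_3d`, then one
#' column per sample count (and optionally `label`).
#'
#' @param path File path.
#' @return `read_gene_stats`: the data.frame. `write_gene_stats`: `path`,
#'   invisibly.
#' @export
read_gene_stats <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_gene_stats
#' @param stats Table to write.
#' @export
write_gene_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
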