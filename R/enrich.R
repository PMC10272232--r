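#' Hypergeometric k-mer class enrichment of gene groups vs all genes
#'
#' The core promoter statistic: every reverse-complement-collapsed k-mer
#' class is scored as present/absent in every promoter window, and its
#' over-representation in the upregulated and in the non-responsive gene
#' group is tested with the upper-tail hypergeometric test against the
#' frequency among all genes with windows (the background universe, which
#' includes the two groups themselves). Presence is binary; occurrence
#' counts within a window are deliberately discarded.
#'
#' @param windows Promoter windows from [extract_promoter_windows()], or a
#'   named `DNAStringSet` / character vector of window sequences (names are
#'   gene ids). Clipped windows participate with their truncated sequence.
#' @param labels Either the data.frame returned by [classify_genes()]
#'   (columns `gene_id`, `label`) or a character vector of labels named by
#'   gene id. Genes absent from `labels` (or labelled `unclassified`) count
#'   only toward the background.
#' @param k Word length (default 6; 2080 classes).
#' @param with_q Add Benjamini-Hochberg q-value columns (`q_up`, `q_nr`);
#'   off by default — the primary output is raw hypergeometric p-values.
#' @return A data.frame, one row per class, sorted by ascending `p_up` with
#'   the canonical string as tie-breaker: `canonical`, `is_palindromic`,
#'   `N`, `K`, `n_up`, `x_up`, `p_up`, `n_nr`, `x_nr`, `p_nr`.
#' @export
kmer_enrichment <- function(windows, labels, k = 6, with_q = FALSE) {
  seqs <- window_sequences(windows)
  if (is.null(names(seqs)) || anyNA(names(seqs)))
    stop("window sequences must be named by gene id")
  if (is.data.frame(labels)) {
    stopifnot(all(c("gene_id", "label") %in% names(labels)))
    lab <- stats::setNames(as.character(labels$label), labels$gene_id)
  } else {
    lab <- as.character(labels)
    names(lab) <- names(labels)
  }
  up_ids <- names(lab)[lab == "upregulated"]
  nr_ids <- names(lab)[lab == "non_responsive"]
  missing <- setdiff(c(up_ids, nr_ids), names(seqs))
  if (length(missing) > 0L)
    stop("labeled gene(s) without a promoter window: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (length(up_ids) == 0L && length(nr_ids) == 0L)
    stop("no genes labeled 'upregulated' or 'non_responsive'; ",
         "nothing to test")

  pres <- kmer_presence_matrix(seqs, k = k)
  classes <- enumerate_kmer_classes(k)
  stopifnot(identical(colnames(pres), classes$canonical))

  N <- nrow(pres)
  K <- colSums(pres)
  n_up <- length(up_ids)
  n_nr <- length(nr_ids)
  x_up <- if (n_up > 0L) colSums(pres[names(seqs) %in% up_ids, , drop = FALSE])
          else integer(ncol(pres))
  x_nr <- if (n_nr > 0L) colSums(pres[names(seqs) %in% nr_ids, , drop = FALSE])
          else integer(ncol(pres))

  out <- data.frame(
    canonical = classes$canonical,
    is_palindromic = classes$is_palindromic,
    N = N, K = as.integer(K),
    n_up = n_up, x_up = as.integer(x_up),
    p_up = hypergeom_upper_tail(x_up, N, K, n_up),
    n_nr = n_nr, x_nr = as.integer(x_nr),
    p_nr = hypergeom_upper_tail(x_nr, N, K, n_nr),
    stringsAsFactors = FALSE
  )
  if (with_q) {
    out$q_up <- stats::p.adjust(out$p_up, method = "BH")
    out$q_nr <- stats::p.adjust(out$p_nr, method = "BH")
  }
  out <- out[order(out$p_up, out$canonical), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scatter export of paired enrichment p-values
#'
#' One row per k-mer class with `neglog10_p_up` and `neglog10_p_nr`, the
#' figure-ready coordinates for comparing enrichment in the two gene groups
#' (classes enriched only among upregulated genes sit far right, near the
#' x axis). Classes matching user-supplied motifs of interest are flagged.
#'
#' @param enrichment Table from [kmer_enrichment()].
#' @param highlight Optional character vector of motifs; each is collapsed
#'   to its canonical class, so querying `"TGCATG"` and `"GCATGC"` flags the
#'   classes `CATGCA` and `GCATGC`.
#' @return A data.frame sorted by canonical string: `canonical`,
#'   `neglog10_p_up`, `neglog10_p_nr`, `highlighted`.
#' @export
export_scatter <- function(enrichment, highlight = character(0)) {
  stopifnot(all(c("canonical", "p_up", "p_nr") %in% names(enrichment)))
  hi <- unique(canonical_kmer(highlight))
  if (anyNA(hi)) stop("highlight motifs must be unambiguous DNA strings")
  out <- data.frame(
    canonical = enrichment$canonical,
    neglog10_p_up = -log10(enrichment$p_up),
    neglog10_p_nr = -log10(enrichment$p_nr),
    highlighted = enrichment$canonical %in% hi,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$canonical), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' BED of occurrences of named k-mer classes in promoter windows
#'
#' Scans both strands of each window's genomic interval for members of the
#' canonical classes of the query motifs and reports genomic occurrences as
#' BED6 rows (0-based half-open, strand of the matching member).
#'
#' @param windows Promoter windows from [extract_promoter_windows()].
#' @param motifs Character vector of query motifs (collapsed to classes).
#' @return A data.frame with BED6 columns plus `gene_id`.
#' @export
class_occurrences_bed <- function(windows, motifs) {
  stopifnot(length(motifs) > 0L)
  canon <- unique(canonical_kmer(motifs))
  if (anyNA(canon)) stop("query motifs must be unambiguous DNA strings")
  res <- list()
  seqs <- S4Vectors::mcols(windows)$seq
  for (m in canon) {
    fwd <- Biostrings::vmatchPattern(m, seqs)
    rev <- Biostrings::vmatchPattern(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(m))),
      seqs)
    for (i in seq_along(windows)) {
      off_f <- IRanges::start(fwd[[i]])
      off_r <- IRanges::start(rev[[i]])
      hits <- data.frame(
        off = c(off_f, off_r),
        strand_rel = rep(c("+", "-"), c(length(off_f), length(off_r))),
        stringsAsFactors = FALSE)
      if (nrow(hits) == 0L) next
      wstrand <- as.character(GenomicRanges::strand(windows))[i]
      wlen <- Biostrings::width(seqs)[i]
      # window sequence is gene-oriented; map offsets back to the genome
      gstart0 <- if (wstrand == "+") {
        GenomicRanges::start(windows)[i] - 1L + hits$off - 1L
      } else {
        GenomicRanges::end(windows)[i] - (hits$off - 1L) - nchar(m)
      }
      gstrand <- ifelse(hits$strand_rel == "+", wstrand,
                        ifelse(wstrand == "+", "-", "+"))
      res[[length(res) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(windows))[i],
        start = gstart0, end = gstart0 + nchar(m),
        name = m, score = 0L, strand = gstrand,
        gene_id = windows$gene_id[i], stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      gene_id = character(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
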