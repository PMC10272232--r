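#' Extract TSS-anchored promoter windows
#'
#' For each gene the window spans `upstream` bases 5' of the transcription
#' start site and `downstream` bases into the gene (default -900..+100, the
#' 1-kb window used for promoter scanning). The TSS is taken as the
#' annotated 5'-most base of the gene feature: `start` on the + strand,
#' `end` on the - strand. Minus-strand window sequences are
#' reverse-complemented so every sequence reads 5' to 3' relative to its
#' gene. Windows that would extend past a contig end are clipped, kept and
#' flagged rather than dropped, so the gene universe used as the enrichment
#' background is preserved. Soft-masked (lowercase) bases are uppercased.
#'
#' @param genome A `Biostrings::DNAStringSet` (named by contig) or path to a
#'   FASTA file.
#' @param annotations A `GenomicRanges::GRanges` of gene features or path to
#'   a GFF3 file.
#' @param upstream,downstream Non-negative window extents in bp.
#' @param feature_type GFF3 feature type to use (default `"gene"`).
#' @param id_attribute Attribute holding the gene identifier (default
#'   `"ID"`).
#' @return A `GRanges` (1-based inclusive, as usual for the container) with
#'   one range per gene and metadata columns `gene_id`, `seq`
#'   (a `DNAStringSet`, gene-oriented) and `clipped`. Names are gene ids.
#' @export
extract_promoter_windows <- function(genome, annotations,
                                     upstream = 900, downstream = 100,
                                     feature_type = "gene",
                                     id_attribute = "ID") {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream >= 1)
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(annotations))
    annotations <- rtracklayer::import(annotations, format = "gff3")
  ann <- annotations
  if ("type" %in% names(S4Vectors::mcols(ann)))
    ann <- ann[as.character(ann$type) == feature_type]
  if (length(ann) == 0L)
    stop("no '", feature_type, "' features in the annotation")
  ids <- S4Vectors::mcols(ann)[[id_attribute]]
  if (is.null(ids)) stop("annotation lacks attribute '", id_attribute, "'")
  ids <- as.character(ids)
  strand <- as.character(GenomicRanges::strand(ann))
  if (any(strand == "*"))
    stop("gene(s) with undefined strand: ",
         paste(utils::head(ids[strand == "*"], 5), collapse = ", "))
  contig <- as.character(GenomicRanges::seqnames(ann))
  missing <- setdiff(unique(contig), names(genome))
  if (length(missing) > 0L)
    stop("contig(s) absent from the genome: ",
         paste(missing, collapse = ", "))
  clen <- setNames(Biostrings::width(genome), names(genome))[contig]

  tss <- ifelse(strand == "+", GenomicRanges::start(ann),
                GenomicRanges::end(ann))
  # 1-based inclusive window: + strand [TSS-upstream, TSS+downstream-1],
  # - strand the mirror image [TSS-downstream+1, TSS+upstream]
  ws <- ifelse(strand == "+", tss - upstream, tss - downstream + 1)
  we <- ifelse(strand == "+", tss + downstream - 1, tss + upstream)
  cs <- pmax(ws, 1L)
  ce <- pmin(we, clen)
  if (any(ce < cs))
    stop("promoter window falls entirely outside its contig for gene(s): ",
         paste(utils::head(ids[ce < cs], 5), collapse = ", "))
  clipped <- cs != ws | ce != we

  seqs <- Biostrings::DNAStringSet(rep("", length(ann)))
  for (ctg in unique(contig)) {
    i <- which(contig == ctg)
    seqs[i] <- Biostrings::extractAt(
      genome[[ctg]], IRanges::IRanges(cs[i], ce[i]))
  }
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
  names(seqs) <- ids

  out <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(cs, ce),
    strand = strand,
    gene_id = ids, seq = seqs, clipped = clipped
  )
  names(out) <- ids
  out
}

#' Write promoter windows as FASTA
#'
#' Headers carry the gene id plus the genomic interval (0-based half-open)
#' and strand, e.g. `g0001 contig1:100-1100(+)`.
#'
#' @param windows Result of [extract_promoter_windows()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  seqs <- S4Vectors::mcols(windows)$seq
  names(seqs) <- sprintf(
    "%s %s:%d-%d(%s)",
    windows$gene_id,
    as.character(GenomicRanges::seqnames(windows)),
    GenomicRanges::start(windows) - 1L,
    GenomicRanges::end(windows),
    as.character(GenomicRanges::strand(windows))
  )
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write promoter windows as BED6
#'
#' Standard BED: 0-based half-open intervals, score column carries 0/1 for
#' the clipped flag.
#'
#' @inheritParams write_windows_fasta
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(windows)),
    start = GenomicRanges::start(windows) - 1L,
    end = GenomicRanges::end(windows),
    name = windows$gene_id,
    score = as.integer(windows$clipped),
    strand = as.character(GenomicRanges::strand(windows))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Window sequences as a named DNAStringSet
#'
#' @inheritParams write_windows_fasta
#' @return A `DNAStringSet` named by gene id.
#' @export
window_sequences <- function(windows) {
  if (methods::is(windows, "DNAStringSet")) return(windows)
  if (is.character(windows)) {
    out <- Biostrings::DNAStringSet(toupper(windows))
    names(out) <- names(windows)
    return(out)
  }
  seqs <- S4Vectors::mcols(windows)$seq
  names(seqs) <- windows$gene_id
  seqs
}
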