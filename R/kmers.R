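#' Canonical representative of a k-mer under reverse complementation
#'
#' A k-mer and its reverse complement occur on opposite strands of the same
#' duplex site, so promoter scanning collapses them into one equivalence
#' class. The class representative is the lexicographically smaller of the
#' two (for palindromic k-mers the two coincide).
#'
#' @param kmer Character vector of DNA strings over \{A,C,G,T\} (case
#'   insensitive). Elements containing any other letter map to `NA` ("no
#'   class"); callers skip those positions.
#' @return Character vector of canonical k-mers, `NA` where the input
#'   contained an ambiguous base.
#' @examples
#' canonical_kmer("TGCATG")  # "CATGCA"
#' canonical_kmer("GCATGC")  # palindrome: itself
#' @export
canonical_kmer <- function(kmer) {
  if (length(kmer) == 0L) return(character(0))
  kmer <- toupper(as.character(kmer))
  ok <- !is.na(kmer) & grepl("^[ACGT]+$", kmer)
  out <- rep(NA_character_, length(kmer))
  if (any(ok)) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(kmer[ok]))
    )
    out[ok] <- ifelse(kmer[ok] <= rc, kmer[ok], rc)
  }
  out
}

#' Enumerate all reverse-complement-collapsed k-mer classes
#'
#' For k = 6 there are 2080 classes: (4^6 + 4^3) / 2, i.e. 2016 two-member
#' classes plus 64 palindromes. Odd k has no palindromes, giving 4^k / 2.
#'
#' @param k Positive integer word length.
#' @return A data.frame with one row per class, sorted by canonical string:
#'   `canonical`, `partner` (the reverse complement; equal to `canonical`
#'   for palindromes) and `is_palindromic`.
#' @export
enumerate_kmer_classes <- function(k) {
  stopifnot(length(k) == 1L, is.numeric(k), k >= 1, k == as.integer(k))
  k <- as.integer(k)
  kmers <- all_kmers(k)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers))
  )
  canon <- ifelse(kmers <= rc, kmers, rc)
  keep <- kmers == canon
  out <- data.frame(
    canonical = kmers[keep],
    partner = rc[keep],
    is_palindromic = kmers[keep] == rc[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$canonical), , drop = FALSE]
}

# All 4^k k-mers in lexicographic order.
all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  g <- do.call(expand.grid,
               c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                 stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  sort(do.call(paste0, g[, rev(seq_len(k)), drop = FALSE]))
}

#' Presence profile of canonical k-mer classes in one sequence
#'
#' Slides a width-`k` window over the sequence and reports the set of
#' canonical classes with at least one occurrence. Presence is binary:
#' occurrence counts are discarded. Windows containing any non-ACGT letter
#' contribute nothing.
#'
#' @param sequence A single DNA string, or a `Biostrings::DNAString`.
#' @param k Word length (default 6).
#' @return Character vector (sorted, unique) of canonical class strings;
#'   empty when `k` exceeds the sequence length.
#' @export
presence_profile <- function(sequence, k = 6) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  n <- nchar(sequence)
  if (k > n) return(character(0))
  words <- substring(sequence, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  canon <- canonical_kmer(words)
  sort(unique(canon[!is.na(canon)]))
}

#' Presence/absence matrix of k-mer classes across promoter windows
#'
#' Vectorized counterpart of [presence_profile()] used by the enrichment
#' test: one row per window, one column per canonical class (all
#' `enumerate_kmer_classes(k)` classes, in canonical order).
#'
#' @param sequences A `Biostrings::DNAStringSet` (or coercible character
#'   vector) of window sequences; names identify the genes.
#' @param k Word length (default 6).
#' @return Logical matrix, `length(sequences)` x number of classes.
#' @export
kmer_presence_matrix <- function(sequences, k = 6) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  counts <- Biostrings::oligonucleotideFrequency(sequences, width = k)
  kmers <- colnames(counts)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers))
  )
  canon <- ifelse(kmers <= rc, kmers, rc)
  # rowsum over columns grouped by canonical class; reorder=TRUE sorts the
  # groups, matching enumerate_kmer_classes() order
  cls <- t(rowsum(t(counts), group = canon, reorder = TRUE))
  m <- cls > 0L
  rownames(m) <- names(sequences)
  m
}
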