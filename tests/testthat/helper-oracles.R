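# Independent oracles used across tests. Deliberately built from base-R
# string/combinatorics primitives only, so they share no code with the
# package paths they check.

# reverse complement of a single DNA string
oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  if (s <= rc) s else rc
}

# all canonical classes of width k by literal grouping of all 4^k words
oracle_classes <- function(k) {
  g <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
  words <- do.call(paste0, g)
  sort(unique(vapply(words, oracle_canonical, character(1))))
}

# presence profile by naive O(L*k) substring scan
oracle_profile <- function(s, k) {
  n <- nchar(s)
  if (k > n) return(character(0))
  words <- vapply(seq_len(n - k + 1L),
                  function(i) substr(s, i, i + k - 1L), character(1))
  words <- words[grepl("^[ACGT]+$", words)]
  sort(unique(vapply(words, oracle_canonical, character(1))))
}

# P(X >= x) by literal enumeration of every size-n draw from an urn of N
# items of which the first K are marked
oracle_hyper_tail <- function(x, N, K, n) {
  if (n == 0L) return(as.numeric(x <= 0))
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= x)
}

# random DNA string
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small simulated dataset shared by enrichment tests
small_planted_sim <- function(seed = 7, n_genes = 200, n_fg = 54,
                              n_nr = 40) {
  cfg <- synthetic_genome_config(
    n_genes = n_genes, contig_length = n_genes * 1100,
    planted_motif = "TGCATG", fg_fraction = 0.6, bg_fraction = 0.1,
    n_foreground = n_fg, n_nonresponsive = n_nr, seed = seed)
  sim <- simulate_genome(cfg)
  sim$windows <- extract_promoter_windows(sim$genome, sim$genes)
  lab <- ifelse(sim$truth$labels == "foreground", "upregulated",
         ifelse(sim$truth$labels == "nonresponsive", "non_responsive",
                "unclassified"))
  names(lab) <- names(sim$truth$labels)
  sim$labels <- lab
  sim
}
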