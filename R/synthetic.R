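#' Configuration for the synthetic genome generator
#'
#' Describes a single-contig genome with `n_genes` non-overlapping
#' TSS-anchored promoter windows, an i.i.d. background nucleotide model
#' with configurable GC content, and optionally a motif planted at elevated
#' frequency in a foreground gene class. The foreground / non-responsive /
#' other label structure mirrors the gene-group design of a treatment
#' response experiment (e.g. 87 upregulated and 157 non-responsive genes
#' against an all-gene background).
#'
#' @param n_genes Number of genes.
#' @param contig_length Contig length in bp; must fit `n_genes`
#'   non-overlapping windows.
#' @param upstream,downstream Promoter window extents (defaults 900 / 100).
#' @param gc_content GC fraction of the background model (default 0.5).
#' @param planted_motif DNA string to plant, or `NULL` for none.
#' @param fg_fraction Probability that a foreground promoter receives one
#'   planted occurrence.
#' @param bg_fraction Same for every non-foreground promoter.
#' @param n_foreground,n_nonresponsive Sizes of the labelled classes.
#' @param seed Master seed; all stage streams derive from it.
#' @return A list of class `synth_genome_config`.
#' @export
synthetic_genome_config <- function(n_genes, contig_length,
                                    upstream = 900, downstream = 100,
                                    gc_content = 0.5, planted_motif = NULL,
                                    fg_fraction = 0, bg_fraction = 0,
                                    n_foreground = 0, n_nonresponsive = 0,
                                    seed = 1) {
  stopifnot(n_genes >= 1, contig_length >= 1,
            upstream >= 0, downstream >= 0, upstream + downstream >= 1,
            gc_content >= 0, gc_content <= 1,
            fg_fraction >= 0, fg_fraction <= 1,
            bg_fraction >= 0, bg_fraction <= 1,
            n_foreground >= 0, n_nonresponsive >= 0,
            n_foreground + n_nonresponsive <= n_genes)
  if (!is.null(planted_motif)) {
    planted_motif <- toupper(planted_motif)
    if (!grepl("^[ACGT]+$", planted_motif))
      stop("planted_motif must be a DNA string over {A,C,G,T}")
    if (nchar(planted_motif) > upstream + downstream)
      stop("planted_motif longer than the promoter window")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    contig_length = as.integer(contig_length),
    upstream = as.integer(upstream), downstream = as.integer(downstream),
    gc_content = gc_content, planted_motif = planted_motif,
    fg_fraction = fg_fraction, bg_fraction = bg_fraction,
    n_foreground = as.integer(n_foreground),
    n_nonresponsive = as.integer(n_nonresponsive),
    seed = as.integer(seed)
  ), class = "synth_genome_config")
}

# Deterministic per-stage seed stream derived from one master seed.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 1e6) * 1021 + 7907 * stage) %% 2147483647L
}

#' Simulate a genome, gene annotation and planted-motif ground truth
#'
#' Genes are placed in equal non-overlapping slots along one contig, on a
#' random strand each, such that every promoter window (-upstream..
#' +downstream around the TSS) lies fully inside its slot. Foreground
#' promoters receive one planted motif occurrence with probability
#' `fg_fraction` (all other promoters with probability `bg_fraction`), at a
#' uniform-random in-window offset on a uniform-random strand. Planting
#' replaces the bases in place, so coordinates never shift, and at most one
#' occurrence is planted per window, so plantings cannot destroy each
#' other. Everything is reproducible from `config$seed`.
#'
#' @param config A [synthetic_genome_config()].
#' @return A list:
#' \describe{
#'   \item{genome}{`DNAStringSet`, one contig (`contig1`).}
#'   \item{genes}{`GRanges` of gene features (`type = "gene"`, `ID`).}
#'   \item{truth}{list with `labels` (named character:
#'     foreground/nonresponsive/other), `motif_positions` (data.frame:
#'     `gene_id`, `offset` 0-based within the gene-oriented window,
#'     `strand` relative to the gene, `genomic_start` 1-based,
#'     `genomic_strand`), and `protected_interval` (`NULL`; footprint truth
#'     belongs to [simulate_peak_table()]).}
#' }
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "synth_genome_config"))
  cfg <- config
  wlen <- cfg$upstream + cfg$downstream
  slot <- cfg$contig_length %/% cfg$n_genes
  gene_len <- cfg$downstream + 50L
  if (slot < wlen + gene_len - cfg$downstream)
    stop("contig_length ", cfg$contig_length, " too short for ",
         cfg$n_genes, " genes with ", wlen, " bp promoter windows")

  set.seed(derive_seed(cfg$seed, 1L))
  gc <- cfg$gc_content
  contig <- Biostrings::DNAString(paste(
    sample(c("A", "C", "G", "T"), cfg$contig_length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))

  set.seed(derive_seed(cfg$seed, 2L))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  slot_start <- (seq_len(cfg$n_genes) - 1L) * slot + 1L   # 1-based
  slot_end <- slot_start + slot - 1L
  tss <- ifelse(strand == "+", slot_start + cfg$upstream,
                slot_end - cfg$upstream)
  gstart <- ifelse(strand == "+", tss, tss - gene_len + 1L)
  gend <- ifelse(strand == "+", tss + gene_len - 1L, tss)
  genes <- GenomicRanges::GRanges(
    seqnames = "contig1",
    ranges = IRanges::IRanges(gstart, gend),
    strand = strand, type = "gene", ID = ids
  )
  names(genes) <- ids

  set.seed(derive_seed(cfg$seed, 3L))
  labels <- rep("other", cfg$n_genes)
  picked <- sample(cfg$n_genes, cfg$n_foreground + cfg$n_nonresponsive)
  labels[picked[seq_len(cfg$n_foreground)]] <- "foreground"
  if (cfg$n_nonresponsive > 0L)
    labels[picked[cfg$n_foreground + seq_len(cfg$n_nonresponsive)]] <-
      "nonresponsive"
  names(labels) <- ids

  motif_positions <- data.frame(
    gene_id = character(0), offset = integer(0), strand = character(0),
    genomic_start = integer(0), genomic_strand = character(0),
    stringsAsFactors = FALSE)
  if (!is.null(cfg$planted_motif)) {
    set.seed(derive_seed(cfg$seed, 4L))
    k <- nchar(cfg$planted_motif)
    p_plant <- ifelse(labels == "foreground", cfg$fg_fraction,
                      cfg$bg_fraction)
    plant <- stats::runif(cfg$n_genes) < p_plant
    offset <- sample.int(wlen - k + 1L, cfg$n_genes, replace = TRUE) - 1L
    rel_strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    if (any(plant)) {
      i <- which(plant)
      # gene-oriented window start in window coordinates -> genomic coords
      win_start <- ifelse(strand == "+", tss - cfg$upstream,
                          tss - cfg$downstream + 1L)
      win_end <- ifelse(strand == "+", tss + cfg$downstream - 1L,
                        tss + cfg$upstream)
      g0 <- ifelse(strand[i] == "+", win_start[i] + offset[i],
                   win_end[i] - offset[i] - k + 1L)
      # sequence written into the genome: the motif as it reads on the
      # forward genomic strand
      motif_rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cfg$planted_motif)))
      same <- (strand[i] == "+") == (rel_strand[i] == "+")
      ins <- ifelse(same, cfg$planted_motif, motif_rc)
      contig <- Biostrings::replaceAt(
        contig, IRanges::IRanges(g0, g0 + k - 1L),
        Biostrings::DNAStringSet(ins))
      motif_positions <- data.frame(
        gene_id = ids[i], offset = offset[i], strand = rel_strand[i],
        genomic_start = as.integer(g0),
        genomic_strand = ifelse(same, "+", "-"),
        stringsAsFactors = FALSE)
    }
  }

  genome <- Biostrings::DNAStringSet(contig)
  names(genome) <- "contig1"
  list(genome = genome, genes = genes,
       truth = list(labels = labels, motif_positions = motif_positions,
                    protected_interval = NULL))
}

#' Simulate a per-gene expression statistics table with known labels
#'
#' Builds the table a differential-expression pipeline would hand to
#' [classify_genes()], with cutoff satisfaction guaranteed by construction:
#' foreground genes get both p-values below 0.01 and all counts above
#' `min_count`; nonresponsive genes get both p-values above 0.9 and all
#' counts above `min_count`; "other" genes violate at least one cutoff (a
#' random mix of intermediate p-values, low-count pseudo-non-responders and
#' single-timepoint responders).
#'
#' @param truth Truth list from [simulate_genome()] (only `labels` is
#'   used), or a named character vector of labels.
#' @param n_samples Number of count columns (default 4).
#' @param base_count Location of the log-normal count distribution
#'   (default 500).
#' @param count_cv Coefficient of variation of counts across samples
#'   (default 0.5).
#' @param min_count Count floor the labelled classes must clear
#'   (default 100).
#' @param seed Seed.
#' @return data.frame: `gene_id`, `p_10h`, `p_3d`, `count_s1` ...
#' @export
simulate_expression_stats <- function(truth, n_samples = 4,
                                      base_count = 500, count_cv = 0.5,
                                      min_count = 100, seed = 1) {
  labels <- if (is.list(truth)) truth$labels else truth
  stopifnot(!is.null(names(labels)), all(nzchar(names(labels))),
            n_samples >= 1, base_count > min_count, count_cv >= 0)
  set.seed(derive_seed(seed, 11L))
  n <- length(labels)
  sdlog <- sqrt(log(1 + count_cv^2))
  # counts strictly above min_count for the labelled classes
  high_counts <- function(m) {
    min_count + matrix(
      stats::rlnorm(m * n_samples, log(base_count - min_count), sdlog),
      m, n_samples)
  }
  p1 <- p2 <- numeric(n)
  counts <- matrix(0, n, n_samples)

  fg <- labels == "foreground"
  nr <- labels == "nonresponsive"
  ot <- !(fg | nr)
  if (any(fg)) {
    p1[fg] <- stats::runif(sum(fg), 0, 0.0099)
    p2[fg] <- stats::runif(sum(fg), 0, 0.0099)
    counts[fg, ] <- high_counts(sum(fg))
  }
  if (any(nr)) {
    p1[nr] <- stats::runif(sum(nr), 0.9001, 1)
    p2[nr] <- stats::runif(sum(nr), 0.9001, 1)
    counts[nr, ] <- high_counts(sum(nr))
  }
  if (any(ot)) {
    m <- sum(ot)
    mode <- sample(3L, m, replace = TRUE)
    q1 <- q2 <- numeric(m)
    cc <- matrix(stats::rlnorm(m * n_samples, log(base_count), sdlog),
                 m, n_samples)
    q1[mode == 1L] <- stats::runif(sum(mode == 1L), 0.05, 0.85)
    q2[mode == 1L] <- stats::runif(sum(mode == 1L), 0.05, 0.85)
    # pseudo-non-responders: right p-values, counts too low
    q1[mode == 2L] <- stats::runif(sum(mode == 2L), 0.9001, 1)
    q2[mode == 2L] <- stats::runif(sum(mode == 2L), 0.9001, 1)
    cc[mode == 2L, ] <- matrix(
      stats::runif(sum(mode == 2L) * n_samples, 0, 0.9 * min_count),
      sum(mode == 2L), n_samples)
    # single-timepoint responders
    q1[mode == 3L] <- stats::runif(sum(mode == 3L), 0, 0.0099)
    q2[mode == 3L] <- stats::runif(sum(mode == 3L), 0.02, 0.89)
    p1[ot] <- q1; p2[ot] <- q2
    counts[ot, ] <- cc
  }
  out <- data.frame(gene_id = names(labels), p_10h = p1, p_3d = p2,
                    stringsAsFactors = FALSE)
  colnames(counts) <- sprintf("count_s%d", seq_len(n_samples))
  cbind(out, as.data.frame(counts))
}

#' Simulate replicate DNase I footprinting peak tables
#'
#' Emulates capillary-electrophoresis peak heights for a
#' reference (protein-free) and a treatment (protein-bound) condition with
#' `n_replicates` samples each. Per-position baselines are log-normal;
#' replicate noise is log-normal with coefficient of variation
#' `replicate_cv`; each sample additionally carries its own loading scale
#' (log-normal, `sample_scale_sdlog`), which the zero-sum normalization is
#' designed to remove. Treatment heights inside `protected_interval` are
#' multiplied by `depletion_factor` (< 1 models protection, > 1
#' hypersensitivity).
#'
#' @param n_peaks Number of positions (default 50; must be >= 10).
#' @param protected_interval Length-2 numeric `c(lo, hi)` in position
#'   coordinates, or `NULL` for none.
#' @param depletion_factor Multiplier applied to treatment heights inside
#'   the interval (must be > 0; default 0.2).
#' @param replicate_cv Replicate noise CV (default 0.05).
#' @param n_replicates Samples per condition (default 3).
#' @param positions Position coordinates (default `-467, -466, ...`,
#'   `n_peaks` of them, emulating promoter-relative coordinates).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-position baseline heights (defaults `log(1000)`, 0.5).
#' @param sample_scale_sdlog Log-sd of the per-sample loading scale
#'   (default 0.25; set 0 for none).
#' @param reference,treatment Condition labels.
#' @param seed Seed.
#' @return Long-format peak table: `position`, `sample_id`, `condition`,
#'   `height` (all heights strictly positive).
#' @export
simulate_peak_table <- function(n_peaks = 50, protected_interval = NULL,
                                depletion_factor = 0.2, replicate_cv = 0.05,
                                n_replicates = 3,
                                positions = seq(-467, by = 1,
                                                length.out = n_peaks),
                                baseline_meanlog = log(1000),
                                baseline_sdlog = 0.5,
                                sample_scale_sdlog = 0.25,
                                reference = "protein_0uM",
                                treatment = "protein_3uM",
                                seed = 1) {
  stopifnot(n_peaks >= 10, n_replicates >= 3, replicate_cv >= 0,
            length(positions) == n_peaks)
  if (!is.null(protected_interval))
    stopifnot(length(protected_interval) == 2,
              protected_interval[1] <= protected_interval[2])
  if (!is.finite(depletion_factor) || depletion_factor <= 0)
    stop("depletion_factor must be > 0")
  set.seed(derive_seed(seed, 21L))
  baseline <- stats::rlnorm(n_peaks, baseline_meanlog, baseline_sdlog)
  sdlog_rep <- if (replicate_cv > 0) sqrt(log(1 + replicate_cv^2)) else 0
  samples <- c(sprintf("%s_r%d", reference, seq_len(n_replicates)),
               sprintf("%s_r%d", treatment, seq_len(n_replicates)))
  condition <- rep(c(reference, treatment), each = n_replicates)
  scale <- if (sample_scale_sdlog > 0)
    stats::rlnorm(length(samples), 0, sample_scale_sdlog) else
    rep(1, length(samples))
  protected <- if (is.null(protected_interval)) rep(FALSE, n_peaks) else
    positions >= protected_interval[1] & positions <= protected_interval[2]

  rows <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    noise <- if (sdlog_rep > 0) stats::rlnorm(n_peaks, 0, sdlog_rep) else
      rep(1, n_peaks)
    h <- baseline * noise * scale[s]
    if (condition[s] == treatment)
      h[protected] <- h[protected] * depletion_factor
    rows[[s]] <- data.frame(position = positions, sample_id = samples[s],
                            condition = condition[s], height = h,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the synthetic ground truth as tab-separated text
#'
#' Two files: `<prefix>_labels.tsv` (`gene_id`, `label`) and
#' `<prefix>_motifs.tsv` (the `motif_positions` table).
#'
#' @param truth Truth list from [simulate_genome()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_truth <- function(truth, prefix) {
  p1 <- paste0(prefix, "_labels.tsv")
  p2 <- paste0(prefix, "_motifs.tsv")
  utils::write.table(
    data.frame(gene_id = names(truth$labels), label = unname(truth$labels)),
    p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$motif_positions, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
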