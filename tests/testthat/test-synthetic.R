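test_that("the generator respects its configuration and records truth", {
  # no planting requested
  cfg <- synthetic_genome_config(n_genes = 10, contig_length = 11000,
                                 seed = 1)
  sim <- simulate_genome(cfg)
  expect_identical(length(sim$genes), 10L)
  expect_identical(nrow(sim$truth$motif_positions), 0L)
  expect_identical(sort(unique(as.character(sim$truth$labels))), "other")

  # probability-1 planting: every foreground promoter carries the class
  cfg2 <- synthetic_genome_config(n_genes = 20, contig_length = 22000,
                                  planted_motif = "TGCATG",
                                  fg_fraction = 1, n_foreground = 5,
                                  seed = 3)
  sim2 <- simulate_genome(cfg2)
  w <- extract_promoter_windows(sim2$genome, sim2$genes)
  fg <- names(sim2$truth$labels)[sim2$truth$labels == "foreground"]
  expect_length(fg, 5)
  for (g in fg) {
    expect_true("CATGCA" %in%
                  presence_profile(window_sequences(w)[[g]], 6))
  }
})

test_that("planted occurrences are findable at the recorded coordinates", {
  cfg <- synthetic_genome_config(n_genes = 60, contig_length = 66000,
                                 planted_motif = "TGCATG",
                                 fg_fraction = 0.7, bg_fraction = 0.2,
                                 n_foreground = 20, n_nonresponsive = 15,
                                 seed = 17)
  sim <- simulate_genome(cfg)
  mp <- sim$truth$motif_positions
  expect_gt(nrow(mp), 0)
  w <- extract_promoter_windows(sim$genome, sim$genes)
  seqs <- window_sequences(w)
  contig <- as.character(sim$genome[[1]])
  for (i in seq_len(nrow(mp))) {
    # window convention: offset within the gene-oriented sequence
    win <- as.character(seqs[[mp$gene_id[i]]])
    word <- substr(win, mp$offset[i] + 1L, mp$offset[i] + 6L)
    expect_identical(word,
                     if (mp$strand[i] == "+") "TGCATG" else "CATGCA")
    # genomic convention: forward-strand slice of the emitted contig
    gword <- substr(contig, mp$genomic_start[i], mp$genomic_start[i] + 5L)
    expect_identical(gword,
                     if (mp$genomic_strand[i] == "+") "TGCATG" else "CATGCA")
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- synthetic_genome_config(n_genes = 30, contig_length = 33000,
                                 planted_motif = "TGCATG",
                                 fg_fraction = 0.5, bg_fraction = 0.1,
                                 n_foreground = 10, n_nonresponsive = 10,
                                 seed = 99)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(as.character(simulate_genome(cfg2)$genome),
                         as.character(a$genome)))

  labels <- a$truth$labels
  expect_identical(simulate_expression_stats(labels, seed = 4),
                   simulate_expression_stats(labels, seed = 4))
  expect_identical(simulate_peak_table(seed = 4),
                   simulate_peak_table(seed = 4))
})

test_that("expression statistics satisfy their label's cutoffs row by row", {
  labels <- rep(c("foreground", "nonresponsive", "other"), c(30, 40, 80))
  names(labels) <- sprintf("g%04d", seq_along(labels))
  st <- simulate_expression_stats(labels, seed = 12)
  counts <- as.matrix(st[, grep("^count_", names(st))])
  cmean <- rowMeans(counts)
  fg <- labels == "foreground"; nr <- labels == "nonresponsive"
  expect_true(all(st$p_10h[fg] < 0.01 & st$p_3d[fg] < 0.01))
  expect_true(all(cmean[fg] > 100))
  expect_true(all(st$p_10h[nr] > 0.9 & st$p_3d[nr] > 0.9))
  expect_true(all(cmean[nr] > 100))
  ot <- !(fg | nr)
  violates <- !(st$p_10h < 0.01 & st$p_3d < 0.01) &
              !(st$p_10h > 0.9 & st$p_3d > 0.9 & cmean > 100)
  expect_true(all(violates[ot]))
})

test_that("peak tables have positive heights and the configured structure", {
  pt <- simulate_peak_table(n_peaks = 50,
                            protected_interval = c(-450, -441),
                            depletion_factor = 0.2, replicate_cv = 0.05,
                            seed = 3)
  expect_true(all(pt$height > 0))
  expect_identical(length(unique(pt$position)), 50L)
  expect_identical(as.vector(table(pt$condition)), c(150L, 150L))

  # depletion shows up only inside the protected interval
  m0 <- tapply(pt$height[pt$condition == "protein_0uM"],
               pt$position[pt$condition == "protein_0uM"], mean)
  m3 <- tapply(pt$height[pt$condition == "protein_3uM"],
               pt$position[pt$condition == "protein_3uM"], mean)
  pos <- as.numeric(names(m0))
  inside <- pos >= -450 & pos <= -441
  expect_true(all(m3[inside] / m0[inside] < 0.5))
  expect_true(all(m3[!inside] / m0[!inside] > 0.5))

  expect_error(simulate_peak_table(depletion_factor = 0), "depletion")
  expect_error(simulate_peak_table(depletion_factor = -1), "depletion")
  expect_error(
    simulate_genome(synthetic_genome_config(n_genes = 100,
                                            contig_length = 5000)),
    "too short")
})

test_that("with zero replicate noise the factors cancel any post-hoc scalar", {
  pt <- simulate_peak_table(replicate_cv = 0, sample_scale_sdlog = 0,
                            protected_interval = NULL, seed = 6)
  scaled <- pt
  scale <- c(protein_0uM_r1 = 2, protein_0uM_r2 = 0.25, protein_0uM_r3 = 1,
             protein_3uM_r1 = 10, protein_3uM_r2 = 1, protein_3uM_r3 = 0.5)
  scaled$height <- scaled$height * scale[scaled$sample_id]
  f <- compute_norm_factors(scaled, trim_peaks(scaled))
  norm <- scaled$height * f[scaled$sample_id]
  # normalization removes every per-sample scalar: all samples collapse
  # back onto the common baseline profile (up to one global constant)
  ratio <- norm / pt$height
  expect_lt(diff(range(ratio)), 1e-12)
})
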