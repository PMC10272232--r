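# Hand-built peak table: heights chosen so the per-position log2 ratio
# (reference over treatment) is exactly `ratios`, with within-condition
# spread controlled by `jitter`.
toy_table <- function(ratios, positions = seq_along(ratios),
                      base = 1000, jitter = c(1, 1.1, 0.9)) {
  rows <- list()
  for (r in 1:3) {
    rows[[length(rows) + 1L]] <- data.frame(
      position = positions, sample_id = paste0("ref", r),
      condition = "protein_0uM", height = base * jitter[r])
    rows[[length(rows) + 1L]] <- data.frame(
      position = positions, sample_id = paste0("trt", r),
      condition = "protein_3uM",
      height = base * jitter[r] / 2^ratios)
  }
  do.call(rbind, rows)
}

test_that("trimming discards floor(trim_frac * P) positions from each ratio end", {
  # ratios 1..10 in shuffled position order; trim 30% of 10 -> 3 + 3 off,
  # ratios 4..7 survive, returned in original position order
  set.seed(31)
  ratios <- sample(1:10)
  tab <- toy_table(ratios)
  kept <- trim_peaks(tab, trim_frac = 0.3)
  expect_identical(kept, sort(which(ratios %in% 4:7)))

  expect_identical(trim_peaks(tab, trim_frac = 0), 1:10)
  expect_error(trim_peaks(tab, trim_frac = 0.5))
  # all ratios tied: ties broken by ascending position, zero-sum still holds
  tied <- toy_table(rep(2, 10))
  kept_tied <- trim_peaks(tied, trim_frac = 0.3)
  expect_identical(kept_tied, 4:7)
  f <- compute_norm_factors(tied, kept_tied)
  expect_true(all(f > 0))
})

test_that("factors satisfy the zero-sum contract and its closed-form cases", {
  # a sample sitting exactly on the reference log-mean profile gets f = 1
  tab <- toy_table(rep(0, 8), jitter = c(1, 1, 1))
  f <- compute_norm_factors(tab, trim_peaks(tab, 0.3))
  expect_equal(unname(f), rep(1, 6), tolerance = 1e-12)

  # random positive tables: residual < 1e-9 for every sample, including
  # adversarial magnitudes spanning 1e-6..1e6
  set.seed(41)
  for (rep_i in 1:5) {
    n <- sample(10:30, 1)
    tab <- data.frame(
      position = rep(1:n, 6),
      sample_id = rep(sprintf("s%d", 1:6), each = n),
      condition = rep(rep(c("protein_0uM", "protein_3uM"), each = 3 * n)),
      height = 10^runif(6 * n, -6, 6))
    kept <- trim_peaks(tab, 0.3)
    f <- compute_norm_factors(tab, kept)
    log2_mean0 <- vapply(kept, function(p)
      mean(log2(tab$height[tab$position == p &
                           tab$condition == "protein_0uM"])),
      numeric(1))
    for (s in unique(tab$sample_id)) {
      h <- tab$height[tab$sample_id == s & tab$position %in% kept]
      expect_lt(abs(sum(log2(f[s] * h) - log2_mean0)), 1e-9)
    }
  }
})

test_that("normalization is idempotent and scale-invariant", {
  pt <- simulate_peak_table(n_peaks = 40, protected_interval = c(-450, -445),
                            depletion_factor = 0.3, seed = 11)
  fn <- normalize_peaks(pt)

  # idempotence: renormalizing the normalized table gives factors of 1
  renorm <- fn$table[, c("position", "sample_id", "condition")]
  renorm$height <- fn$table$norm_height
  expect_equal(unname(normalize_peaks(renorm)$factors), rep(1, 6),
               tolerance = 1e-12)

  # scaling a treatment sample: its factor shrinks by exactly that scalar
  # and normalized heights are unchanged
  sc <- pt
  idx <- sc$sample_id == "protein_3uM_r2"
  sc$height[idx] <- sc$height[idx] * 8
  fn_sc <- normalize_peaks(sc)
  expect_equal(unname(fn_sc$factors["protein_3uM_r2"]),
               unname(fn$factors["protein_3uM_r2"]) / 8, tolerance = 1e-12)
  expect_equal(fn_sc$table$norm_height, fn$table$norm_height,
               tolerance = 1e-12)

  # scaling a reference sample: kept set, effects and calls are invariant
  sc2 <- pt
  idx2 <- sc2$sample_id == "protein_0uM_r1"
  sc2$height[idx2] <- sc2$height[idx2] * 1e4
  fn_sc2 <- normalize_peaks(sc2)
  expect_identical(fn_sc2$kept_positions, fn$kept_positions)
  c1 <- call_protection(fn); c2 <- call_protection(fn_sc2)
  expect_equal(c1$effect, c2$effect, tolerance = 1e-9)
  expect_identical(as.character(c1$direction), as.character(c2$direction))
})

test_that("protection calls recover the depleted interval and its sign", {
  for (seed in c(3, 19)) {
    pt <- simulate_peak_table(n_peaks = 50,
                              protected_interval = c(-450, -441),
                              depletion_factor = 0.2, replicate_cv = 0.05,
                              seed = seed)
    calls <- call_protection(normalize_peaks(pt))
    inside <- calls$position >= -450 & calls$position <= -441
    expect_identical(sum(calls$direction[inside] == "lost"), 10L)
    expect_identical(sum(calls$direction[!inside] == "lost"), 0L)
  }

  # identically distributed conditions: nothing is called
  pt0 <- simulate_peak_table(depletion_factor = 1,
                             protected_interval = c(-450, -441), seed = 5)
  calls0 <- call_protection(normalize_peaks(pt0))
  expect_true(all(calls0$direction == "unchanged"))

  # enrichment of digestion (hypersensitivity) flips the sign
  ptg <- simulate_peak_table(protected_interval = c(-450, -441),
                             depletion_factor = 4, replicate_cv = 0.05,
                             seed = 7)
  cg <- call_protection(normalize_peaks(ptg))
  inside <- cg$position >= -450 & cg$position <= -441
  expect_identical(sum(cg$direction[inside] == "gained"), 10L)
  expect_identical(sum(cg$direction[!inside] == "gained"), 0L)
  # lost => negative effect, gained => positive effect
  expect_true(all(cg$effect[cg$direction == "gained"] > 0))
})

test_that("degenerate and malformed tables are handled as documented", {
  pt <- simulate_peak_table(seed = 2)
  bad <- pt; bad$height[7] <- 0
  expect_error(trim_peaks(bad), "non-positive")

  # a position missing from one sample is excluded with a warning
  holey <- pt[!(pt$position == -460 & pt$sample_id == "protein_3uM_r1"), ]
  expect_warning(trim_peaks(holey), "missing")
  fn <- suppressWarnings(normalize_peaks(holey))
  expect_false(-460 %in% fn$summary$position)
  expect_false(-460 %in% fn$kept_positions)

  # raw effect and p columns are always present for downstream rules
  calls <- call_protection(normalize_peaks(pt))
  expect_true(all(c("position", "effect", "p_value", "direction") %in%
                  names(calls)))
  expect_true(all(calls$p_value >= 0 & calls$p_value <= 1))

  # peak table TSV round trip preserves the analysis
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(pt, path)
  back <- read_peak_table(path)
  expect_equal(normalize_peaks(back)$factors, normalize_peaks(pt)$factors,
               tolerance = 1e-9)
})
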