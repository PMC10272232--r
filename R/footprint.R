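#' DNase I footprinting peak normalization and protection calling
#'
#' Capillary-electrophoresis peak heights from replicate digests are not on
#' a common scale, so between-condition comparison (protein-bound vs free
#' probe) needs per-sample normalization. The procedure implemented here:
#' per position, the log2 ratio of the reference-condition mean height to
#' the treatment-condition mean height is computed; positions in the lowest
#' and highest `trim_frac` of that ratio are discarded (these are the
#' candidate footprint / hypersensitive positions plus outliers, which must
#' not drive the scaling); per-sample multiplicative factors are then chosen
#' so that, over the kept positions, the log2 ratios of each sample's
#' normalized heights to the reference-condition raw mean sum exactly to
#' zero. Protection is finally called per position from the normalized
#' heights.
#'
#' @name footprint
NULL

# Per-position reference profile: mean of log2 heights over the reference
# samples (i.e. the geometric mean on the raw scale). Working in log space
# throughout makes the zero-sum factors exactly idempotent and makes the
# trim ranking and all protection calls invariant under rescaling any
# single sample.
ref_log2_profile <- function(H, is_ref) {
  rowMeans(log2(H[, is_ref, drop = FALSE]))
}

# Pivot a long peak table to a positions x samples height matrix with
# condition metadata; validates heights and completeness.
peak_matrix <- function(table, reference, treatment) {
  stopifnot(is.data.frame(table),
            all(c("position", "sample_id", "condition", "height")
                %in% names(table)))
  conds <- unique(table[, c("sample_id", "condition")])
  if (anyDuplicated(conds$sample_id))
    stop("sample(s) assigned to more than one condition")
  if (!all(c(reference, treatment) %in% conds$condition))
    stop("peak table lacks condition '",
         setdiff(c(reference, treatment), conds$condition)[1], "'")
  bad <- !is.finite(table$height) | table$height <= 0
  if (any(bad))
    stop("non-positive peak height at (sample ", table$sample_id[bad][1],
         ", position ", table$position[bad][1], ")")
  positions <- sort(unique(table$position))
  samples <- conds$sample_id
  H <- matrix(NA_real_, length(positions), length(samples),
              dimnames = list(as.character(positions), samples))
  H[cbind(match(table$position, positions),
          match(table$sample_id, samples))] <- table$height
  incomplete <- rowSums(is.na(H)) > 0L
  if (any(incomplete)) {
    warning(sum(incomplete), " position(s) missing in some sample; ",
            "excluded from normalization and calling")
    H <- H[!incomplete, , drop = FALSE]
    positions <- positions[!incomplete]
  }
  list(H = H, positions = positions,
       condition = stats::setNames(conds$condition, conds$sample_id))
}

#' Trim extreme-ratio positions before normalization
#'
#' Per position p the ratio r(p) = mean log2 reference height - mean log2
#' treatment height is computed from raw heights; the `floor(trim_frac * P)`
#' positions with the lowest r and the same number with the highest r are
#' discarded (these carry the candidate footprint / hypersensitive signal
#' plus outliers, which must not drive the between-sample scaling). Ties
#' are broken by ascending position, so trimming is deterministic, and
#' because r is a log-space contrast the ranking is unchanged when any
#' single sample is rescaled.
#'
#' @param table Long-format peak table: columns `position`, `sample_id`,
#'   `condition`, `height` (heights strictly positive).
#' @param trim_frac Fraction trimmed from each end of the ratio ranking
#'   (default 0.3).
#' @param reference,treatment Condition labels; `reference` is the
#'   protein-free (0 uM) condition.
#' @return The kept positions, in original (ascending) order.
#' @export
trim_peaks <- function(table, trim_frac = 0.3,
                       reference = "protein_0uM", treatment = "protein_3uM") {
  stopifnot(trim_frac >= 0, trim_frac < 0.5)
  pm <- peak_matrix(table, reference, treatment)
  P <- length(pm$positions)
  if (P < 1L) stop("no complete positions in the peak table")
  r <- ref_log2_profile(pm$H, pm$condition == reference) -
       ref_log2_profile(pm$H, pm$condition == treatment)
  ndrop <- floor(trim_frac * P)
  if (2L * ndrop >= P)
    stop("trim_frac = ", trim_frac, " would discard all ", P, " positions")
  ord <- order(r, seq_len(P))      # stable: ties by ascending position
  kept_idx <- sort(ord[seq.int(ndrop + 1L, P - ndrop)])
  pm$positions[kept_idx]
}

#' Per-sample zero-sum normalization factors
#'
#' For sample s, log2 f_s = -(1/|kept|) * sum over kept positions p of
#' log2(h(s,p) / mean0(p)), where mean0(p) is the log-space mean height of
#' the reference-condition samples at p (geometric mean of raw heights).
#' By construction the normalized log2 ratios of every sample then sum to
#' zero over the kept positions, and renormalizing an already-normalized
#' table returns factors of exactly 1.
#'
#' @inheritParams trim_peaks
#' @param kept Positions to use (typically from [trim_peaks()]).
#' @return Named numeric vector of strictly positive factors, one per
#'   sample.
#' @export
compute_norm_factors <- function(table, kept,
                                 reference = "protein_0uM",
                                 treatment = "protein_3uM") {
  pm <- peak_matrix(table, reference, treatment)
  idx <- match(kept, pm$positions)
  if (anyNA(idx)) stop("kept positions absent from the peak table")
  if (length(idx) == 0L) stop("kept position set is empty")
  H <- pm$H[idx, , drop = FALSE]
  log2_mean0 <- ref_log2_profile(H, pm$condition == reference)
  log2f <- -colMeans(log2(H) - log2_mean0)
  2^log2f
}

#' Normalize a peak table (trim, fit factors, apply)
#'
#' @inheritParams trim_peaks
#' @return An object of class `footprint_norm`: a list with `table` (the
#'   input plus a `norm_height` column), `kept_positions`, `factors`,
#'   `condition` (per sample), `reference`, `treatment`, and `summary` (per
#'   position: normalized condition means `mean_ref` / `mean_trt` and
#'   `log2_ratio` = log2(mean_trt / mean_ref)).
#' @export
normalize_peaks <- function(table, trim_frac = 0.3,
                            reference = "protein_0uM",
                            treatment = "protein_3uM") {
  kept <- trim_peaks(table, trim_frac, reference, treatment)
  f <- compute_norm_factors(table, kept, reference, treatment)
  pm <- peak_matrix(table, reference, treatment)
  out <- table[table$position %in% pm$positions, , drop = FALSE]
  out$norm_height <- out$height * f[out$sample_id]
  Hn <- pm$H * rep(f[colnames(pm$H)], each = nrow(pm$H))
  # log-space condition means of normalized heights, consistent with the
  # factor fitting and the calling statistic
  mean_ref <- 2^ref_log2_profile(Hn, pm$condition == reference)
  mean_trt <- 2^ref_log2_profile(Hn, pm$condition == treatment)
  structure(list(
    table = out,
    kept_positions = kept,
    factors = f,
    condition = pm$condition,
    reference = reference,
    treatment = treatment,
    summary = data.frame(position = pm$positions,
                         mean_ref = mean_ref, mean_trt = mean_trt,
                         log2_ratio = log2(mean_trt / mean_ref))
  ), class = "footprint_norm")
}

#' @export
print.footprint_norm <- function(x, ...) {
  cat("Footprint normalization:", length(x$factors), "samples (",
      sum(x$condition == x$reference), "x", x$reference, ",",
      sum(x$condition == x$treatment), "x", x$treatment, "),",
      nrow(x$summary), "positions,", length(x$kept_positions),
      "kept for factor fitting\n")
  cat("factors:\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Call protected (lost) and hypersensitive (gained) positions
#'
#' Per position the effect is the difference in mean log2 normalized height
#' (treatment minus reference, i.e. the log2 ratio of geometric means) and
#' the evidence a two-sided Welch t-test on log2 normalized heights. A position is `lost` (protein protected it from
#' digestion) when effect < -min_abs_effect with p < alpha, `gained`
#' (hypersensitive) when effect > +min_abs_effect with p < alpha, otherwise
#' `unchanged`. The default effect floor of one log2 unit (two-fold) keeps
#' small-replicate noise from producing spurious calls; set it to 0 to rely
#' on the t-test alone. Raw effect and p columns are always emitted so any
#' other rule can be applied downstream.
#'
#' @param result A `footprint_norm` from [normalize_peaks()].
#' @param alpha Significance level (default 0.05).
#' @param min_abs_effect Minimum |log2 effect| to call (default 1).
#' @return A data.frame: `position`, `effect`, `p_value`, `direction`
#'   (factor: lost / gained / unchanged).
#' @export
call_protection <- function(result, alpha = 0.05, min_abs_effect = 1) {
  stopifnot(inherits(result, "footprint_norm"),
            alpha > 0, alpha <= 1, min_abs_effect >= 0)
  tab <- result$table
  ref_samples <- names(result$condition)[result$condition == result$reference]
  trt_samples <- names(result$condition)[result$condition == result$treatment]
  if (length(ref_samples) < 2L || length(trt_samples) < 2L)
    stop("need >= 2 samples per condition for protection calling")
  positions <- result$summary$position
  eff <- numeric(length(positions))
  pv <- numeric(length(positions))
  for (i in seq_along(positions)) {
    rows <- tab[tab$position == positions[i], ]
    a <- log2(rows$norm_height[rows$sample_id %in% trt_samples])
    b <- log2(rows$norm_height[rows$sample_id %in% ref_samples])
    eff[i] <- mean(a) - mean(b)
    pv[i] <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      stats::t.test(a, b, var.equal = FALSE)$p.value
    }
  }
  direction <- ifelse(pv < alpha & eff < -min_abs_effect, "lost",
               ifelse(pv < alpha & eff > min_abs_effect, "gained",
                      "unchanged"))
  data.frame(position = positions, effect = eff, p_value = pv,
             direction = factor(direction,
                                levels = c("lost", "gained", "unchanged")))
}

#' Read / write a long-format peak table
#'
#' Tab-separated with header; columns `position`, `sample_id`, `condition`,
#' `height`.
#'
#' @param path File path.
#' @return `read_peak_table`: the data.frame. `write_peak_table`: `path`,
#'   invisibly.
#' @export
read_peak_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_peak_table
#' @param table Table to write.
#' @export
write_peak_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
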