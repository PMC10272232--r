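#' Pipeline configuration
#'
#' Collects paths and parameters for [run_pipeline()]. When `simulate =
#' TRUE` the input paths are ignored and a synthetic dataset with known
#' ground truth is generated into the output directory first; the `sim_*`
#' fields describe it (defaults: 1997 genes — 90 foreground, 157
#' non-responsive, 1750 other — with TGCATG planted in 60% of foreground
#' and 10% of other promoters, mirroring a motif-discovery study design).
#'
#' @param outdir Output directory (created if needed).
#' @param genome,annotations,stats,peaks Input paths (FASTA, GFF3, TSV,
#'   TSV); any may be `NULL` when simulating or when a stage is skipped.
#' @param upstream,downstream,k,p_up,p_nr,min_count,trim_frac,alpha,min_abs_effect
#'   Stage parameters (see the stage functions).
#' @param highlight Motifs flagged in the scatter export.
#' @param seed Master seed.
#' @param simulate Generate synthetic inputs first?
#' @param sim_n_genes,sim_n_foreground,sim_n_nonresponsive,sim_fg_fraction,sim_bg_fraction,sim_motif,sim_gc,sim_contig_length
#'   Synthetic dataset description.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            genome = NULL, annotations = NULL,
                            stats = NULL, peaks = NULL,
                            upstream = 900, downstream = 100, k = 6,
                            p_up = 0.01, p_nr = 0.9, min_count = 100,
                            trim_frac = 0.3, alpha = 0.05,
                            min_abs_effect = 1,
                            highlight = c("TGCATG", "GCATGC"),
                            seed = 1, simulate = FALSE,
                            sim_n_genes = 1997, sim_n_foreground = 90,
                            sim_n_nonresponsive = 157,
                            sim_fg_fraction = 0.6, sim_bg_fraction = 0.1,
                            sim_motif = "TGCATG", sim_gc = 0.5,
                            sim_contig_length = sim_n_genes *
                              (upstream + downstream + 100)) {
  cfg <- as.list(environment())
  stopifnot(k >= 1, p_up > 0, p_up < 1, p_nr > 0, p_nr < 1,
            min_count >= 0, trim_frac >= 0, trim_frac < 0.5,
            alpha > 0, alpha <= 1, min_abs_effect >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as flat key=value text
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_pipeline_config`: `path` invisibly;
#'   `read_pipeline_config`: the `pipeline_config` (lossless round trip).
#' @export
write_pipeline_config <- function(config, path) {
  ser <- function(v) {
    if (is.null(v)) "NULL" else paste(as.character(v), collapse = ",")
  }
  lines <- vapply(names(config), function(nm)
    paste0(nm, "=", ser(config[[nm]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  defaults <- formals(pipeline_config)
  args <- list()
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (identical(v, "NULL")) { args[nm] <- list(NULL); next }
    v <- strsplit(v, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) v <- num
    if (identical(v, "TRUE") || identical(v, "FALSE")) v <- as.logical(v)
    args[[nm]] <- v
  }
  do.call(pipeline_config, args)
}

#' Run the full cis-element discovery pipeline
#'
#' Stages: (optionally) simulate inputs; extract promoter windows; classify
#' genes from the expression statistics table; test k-mer class enrichment
#' of the two gene groups against the all-gene background; and, when a peak
#' table is supplied (or simulated), normalize the footprinting peaks and
#' call protection. All result tables are written to `config$outdir`
#' together with a manifest (package version, parameters, seed, input
#' checksums). Given the same configuration and seed, reruns are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages to stderr.
#' @return Invisibly, a list with the in-memory results (`windows`,
#'   `labels`, `enrichment`, `scatter`, `footprint`, `calls`, `truth` when
#'   simulated) and `files` (all written paths).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[cisray] ", ...)
  t0 <- Sys.time()
  files <- character(0)
  add_file <- function(p) files <<- c(files, p)
  truth <- NULL

  if (isTRUE(cfg$simulate)) {
    say("simulating genome (", cfg$sim_n_genes, " genes) and tables")
    gcfg <- synthetic_genome_config(
      n_genes = cfg$sim_n_genes, contig_length = cfg$sim_contig_length,
      upstream = cfg$upstream, downstream = cfg$downstream,
      gc_content = cfg$sim_gc, planted_motif = cfg$sim_motif,
      fg_fraction = cfg$sim_fg_fraction, bg_fraction = cfg$sim_bg_fraction,
      n_foreground = cfg$sim_n_foreground,
      n_nonresponsive = cfg$sim_n_nonresponsive, seed = cfg$seed)
    sim <- simulate_genome(gcfg)
    truth <- sim$truth
    cfg$genome <- file.path(cfg$outdir, "genome.fasta")
    cfg$annotations <- file.path(cfg$outdir, "genes.gff3")
    cfg$stats <- file.path(cfg$outdir, "expression_stats.tsv")
    cfg$peaks <- file.path(cfg$outdir, "peak_table.tsv")
    Biostrings::writeXStringSet(sim$genome, cfg$genome)
    rtracklayer::export(sim$genes, cfg$annotations, format = "gff3")
    write_gene_stats(
      simulate_expression_stats(truth, min_count = cfg$min_count,
                                seed = cfg$seed),
      cfg$stats)
    write_peak_table(
      simulate_peak_table(protected_interval = c(-450, -441),
                          seed = cfg$seed),
      cfg$peaks)
    write_truth(truth, file.path(cfg$outdir, "truth"))
    add_file(c(cfg$genome, cfg$annotations, cfg$stats, cfg$peaks))
  }
  if (is.null(cfg$genome) || is.null(cfg$annotations) || is.null(cfg$stats))
    stop("genome, annotations and stats inputs are required ",
         "(or set simulate = TRUE)")

  say("extracting promoter windows (-", cfg$upstream, "..+",
      cfg$downstream, ")")
  windows <- extract_promoter_windows(cfg$genome, cfg$annotations,
                                      upstream = cfg$upstream,
                                      downstream = cfg$downstream)
  say(length(windows), " windows (", sum(windows$clipped), " clipped)")
  f_fa <- file.path(cfg$outdir, "promoters.fasta")
  f_bed <- file.path(cfg$outdir, "promoters.bed")
  write_windows_fasta(windows, f_fa)
  write_windows_bed(windows, f_bed)
  add_file(c(f_fa, f_bed))

  say("classifying genes (p_up<", cfg$p_up, ", p_nr>", cfg$p_nr,
      ", counts>", cfg$min_count, ")")
  labels <- classify_genes(read_gene_stats(cfg$stats), p_up = cfg$p_up,
                           p_nr = cfg$p_nr, min_count = cfg$min_count)
  say(sum(labels$label == "upregulated"), " upregulated, ",
      sum(labels$label == "non_responsive"), " non-responsive")
  f_lab <- file.path(cfg$outdir, "gene_labels.tsv")
  write_gene_stats(labels, f_lab)
  add_file(f_lab)

  say("testing ", cfg$k, "-mer class enrichment")
  enrichment <- kmer_enrichment(windows, labels, k = cfg$k)
  scatter <- export_scatter(enrichment, highlight = cfg$highlight)
  f_enr <- file.path(cfg$outdir, "enrichment.tsv")
  f_sc <- file.path(cfg$outdir, "scatter.tsv")
  utils::write.table(enrichment, f_enr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scatter, f_sc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_file(c(f_enr, f_sc))
  say("top class: ", enrichment$canonical[1],
      " (p_up = ", signif(enrichment$p_up[1], 3), ")")

  footprint <- NULL
  calls <- NULL
  if (!is.null(cfg$peaks)) {
    say("normalizing footprint peaks and calling protection")
    peaks <- read_peak_table(cfg$peaks)
    footprint <- normalize_peaks(peaks, trim_frac = cfg$trim_frac)
    calls <- call_protection(footprint, alpha = cfg$alpha,
                             min_abs_effect = cfg$min_abs_effect)
    f_fac <- file.path(cfg$outdir, "footprint_factors.tsv")
    f_norm <- file.path(cfg$outdir, "footprint_normalized.tsv")
    f_call <- file.path(cfg$outdir, "footprint_calls.tsv")
    utils::write.table(
      data.frame(sample_id = names(footprint$factors),
                 condition = unname(footprint$condition[
                   names(footprint$factors)]),
                 factor = unname(footprint$factors),
                 kept = paste(footprint$kept_positions, collapse = ",")),
      f_fac, sep = "\t", quote = FALSE, row.names = FALSE)
    write_peak_table(footprint$table, f_norm)
    utils::write.table(calls, f_call, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_file(c(f_fac, f_norm, f_call))
    say(sum(calls$direction == "lost"), " lost, ",
        sum(calls$direction == "gained"), " gained positions")
  }

  inputs <- c(cfg$genome, cfg$annotations, cfg$stats, cfg$peaks)
  input_md5 <- unname(tools::md5sum(inputs))
  # path-valued fields enter the manifest by basename so that the same
  # configuration run into two directories yields byte-identical manifests
  mcfg <- cfg
  mcfg$outdir <- NULL   # where results land does not identify the analysis
  for (nm in c("genome", "annotations", "stats", "peaks"))
    if (!is.null(mcfg[[nm]])) mcfg[[nm]] <- basename(mcfg[[nm]])
  flat <- unlist(mcfg[!vapply(mcfg, is.null, logical(1))])
  manifest <- data.frame(
    key = c("package", "version", names(flat),
            paste0("md5_", basename(inputs))),
    value = c("cisray", as.character(utils::packageVersion("cisray")),
              unname(vapply(flat, as.character, character(1))),
              input_md5),
    stringsAsFactors = FALSE)
  f_man <- file.path(cfg$outdir, "manifest.tsv")
  utils::write.table(manifest, f_man, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_file(f_man)
  say("done in ", round(as.numeric(Sys.time() - t0, units = "secs"), 1),
      " s")

  invisible(list(windows = windows, labels = labels,
                 enrichment = enrichment, scatter = scatter,
                 footprint = footprint, calls = calls, truth = truth,
                 files = files))
}
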