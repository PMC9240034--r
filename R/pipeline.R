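# End-to-end orchestration with stable plain-text file contracts (TSV,
# BED6+, bedGraph, GTF, FASTA, JSON manifest). All outputs are written
# atomically into a staging directory and moved into place only when every
# stage has succeeded, so a failed run leaves no partial outputs.

#' Write / read a window-count table as TSV
#'
#' The counts TSV carries `transcript_id`, `window_start`, `window_end` and
#' one column per sample; the sample sheet TSV maps columns to assay,
#' genotype and replicate.
#'
#' @param wt a `window_table`
#' @param counts_path,samples_path TSV paths
#' @return `counts_path` ([write_window_table()]) or a `window_table`
#' @export
write_window_table <- function(wt, counts_path, samples_path) {
  df <- data.frame(transcript_id = wt$windows$transcript_id,
                   window_start = wt$windows$start,
                   window_end = wt$windows$end, stringsAsFactors = FALSE)
  write_tsv(cbind(df, as.data.frame(wt$counts)), counts_path)
  write_tsv(wt$samples, samples_path)
  invisible(counts_path)
}

#' @rdname write_window_table
#' @param window,step scan parameters recorded in the returned object
#' @export
read_window_table <- function(counts_path, samples_path, window = 100L, step = 10L) {
  df <- read_tsv(counts_path)
  need <- c("transcript_id", "window_start", "window_end")
  if (!all(need %in% names(df)))
    stopf("'%s': missing column(s) %s", counts_path,
          paste(setdiff(need, names(df)), collapse = ", "))
  samples <- read_tsv(samples_path)
  windows <- data.frame(transcript_id = df$transcript_id,
                        start = df$window_start, end = df$window_end,
                        stringsAsFactors = FALSE)
  window_table(windows, as.matrix(df[, as.character(samples$sample), drop = FALSE]),
               samples, window = window, step = step)
}

bed_score <- function(q) pmin(1000L, as.integer(round(-10 * log10(pmax(q, 1e-100)))))

#' Write peaks as BED6+
#'
#' Transcript-space BED uses the transcript id as the chromosome; with
#' `models` supplied, a genome-projected BED (exonic span of the peak) is
#' written instead. Extra columns: summit, log2 enrichment, p, q.
#'
#' @param peaks peak data.frame from [call_peaks()]
#' @param path output path
#' @param models optional named list of `transcript_model` for genomic
#'   projection
#' @return `path`, invisibly
#' @export
write_peaks_bed <- function(peaks, path, models = NULL) {
  if (nrow(peaks) == 0L) return(atomic_write(path, function(p) writeLines(character(0), p)))
  if (is.null(models)) {
    df <- data.frame(chrom = peaks$transcript_id, start = peaks$start,
                     end = peaks$end,
                     name = sprintf("%s_peak%d", peaks$transcript_id,
                                    seq_len(nrow(peaks))),
                     score = bed_score(peaks$q_value), strand = "+",
                     summit = peaks$summit,
                     log2_enrichment = peaks$log2_enrichment,
                     p_value = peaks$p_value, q_value = peaks$q_value)
  } else {
    proj <- t(vapply(seq_len(nrow(peaks)), function(i) {
      tm <- models[[peaks$transcript_id[i]]]
      g <- transcript_to_genomic(tm, c(peaks$start[i], peaks$end[i] - 1L))
      gs <- transcript_to_genomic(tm, peaks$summit[i])
      c(min(g), max(g) + 1L, gs)
    }, integer(3L)))
    chrom <- vapply(peaks$transcript_id, function(t) models[[t]]$chrom, character(1L))
    strand <- vapply(peaks$transcript_id, function(t) models[[t]]$strand, character(1L))
    df <- data.frame(chrom = chrom, start = proj[, 1L], end = proj[, 2L],
                     name = sprintf("%s_peak%d", peaks$transcript_id,
                                    seq_len(nrow(peaks))),
                     score = bed_score(peaks$q_value), strand = strand,
                     summit = proj[, 3L],
                     log2_enrichment = peaks$log2_enrichment,
                     p_value = peaks$p_value, q_value = peaks$q_value)
  }
  atomic_write(path, function(p)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE))
}

#' Write per-window log2 enrichment as bedGraph (transcript space)
#'
#' @param tested tested-window data.frame (attribute `tested_windows` of
#'   [call_peaks()] output)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(tested, path) {
  atomic_write(path, function(p)
    write.table(data.frame(tested$transcript_id, tested$start, tested$end,
                           signif(tested$log2_enrichment, 6)),
                p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE))
}

#' Run the full pipeline on simulated data
#'
#' simulate -> peak calling -> landscape -> differential methylation ->
#' decay -> qPCR -> differential expression, writing every artifact under
#' `out_dir`. Deterministic given (config, seed): running twice with the
#' same configuration produces byte-identical files. On any stage error the
#' staging area is discarded and no partial outputs are left behind.
#'
#' @param out_dir output directory (created if needed)
#' @param cfg a [sim_config()]; its seed drives every stochastic stage
#' @param q_threshold peak FDR threshold (default 0.05)
#' @param exclude_frac exclusion fraction (default 1/20)
#' @param bins_per_segment metagene bins per segment (default 33)
#' @param flank motif window half-width in nt (default 50)
#' @param n_background background draws for the motif test (default 10000)
#' @param alpha,lfc DEG thresholds (defaults 0.05 and 1)
#' @return invisible list of the in-memory stage results; files on disk
#' @export
run_pipeline <- function(out_dir, cfg, q_threshold = 0.05,
                         exclude_frac = 1 / 20, bins_per_segment = 33L,
                         flank = 50L, n_background = 10000L,
                         alpha = 0.05, lfc = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- file.path(out_dir, sprintf(".staging-%d", Sys.getpid()))
  dir.create(stage, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  pth <- function(f) file.path(stage, f)

  sim <- simulate_transcriptome(cfg)
  Biostrings::writeXStringSet(sim$sequences, pth("transcripts.fa"))
  write_gtf(sim$models, pth("annotation.gtf"))
  jsonlite::write_json(list(genes = sim$truth$genes, sites = sim$truth$sites),
                       pth("truth.json"), digits = NA, pretty = TRUE)

  wt <- simulate_merip_counts(sim, cfg)
  write_window_table(wt, pth("merip_counts.tsv"), pth("samples.tsv"))

  peaks <- suppressWarnings(call_peaks(wt, q_threshold = q_threshold,
                                       exclude_frac = exclude_frac))
  write_tsv(peaks, pth("peaks.tsv"))
  write_peaks_bed(peaks, pth("peaks_tx.bed"))
  write_peaks_bed(peaks, pth("peaks_genome.bed"), models = sim$models)
  write_bedgraph(attr(peaks, "tested_windows"), pth("enrichment.bedgraph"))

  if (nrow(peaks) > 0L) {
    prof <- suppressWarnings(metagene_profile(peaks, sim$models, bins_per_segment))
    write_tsv(as.data.frame(prof), pth("metagene.tsv"))
    seg <- suppressWarnings(segment_distribution(peaks, sim$models))
    write_tsv(data.frame(segment = names(seg), fraction = as.numeric(seg)),
              pth("segment_fractions.tsv"))
    motif <- drach_enrichment(peaks, sim$sequences, flank = flank,
                              n_background = n_background, seed = cfg$seed + 5L)
    jsonlite::write_json(motif, pth("drach.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    dm <- differential_methylation(peaks, wt)
    write_tsv(dm, pth("diffmeth.tsv"))
  }

  decay <- normalize_decay(simulate_decay(sim, cfg))
  write_tsv(decay, pth("decay_normalized.tsv"))
  fits <- do.call(rbind, lapply(split(decay, list(decay$gene, decay$genotype)),
                                function(d) {
    f <- fit_halflife(d)
    data.frame(gene = d$gene[1L], genotype = d$genotype[1L], k = f$k,
               halflife = f$halflife, se_k = f$se_k, r_squared = f$r_squared,
               stringsAsFactors = FALSE)
  }))
  fits <- fits[order(fits$gene, fits$genotype), ]
  rownames(fits) <- NULL
  write_tsv(fits, pth("decay_fits.tsv"))
  targets <- sim$truth$genes$gene_id[sim$truth$genes$target]
  cmp <- do.call(rbind, lapply(targets, function(g) {
    d <- decay[decay$gene == g, ]
    cs <- compare_stability(d[d$genotype == "WT", ], d[d$genotype == "KO", ],
                            seed = cfg$seed + 6L)
    data.frame(gene = g, halflife_wt = cs$halflife_ref,
               halflife_ko = cs$halflife_test,
               halflife_diff = cs$halflife_diff,
               ci_lower = cs$ci[1L], ci_upper = cs$ci[2L],
               min_timepoint_p = min(cs$timepoints$p_value),
               stringsAsFactors = FALSE)
  }))
  write_tsv(cmp, pth("decay_comparison.tsv"))

  ct <- simulate_qpcr(sim, cfg)
  rel <- do.call(rbind, lapply(targets, function(g) {
    d <- ct[ct$gene == g, ]
    m <- function(grp, col) mean(d[[col]][d$group == grp])
    data.frame(gene = g,
               fold_ko_vs_wt = ddct(m("KO", "ct_target"), m("KO", "ct_ref"),
                                    m("WT", "ct_target"), m("WT", "ct_ref")),
               stringsAsFactors = FALSE)
  }))
  write_tsv(rel, pth("qpcr_ddct.tsv"))

  expr <- simulate_expression(cfg)
  de <- classify_deg(de_test(expr$counts, expr$conditions),
                     alpha = alpha, lfc = lfc)
  write_tsv(de, pth("expression_de.tsv"))
  sets <- list(planted_up = expr$truth$gene[expr$truth$label == "up"],
               planted_down = expr$truth$gene[expr$truth$label == "down"],
               first_decile = expr$truth$gene[seq_len(max(1L, nrow(expr$truth) %/% 10L))])
  sets <- sets[vapply(sets, length, integer(1L)) > 0L]
  enr <- geneset_enrichment(de$gene[de$class != "ns"], de$gene, sets)
  write_tsv(enr, pth("geneset_enrichment.tsv"))

  manifest <- list(
    package = "meriptools",
    version = as.character(utils::packageVersion("meriptools")),
    parameters = c(unclass(cfg),
                   list(q_threshold = q_threshold, exclude_frac = exclude_frac,
                        bins_per_segment = bins_per_segment, flank = flank,
                        n_background = n_background, alpha = alpha, lfc = lfc)),
    input_checksums = as.list(tools::md5sum(c(pth("transcripts.fa"),
                                              pth("annotation.gtf"),
                                              pth("merip_counts.tsv")))),
    n_peaks = nrow(peaks))
  names(manifest$input_checksums) <- basename(names(manifest$input_checksums))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  for (f in list.files(stage)) {
    if (!file.rename(file.path(stage, f), file.path(out_dir, f)))
      stopf("failed to move '%s' into '%s'", f, out_dir)
  }
  ok <- TRUE
  invisible(list(sim = sim, window_table = wt, peaks = peaks, decay = decay,
                 fits = fits, comparison = cmp, ddct = rel, de = de,
                 enrichment = enr))
}
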