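# m6A peak calling: 100-nt sliding windows (10-nt steps) on the longest
# isoform, exclusion of windows below 1/20 of the transcript's top window in
# both IP and input, one-sided Fisher IP-vs-input enrichment against library
# totals, BH FDR, and merging of significant windows into peaks.

#' Sliding windows over a transcript
#'
#' Window starts are `0, step, 2*step, ...` while `start + window <=
#' length_tx`, plus a final flush window ending at `length_tx` when the
#' stepped scan would leave a 3'-tail uncovered. A transcript shorter than
#' one window yields a single whole-transcript window. With `step <= window`
#' every base is therefore covered.
#'
#' @param tm a `transcript_model`, or a single transcript length in nt
#' @param window window width in nt (default 100)
#' @param step step in nt (default 10)
#' @return data.frame with columns `transcript_id` (absent when `tm` is a
#'   bare length), `start`, `end` (0-based half-open transcript coords)
#' @export
make_windows <- function(tm, window = 100L, step = 10L) {
  if (!is_count(window) || !is_count(step))
    stopf("window and step must be positive integers")
  len <- if (inherits(tm, "transcript_model")) tm$length_tx else as.integer(tm)
  if (len < 1L) stopf("transcript length must be positive")
  starts <- if (len < window) 0L else seq.int(0L, len - window, by = step)
  if (len >= window && starts[length(starts)] + window < len)
    starts <- c(starts, len - window)
  ends <- pmin(starts + window, len)
  out <- data.frame(start = as.integer(starts), end = as.integer(ends))
  if (inherits(tm, "transcript_model"))
    out <- cbind(transcript_id = tm$transcript_id, out, stringsAsFactors = FALSE)
  out
}

#' Assemble a window-count table
#'
#' Couples window coordinates with a per-sample count matrix and a sample
#' sheet describing each column (assay IP/input, genotype, replicate).
#'
#' @param windows data.frame with `transcript_id`, `start`, `end`
#' @param counts integer matrix, `nrow(windows)` rows; columns named as in
#'   `samples$sample`
#' @param samples data.frame with columns `sample`, `assay` (`"IP"` or
#'   `"input"`), `genotype`, `replicate`
#' @param window,step the scan parameters the windows were built with
#' @return object of class `window_table`
#' @export
window_table <- function(windows, counts, samples, window = 100L, step = 10L) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(windows),
            all(c("transcript_id", "start", "end") %in% names(windows)),
            all(c("sample", "assay", "genotype", "replicate") %in% names(samples)))
  if (!all(samples$assay %in% c("IP", "input")))
    stopf("sample assay labels must be 'IP' or 'input'")
  if (!identical(sort(colnames(counts)), sort(as.character(samples$sample))))
    stopf("count matrix columns must match the sample sheet")
  counts <- counts[, as.character(samples$sample), drop = FALSE]
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be non-negative integers")
  structure(list(windows = as.data.frame(windows), counts = counts,
                 samples = as.data.frame(samples),
                 window = as.integer(window), step = as.integer(step)),
            class = "window_table")
}

#' @export
print.window_table <- function(x, ...) {
  cat(sprintf("<window_table> %d windows x %d samples (%d transcripts; W=%d, step=%d)\n",
              nrow(x$windows), ncol(x$counts),
              length(unique(x$windows$transcript_id)), x$window, x$step))
  invisible(x)
}

assay_sums <- function(wt, assay, genotypes = NULL) {
  sel <- wt$samples$assay == assay
  if (!is.null(genotypes)) sel <- sel & wt$samples$genotype %in% genotypes
  cols <- as.character(wt$samples$sample[sel])
  if (length(cols) == 0L) stopf("no '%s' samples selected", assay)
  rowSums(wt$counts[, cols, drop = FALSE])
}

#' Low-count window exclusion
#'
#' Implements the rule of dropping windows whose read counts fall below a
#' fraction `frac` (default 1/20) of the transcript's top window. With the
#' default `mode = "both"` a window is excluded only if it is strictly below
#' the threshold in *both* the IP and the input assay (replicates summed
#' within assay); a window at exactly the threshold is retained. `mode =
#' "either"` excludes on failing either assay.
#'
#' @param wt a `window_table`
#' @param frac exclusion fraction (default 1/20); `frac = 0` retains all
#' @param mode `"both"` (default) or `"either"`
#' @param genotypes optional genotype subset used for the assay sums
#' @return the retained `window_table`; attributes `thresholds` (per
#'   transcript) and `keep` (logical over the input windows) record the rule
#'   application
#' @export
exclusion_filter <- function(wt, frac = 1 / 20, mode = c("both", "either"),
                             genotypes = NULL) {
  mode <- match.arg(mode)
  if (frac < 0) stopf("frac must be >= 0")
  ip <- assay_sums(wt, "IP", genotypes)
  input <- assay_sums(wt, "input", genotypes)
  tid <- wt$windows$transcript_id
  max_ip <- tapply(ip, tid, max)[tid]
  max_input <- tapply(input, tid, max)[tid]
  all_zero <- max_ip == 0 & max_input == 0
  if (any(all_zero))
    warnf("%d transcript(s) with all-zero counts: all their windows excluded",
          length(unique(tid[all_zero])))
  below_ip <- ip < frac * max_ip
  below_input <- input < frac * max_input
  excluded <- if (mode == "both") below_ip & below_input else below_ip | below_input
  keep <- unname(as.vector(!excluded & !all_zero))
  thr <- unique(data.frame(transcript_id = tid,
                           threshold_ip = frac * max_ip,
                           threshold_input = frac * max_input,
                           row.names = NULL))
  out <- wt
  out$windows <- wt$windows[keep, , drop = FALSE]
  out$counts <- wt$counts[keep, , drop = FALSE]
  rownames(out$windows) <- NULL
  attr(out, "thresholds") <- thr
  attr(out, "keep") <- keep
  out
}

#' One-sided IP-enrichment test for a window
#'
#' One-sided Fisher's exact test on the 2x2 table
#' `[[ip_count, ip_total - ip_count], [input_count, input_total -
#' input_count]]` with alternative "IP-enriched", computed as the
#' hypergeometric upper tail. The reported effect size is
#' `log2(((ip_count + 0.5)/ip_total) / ((input_count + 0.5)/input_total))`;
#' the 0.5 pseudocount enters only the ratio, never the test.
#'
#' @param ip_count,input_count window counts (vectors recycle)
#' @param ip_total,input_total library totals
#' @return list with vectors `p_value` and `log2_enrichment`
#' @export
window_enrichment_test <- function(ip_count, input_count, ip_total, input_total) {
  n <- max(length(ip_count), length(input_count))
  ip_count <- rep_len(ip_count, n); input_count <- rep_len(input_count, n)
  ip_total <- rep_len(ip_total, n); input_total <- rep_len(input_total, n)
  if (any(ip_count < 0) || any(input_count < 0))
    stopf("counts must be non-negative")
  if (any(ip_count > ip_total) || any(input_count > input_total))
    stopf("window count exceeds library total")
  p <- phyper(ip_count - 1, ip_total, input_total, ip_count + input_count,
              lower.tail = FALSE)
  lfc <- log2(((ip_count + 0.5) / ip_total) / ((input_count + 0.5) / input_total))
  list(p_value = pmin(p, 1), log2_enrichment = lfc)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p_values numeric vector in `[0, 1]`
#' @return step-up adjusted q-values
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Merge significant windows into peaks
#'
#' Overlapping or bookended windows with `q <= q_threshold` are merged into
#' one peak spanning their union. The peak p/q are the minima over merged
#' windows; the summit is the midpoint of the minimum-p window (earliest such
#' window on ties); `log2_enrichment` is taken from that window.
#'
#' @param tested data.frame with `transcript_id`, `start`, `end`, `p_value`,
#'   `q_value`, `log2_enrichment`
#' @param q_threshold FDR threshold (default 0.05)
#' @return data.frame of peaks (`transcript_id`, `start`, `end`, `summit`,
#'   `p_value`, `q_value`, `log2_enrichment`, `n_windows`)
#' @export
merge_windows <- function(tested, q_threshold = 0.05) {
  sig <- tested[tested$q_value <= q_threshold, , drop = FALSE]
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), summit = integer(), p_value = double(),
                      q_value = double(), log2_enrichment = double(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(empty)
  res <- lapply(split(sig, sig$transcript_id), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(d$start[-1L] > cummax(d$end[-nrow(d)]))))
    do.call(rbind, lapply(split(d, grp), function(g) {
      best <- which.min(g$p_value)[1L]
      data.frame(transcript_id = g$transcript_id[1L],
                 start = min(g$start), end = max(g$end),
                 summit = as.integer(floor((g$start[best] + g$end[best]) / 2)),
                 p_value = min(g$p_value), q_value = min(g$q_value),
                 log2_enrichment = g$log2_enrichment[best],
                 n_windows = nrow(g), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call m6A peaks from a window-count table
#'
#' Composition of the scan: low-count exclusion, per-window one-sided Fisher
#' IP-vs-input test against library totals (replicates summed within assay),
#' BH adjustment across all tested windows of the run, and merging of
#' significant windows into peaks. Library totals are column sums over the
#' *full* table, i.e. library sizes, not post-filter sums.
#'
#' @param wt a `window_table`
#' @param q_threshold FDR threshold for window significance (default 0.05)
#' @param exclude_frac exclusion fraction (default 1/20)
#' @param exclusion_mode `"both"` (default) or `"either"`; see
#'   [exclusion_filter()]
#' @param genotypes optional genotype subset (default: all samples pooled)
#' @return data.frame of peaks as in [merge_windows()]; attribute
#'   `provenance` records thresholds, totals and window counts at each stage
#' @export
call_peaks <- function(wt, q_threshold = 0.05, exclude_frac = 1 / 20,
                       exclusion_mode = "both", genotypes = NULL) {
  sel <- rep(TRUE, nrow(wt$samples))
  if (!is.null(genotypes)) sel <- wt$samples$genotype %in% genotypes
  ip_cols <- as.character(wt$samples$sample[sel & wt$samples$assay == "IP"])
  input_cols <- as.character(wt$samples$sample[sel & wt$samples$assay == "input"])
  if (length(ip_cols) == 0L || length(input_cols) == 0L)
    stopf("call_peaks requires both IP and input samples")
  ip_total <- sum(wt$counts[, ip_cols, drop = FALSE])
  input_total <- sum(wt$counts[, input_cols, drop = FALSE])
  kept <- suppressWarnings(
    exclusion_filter(wt, frac = exclude_frac, mode = exclusion_mode,
                     genotypes = genotypes))
  prov <- list(n_windows = nrow(wt$windows), n_tested = nrow(kept$windows),
               ip_total = ip_total, input_total = input_total,
               thresholds = attr(kept, "thresholds"),
               q_threshold = q_threshold, exclude_frac = exclude_frac,
               exclusion_mode = exclusion_mode)
  if (nrow(kept$windows) == 0L) {
    out <- merge_windows(data.frame(transcript_id = character(), start = integer(),
                                    end = integer(), p_value = double(),
                                    q_value = double(), log2_enrichment = double()),
                         q_threshold)
    attr(out, "provenance") <- c(prov, list(n_significant = 0L))
    return(out)
  }
  ip <- rowSums(kept$counts[, ip_cols, drop = FALSE])
  input <- rowSums(kept$counts[, input_cols, drop = FALSE])
  test <- window_enrichment_test(ip, input, ip_total, input_total)
  tested <- cbind(kept$windows[, c("transcript_id", "start", "end")],
                  p_value = test$p_value, q_value = bh_adjust(test$p_value),
                  log2_enrichment = test$log2_enrichment)
  peaks <- merge_windows(tested, q_threshold)
  attr(peaks, "provenance") <- c(prov, list(n_significant = sum(tested$q_value <= q_threshold)))
  attr(peaks, "tested_windows") <- tested
  peaks
}

#' Knockout-versus-wild-type differential methylation
#'
#' For each peak (called on pooled data) the counts of its constituent
#' windows -- those contained in the merged peak span -- are summed per
#' genotype x assay (replicates summed) and compared by a
#' two-sided Fisher's exact test on `[[IP_KO, input_KO], [IP_WT,
#' input_WT]]`. The effect size is the log2 ratio of library-size-normalized
#' IP/input enrichment between genotypes (0.5 pseudocount on counts, applied
#' to the ratio only, never inside the test); positive values mean higher
#' methylation in the test genotype. Library sizes are median-of-ratios
#' factors over all windows rather than raw column totals, so that strong
#' differential peaks cannot bias the normalization of every other peak
#' through library composition; with no such peaks the two coincide. BH
#' adjustment is across peaks. Swapping the genotype labels negates the
#' log2 ratio exactly and leaves p-values unchanged.
#'
#' @param peaks data.frame of peaks from [call_peaks()]
#' @param wt the `window_table` holding both genotypes
#' @param test,reference genotype labels (defaults `"KO"` vs `"WT"`)
#' @return `peaks` with added columns `ip_test`, `input_test`, `ip_ref`,
#'   `input_ref`, `log2_ratio`, `dm_p_value`, `dm_q_value`
#' @export
differential_methylation <- function(peaks, wt, test = "KO", reference = "WT") {
  for (g in c(test, reference))
    if (!g %in% wt$samples$genotype) stopf("genotype '%s' absent from sample sheet", g)
  cols <- function(genotype, assay)
    as.character(wt$samples$sample[wt$samples$genotype == genotype &
                                     wt$samples$assay == assay])
  ip_t <- rowSums(wt$counts[, cols(test, "IP"), drop = FALSE])
  in_t <- rowSums(wt$counts[, cols(test, "input"), drop = FALSE])
  ip_r <- rowSums(wt$counts[, cols(reference, "IP"), drop = FALSE])
  in_r <- rowSums(wt$counts[, cols(reference, "input"), drop = FALSE])
  pooled <- cbind(ip_t = ip_t, in_t = in_t, ip_r = ip_r, in_r = in_r)
  totals <- tryCatch(size_factors(pooled),
                     error = function(e) colSums(pooled) / mean(colSums(pooled)))
  if (nrow(peaks) == 0L) {
    peaks$ip_test <- peaks$input_test <- peaks$ip_ref <- peaks$input_ref <- numeric(0)
    peaks$log2_ratio <- peaks$dm_p_value <- peaks$dm_q_value <- numeric(0)
    return(peaks)
  }
  stats <- t(vapply(seq_len(nrow(peaks)), function(i) {
    ov <- wt$windows$transcript_id == peaks$transcript_id[i] &
      wt$windows$start >= peaks$start[i] & wt$windows$end <= peaks$end[i]
    c(sum(ip_t[ov]), sum(in_t[ov]), sum(ip_r[ov]), sum(in_r[ov]))
  }, numeric(4L)))
  colnames(stats) <- c("ip_test", "input_test", "ip_ref", "input_ref")
  log2_ratio <- log2(((stats[, "ip_test"] + 0.5) / totals["ip_t"]) /
                       ((stats[, "input_test"] + 0.5) / totals["in_t"])) -
    log2(((stats[, "ip_ref"] + 0.5) / totals["ip_r"]) /
           ((stats[, "input_ref"] + 0.5) / totals["in_r"]))
  p <- vapply(seq_len(nrow(stats)), function(i)
    stats::fisher.test(matrix(stats[i, ], nrow = 2, byrow = TRUE))$p.value,
    numeric(1L))
  cbind(peaks, as.data.frame(stats), log2_ratio = log2_ratio,
        dm_p_value = p, dm_q_value = bh_adjust(p))
}
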