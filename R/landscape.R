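# Landscape of called peaks: metagene density on the segment-normalized
# transcript, segment distribution of summits, and a calibrated DRACH motif
# enrichment test against transcriptome-matched background windows.

metagene_coord <- function(tm, pos) {
  seg <- segment_lengths(tm)
  if (pos < tm$cds_start_tx) pos / seg[["FIVE_UTR"]]
  else if (pos < tm$cds_end_tx) 1 + (pos - tm$cds_start_tx) / seg[["CDS"]]
  else 2 + (pos - tm$cds_end_tx) / seg[["THREE_UTR"]]
}

summit_coords <- function(peaks, models, warn = TRUE) {
  out <- rep(NA_real_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    tm <- models[[peaks$transcript_id[i]]]
    if (is.null(tm)) stopf("no transcript model for '%s'", peaks$transcript_id[i])
    if (!is_coding(tm)) {
      if (warn) warnf("peak on non-coding transcript '%s' skipped", tm$transcript_id)
      next
    }
    if (any(segment_lengths(tm) == 0L)) {
      if (warn) warnf("transcript '%s' has a zero-length segment: skipped", tm$transcript_id)
      next
    }
    out[i] <- metagene_coord(tm, peaks$summit[i])
  }
  out
}

#' Metagene profile of peak density
#'
#' Each peak contributes its summit, mapped to the segment-normalized
#' coordinate: 5'UTR to `[0,1)`, CDS to `[1,2)`, 3'UTR to `[2,3]` (position
#' within segment divided by segment length, offset by segment index). The
#' histogram over `bins_per_segment` bins per segment is normalized to unit
#' area, so `sum(density * bin width) == 1`.
#'
#' @param peaks data.frame with `transcript_id` and `summit`
#' @param models named list of `transcript_model` (coding models are used;
#'   peaks on non-coding transcripts are skipped with a warning)
#' @param bins_per_segment bins per segment (default 33, i.e. 99 in total)
#' @return object of class `metagene_profile`: data.frame with `bin_start`,
#'   `bin_mid`, `bin_end`, `count`, `density`
#' @export
metagene_profile <- function(peaks, models, bins_per_segment = 33L) {
  coords <- summit_coords(peaks, models)
  coords <- coords[!is.na(coords)]
  if (length(coords) == 0L) stopf("no summits on coding transcripts")
  breaks <- seq(0, 3, length.out = 3L * bins_per_segment + 1L)
  width <- 3 / (3 * bins_per_segment)
  cnt <- as.integer(table(cut(coords, breaks, include.lowest = TRUE, right = FALSE)))
  out <- data.frame(bin_start = breaks[-length(breaks)],
                    bin_mid = breaks[-length(breaks)] + width / 2,
                    bin_end = breaks[-1L], count = cnt,
                    density = cnt / (length(coords) * width))
  class(out) <- c("metagene_profile", "data.frame")
  attr(out, "n_summits") <- length(coords)
  out
}

#' Distribution of peak summits over transcript segments
#'
#' @param peaks data.frame with `transcript_id` and `summit`
#' @param models named list of `transcript_model`
#' @return named numeric vector of fractions over
#'   `FIVE_UTR`/`CDS`/`THREE_UTR`, summing to 1
#' @export
segment_distribution <- function(peaks, models) {
  if (nrow(peaks) == 0L) stopf("segment_distribution: empty peak set")
  labs <- character(0)
  for (i in seq_len(nrow(peaks))) {
    tm <- models[[peaks$transcript_id[i]]]
    if (is.null(tm) || !is_coding(tm)) next
    labs <- c(labs, segment_of(tm, peaks$summit[i]))
  }
  if (length(labs) == 0L) stopf("segment_distribution: no summits on coding transcripts")
  cnt <- table(factor(labs, levels = c("FIVE_UTR", "CDS", "THREE_UTR")))
  setNames(as.numeric(cnt) / sum(cnt), names(cnt))
}

#' DRACH motif enrichment around peak summits
#'
#' Counts summit-centred windows (`summit +/- flank`, clipped at transcript
#' bounds) containing at least one DRACH match (`[AGT][AG]AC[ACT]`, i.e. the
#' IUPAC pattern `DRACH`), estimates the background rate from equal-width
#' windows drawn uniformly from the same transcriptome (seeded), and reports
#' a one-sided binomial test of observed versus background rate.
#'
#' @param peaks data.frame with `transcript_id` and `summit`
#' @param sequences named `DNAStringSet` (or named character vector) of
#'   transcript sequences
#' @param flank half-width of the summit window in nt (default 50)
#' @param n_background number of background draws (default 10000)
#' @param seed RNG seed for the background sampling
#' @return list with `observed_rate`, `expected_rate`, `p_value`, `n_peaks`,
#'   `n_background`, `n_clipped`
#' @export
drach_enrichment <- function(peaks, sequences, flank = 50L,
                             n_background = 10000L, seed = 1L) {
  if (nrow(peaks) == 0L) stopf("drach_enrichment: empty peak set")
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences))) stopf("sequences must be named by transcript id")
  missing <- setdiff(unique(peaks$transcript_id), names(sequences))
  if (length(missing))
    stopf("no sequence for transcript(s): %s", paste(missing, collapse = ", "))
  lens <- Biostrings::width(sequences)
  names(lens) <- names(sequences)
  width <- 2L * flank + 1L
  starts <- pmax(0L, peaks$summit - flank)
  ends <- pmin(lens[peaks$transcript_id], peaks$summit + flank + 1L)
  n_clipped <- sum(ends - starts < width)
  obs_seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(peaks)), function(i)
    Biostrings::subseq(sequences[[peaks$transcript_id[i]]],
                       start = starts[i] + 1L, end = ends[i])))
  has_drach <- function(ss)
    Biostrings::vcountPattern("DRACH", ss, fixed = FALSE) > 0L
  obs_hit <- has_drach(obs_seqs)
  bg_hit <- withr::with_seed(seed, {
    tx <- sample(length(sequences), n_background, replace = TRUE,
                 prob = pmax(lens, 1L))
    bstart <- vapply(tx, function(j) {
      m <- max(lens[j] - width, 0L)
      as.integer(floor(runif(1, 0, m + 1)))
    }, integer(1L))
    bend <- pmin(bstart + width, lens[tx])
    has_drach(Biostrings::DNAStringSet(lapply(seq_len(n_background), function(i)
      Biostrings::subseq(sequences[[tx[i]]], start = bstart[i] + 1L, end = bend[i]))))
  })
  expected <- mean(bg_hit)
  # one-sided exact binomial upper tail of the observed hit count
  p <- pbinom(sum(obs_hit) - 1L, nrow(peaks), expected, lower.tail = FALSE)
  list(observed_rate = mean(obs_hit), expected_rate = expected,
       p_value = min(max(p, 0), 1), n_peaks = nrow(peaks),
       n_background = as.integer(n_background), n_clipped = as.integer(n_clipped))
}
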