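# Transcript models: longest-isoform selection and transcript-relative
# coordinates. Internal coordinates are 0-based half-open throughout; GTF is
# read as 1-based closed and converted at the boundary.

#' Construct a transcript model
#'
#' A transcript model carries one isoform's exon structure together with
#' transcript-relative CDS offsets, so that downstream window scanning,
#' metagene profiling and segment classification can work entirely in
#' transcript coordinates.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end`: genomic
#'   0-based half-open intervals, rows ordered 5'->3' in *transcript*
#'   orientation (descending genomic coordinate on the minus strand).
#' @param cds_start_tx,cds_end_tx transcript-relative CDS span (0-based
#'   half-open), or `NA` for a non-coding transcript.
#' @return an object of class `transcript_model` with fields
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `exons`, `cds_start_tx`,
#'   `cds_end_tx`, `length_tx`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start_tx = NA_integer_,
                             cds_end_tx = NA_integer_) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-', got '%s'", strand)
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (nrow(exons) == 0L) stopf("transcript '%s' has no exons", transcript_id)
  if (any(exons$end <= exons$start))
    stopf("transcript '%s': exon with non-positive width", transcript_id)
  ord <- if (strand == "+") order(exons$start) else order(-exons$start)
  if (!identical(ord, seq_len(nrow(exons)))) exons <- exons[ord, , drop = FALSE]
  gord <- order(exons$start)
  g <- exons[gord, , drop = FALSE]
  if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)]))
    stopf("transcript '%s': overlapping exons", transcript_id)
  rownames(exons) <- NULL
  length_tx <- sum(exons$end - exons$start)
  coding <- !is.na(cds_start_tx) || !is.na(cds_end_tx)
  if (coding) {
    if (is.na(cds_start_tx) || is.na(cds_end_tx))
      stopf("transcript '%s': cds_start_tx and cds_end_tx must both be set", transcript_id)
    if (!(cds_start_tx >= 0 && cds_start_tx < cds_end_tx && cds_end_tx <= length_tx))
      stopf("transcript '%s': CDS [%d,%d) outside transcript of length %d",
            transcript_id, cds_start_tx, cds_end_tx, length_tx)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_start_tx = if (coding) as.integer(cds_start_tx) else NA_integer_,
                 cds_end_tx = if (coding) as.integer(cds_end_tx) else NA_integer_,
                 length_tx = as.integer(length_tx)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is_coding(x)) sprintf("CDS [%d,%d)", x$cds_start_tx, x$cds_end_tx) else "non-coding"
  cat(sprintf("<transcript_model> %s (%s) %s:%s, %d exon(s), %d nt, %s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$length_tx, cds))
  invisible(x)
}

#' Is a transcript model coding?
#' @param tm a `transcript_model`
#' @return logical
#' @export
is_coding <- function(tm) !is.na(tm$cds_start_tx)

#' Segment lengths of a coding transcript
#'
#' @param tm a coding `transcript_model`
#' @return named integer vector `c(FIVE_UTR=, CDS=, THREE_UTR=)`; the three
#'   lengths always partition `length_tx`.
#' @export
segment_lengths <- function(tm) {
  if (!is_coding(tm)) stopf("transcript '%s' is non-coding: no segmentation", tm$transcript_id)
  c(FIVE_UTR = tm$cds_start_tx,
    CDS = tm$cds_end_tx - tm$cds_start_tx,
    THREE_UTR = tm$length_tx - tm$cds_end_tx)
}

#' Segment label of a transcript position
#'
#' Classifies a transcript-relative position into 5'UTR, CDS or 3'UTR by
#' half-open comparison against the CDS span: `pos == cds_start_tx` is CDS,
#' `pos == cds_end_tx` is 3'UTR.
#'
#' @param tm a coding `transcript_model`
#' @param pos transcript coordinate(s), `0 <= pos < length_tx`
#' @return character vector over `{"FIVE_UTR","CDS","THREE_UTR"}`
#' @export
segment_of <- function(tm, pos) {
  if (!is_coding(tm)) stopf("transcript '%s' is non-coding: no segmentation", tm$transcript_id)
  if (any(pos < 0 | pos >= tm$length_tx))
    stopf("position out of range [0,%d) for transcript '%s'", tm$length_tx, tm$transcript_id)
  ifelse(pos < tm$cds_start_tx, "FIVE_UTR",
         ifelse(pos < tm$cds_end_tx, "CDS", "THREE_UTR"))
}

#' Map genomic to transcript coordinates
#'
#' @param tm a `transcript_model`
#' @param gpos genomic coordinate(s) (0-based); must lie within an exon
#' @return transcript coordinate(s), 0-based, in transcript orientation
#' @export
genomic_to_transcript <- function(tm, gpos) {
  widths <- tm$exons$end - tm$exons$start
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  vapply(gpos, function(g) {
    i <- which(g >= tm$exons$start & g < tm$exons$end)
    if (length(i) != 1L)
      stopf("genomic position %d is not exonic in transcript '%s'", g, tm$transcript_id)
    within <- if (tm$strand == "+") g - tm$exons$start[i] else tm$exons$end[i] - 1L - g
    as.integer(offsets[i] + within)
  }, integer(1L))
}

#' Map transcript to genomic coordinates
#'
#' Exact inverse of [genomic_to_transcript()] on exonic bases.
#'
#' @param tm a `transcript_model`
#' @param tpos transcript coordinate(s), `0 <= tpos < length_tx`
#' @return genomic coordinate(s) (0-based)
#' @export
transcript_to_genomic <- function(tm, tpos) {
  widths <- tm$exons$end - tm$exons$start
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  vapply(tpos, function(t) {
    if (t < 0 || t >= tm$length_tx)
      stopf("transcript position %d out of range [0,%d)", t, tm$length_tx)
    i <- max(which(t >= offsets))
    within <- t - offsets[i]
    if (tm$strand == "+") as.integer(tm$exons$start[i] + within)
    else as.integer(tm$exons$end[i] - 1L - within)
  }, integer(1L))
}

#' Longest isoform of one gene
#'
#' @param models non-empty list of `transcript_model`s sharing a `gene_id`
#' @return the model with maximal `length_tx`; ties are broken by
#'   lexicographically smallest `transcript_id` so the choice is deterministic.
#' @export
longest_isoform <- function(models) {
  if (length(models) == 0L) stopf("longest_isoform: empty model list")
  gids <- vapply(models, `[[`, character(1L), "gene_id")
  if (length(unique(gids)) != 1L)
    stopf("longest_isoform: models span multiple genes (%s)",
          paste(unique(gids), collapse = ", "))
  lens <- vapply(models, `[[`, integer(1L), "length_tx")
  tids <- vapply(models, `[[`, character(1L), "transcript_id")
  models[[order(-lens, tids)[1L]]]
}

#' Longest isoform per gene
#'
#' @param models list of `transcript_model`s (any number of genes)
#' @return named list (by `transcript_id`, genes in sorted `gene_id` order)
#'   with one model per gene
#' @export
longest_per_gene <- function(models) {
  gids <- vapply(models, `[[`, character(1L), "gene_id")
  out <- lapply(sort(unique(gids)), function(g) longest_isoform(models[gids == g]))
  names(out) <- vapply(out, `[[`, character(1L), "transcript_id")
  out
}

#' Read transcript models from a GTF file
#'
#' Parses `exon` (and, when present, `CDS`) features, converts GTF 1-based
#' closed coordinates to internal 0-based half-open ones, and orients exons
#' 5'->3' along the transcript (reversed genomic order on the minus strand).
#' CDS features are projected into transcript coordinates; a CDS falling
#' outside the transcript's exons is a validation error.
#'
#' @param path path to a GTF file
#' @return named list of `transcript_model` (names are transcript ids)
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF file '%s' does not exist", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stopf("failed to parse GTF '%s': %s", path, conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) stopf("GTF '%s' contains no exon/CDS features", path)
  if (is.null(md$transcript_id) || is.null(md$gene_id))
    stopf("GTF '%s': exon/CDS records lack gene_id/transcript_id attributes", path)
  bad <- which(is.na(md$transcript_id) | is.na(md$gene_id))
  if (length(bad))
    stopf("GTF '%s': exon/CDS record %d lacks a gene_id/transcript_id attribute",
          path, bad[1L])
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  feat <- data.frame(type = as.character(md$type),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(BiocGenerics::strand(gr)),
                     start = start0, end = end0,
                     gene_id = as.character(md$gene_id),
                     transcript_id = as.character(md$transcript_id),
                     stringsAsFactors = FALSE)
  if (any(!feat$strand %in% c("+", "-")))
    stopf("GTF '%s': exon/CDS feature without '+'/'-' strand", path)
  out <- lapply(split(feat, feat$transcript_id), function(ft) {
    ex <- ft[ft$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L)
      stopf("transcript '%s' has CDS features but no exons", ft$transcript_id[1L])
    tm <- transcript_model(ft$transcript_id[1L], ft$gene_id[1L],
                           ex$chrom[1L], ex$strand[1L],
                           ex[, c("start", "end")])
    cds <- ft[ft$type == "CDS", , drop = FALSE]
    if (nrow(cds) > 0L) {
      tx <- tryCatch(
        unlist(lapply(seq_len(nrow(cds)), function(i)
          genomic_to_transcript(tm, c(cds$start[i], cds$end[i] - 1L)))),
        error = function(e) stopf("transcript '%s': CDS outside exons (%s)",
                                  tm$transcript_id, conditionMessage(e)))
      tm <- transcript_model(tm$transcript_id, tm$gene_id, tm$chrom, tm$strand,
                             tm$exons, cds_start_tx = min(tx),
                             cds_end_tx = max(tx) + 1L)
    }
    tm
  })
  out[order(names(out))]
}

#' Write transcript models to a GTF file
#'
#' Emits `exon` and (for coding models) `CDS` features in GTF 1-based closed
#' coordinates. Used by the simulator so that generated annotations
#' round-trip through [read_gtf()].
#'
#' @param models list of `transcript_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(tm) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tm$gene_id, tm$transcript_id)
    ex <- tm$exons[order(tm$exons$start), , drop = FALSE]
    ln <- sprintf("%s\tmeriptools\texon\t%d\t%d\t.\t%s\t.\t%s",
                  tm$chrom, ex$start + 1L, ex$end, tm$strand, attrs)
    if (is_coding(tm)) {
      # CDS transcript span -> genomic intervals, one per touched exon
      tpos <- tm$cds_start_tx:(tm$cds_end_tx - 1L)
      gpos <- sort(transcript_to_genomic(tm, tpos))
      brk <- c(0L, which(diff(gpos) != 1L), length(gpos))
      cds_ln <- vapply(seq_len(length(brk) - 1L), function(i) {
        g <- gpos[(brk[i] + 1L):brk[i + 1L]]
        sprintf("%s\tmeriptools\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                tm$chrom, min(g) + 1L, max(g) + 1L, tm$strand, attrs)
      }, character(1L))
      ln <- c(ln, cds_ln)
    }
    ln
  }))
  atomic_write(path, function(p) writeLines(lines, p))
}
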