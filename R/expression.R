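# Expression analysis: TPM, median-of-ratios size factors, a Welch-t
# differential-expression stand-in on log2 normalized counts (documented as
# *not* a negative-binomial GLM), threshold-based DEG classification, and
# hypergeometric gene-set enrichment.

#' Transcripts per million
#'
#' `rate_g = count_g / (length_g / 1000)`; `TPM_g = rate_g / sum(rates) *
#' 1e6`, per sample, so every column sums to one million.
#'
#' @param counts gene x sample count matrix
#' @param lengths effective gene lengths in nt (positive, one per gene)
#' @return TPM matrix of the same shape
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) stopf("one length per gene required")
  if (any(lengths <= 0)) stopf("gene lengths must be positive")
  if (any(counts < 0)) stopf("counts must be non-negative")
  rate <- counts / (lengths / 1000)
  cs <- colSums(rate)
  if (any(cs == 0)) stopf("all-zero sample column: TPM undefined")
  sweep(rate, 2L, cs, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median over all-nonzero genes of the ratio of
#' that sample's count to the gene's geometric mean across samples.
#'
#' @param counts gene x sample count matrix
#' @return per-sample size factors
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  nz <- rowSums(counts > 0) == ncol(counts)
  if (!any(nz)) stopf("no gene with nonzero counts in every sample")
  lg <- log(counts[nz, , drop = FALSE])
  ref <- rowMeans(lg)
  apply(lg, 2L, function(col) exp(median(col - ref)))
}

row_welch <- function(x, g1, g2) {
  x1 <- x[, g1, drop = FALSE]; x2 <- x[, g2, drop = FALSE]
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate: zero variance in both groups
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  tstat[zero & m1 == m2] <- 0
  list(log2fc = m2 - m1, t = tstat, df = df, p = p)
}

#' Differential-expression stand-in test
#'
#' Per-gene two-sided Welch t test on `log2(count / size_factor + 0.5)`,
#' with BH adjustment across genes. The log2 fold change is the difference
#' of group means on that scale (second condition level minus first). This
#' is a deliberately simple, well-calibrated stand-in and makes no
#' negative-binomial dispersion assumptions.
#'
#' @param counts gene x sample count matrix (rownames = gene ids)
#' @param conditions factor/character of length `ncol(counts)` with exactly
#'   two levels and >= 2 replicates each
#' @param sf optional size factors (default: [size_factors()])
#' @return data.frame `gene`, `base_mean`, `log2fc`, `t`, `df`, `p_value`,
#'   `q_value`
#' @export
de_test <- function(counts, conditions, sf = NULL) {
  counts <- as.matrix(counts)
  conditions <- factor(conditions)
  if (nlevels(conditions) != 2L) stopf("exactly two conditions required")
  if (any(table(conditions) < 2L)) stopf("need >= 2 replicates per condition")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  x <- log2(norm + 0.5)
  g1 <- which(conditions == levels(conditions)[1L])
  g2 <- which(conditions == levels(conditions)[2L])
  w <- row_welch(x, g1, g2)
  data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             base_mean = rowMeans(norm), log2fc = w$log2fc, t = w$t, df = w$df,
             p_value = w$p, q_value = bh_adjust(w$p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify differentially expressed genes
#'
#' A gene is `up` iff `p <= alpha` and `log2fc >= lfc`; `down` iff `p <=
#' alpha` and `log2fc <= -lfc`; otherwise `ns`. Boundaries are inclusive.
#' By default the *raw* p-value is thresholded; set `use_adjusted = TRUE`
#' to threshold the BH q-value instead.
#'
#' @param results data.frame with `p_value`, `q_value`, `log2fc`
#' @param alpha significance threshold (default 0.05)
#' @param lfc absolute log2 fold-change threshold (default 1)
#' @param use_adjusted threshold `q_value` instead of `p_value`
#' @return `results` with an added `class` column over `{"up","down","ns"}`
#' @export
classify_deg <- function(results, alpha = 0.05, lfc = 1, use_adjusted = FALSE) {
  p <- if (use_adjusted) results$q_value else results$p_value
  cls <- rep("ns", nrow(results))
  cls[p <= alpha & results$log2fc >= lfc] <- "up"
  cls[p <= alpha & results$log2fc <= -lfc] <- "down"
  results$class <- cls
  results
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric upper-tail test of the overlap between a gene
#' list and each set, within a fixed universe, with BH adjustment across
#' sets.
#'
#' @param genes character vector of selected genes (e.g. DEGs); must be a
#'   subset of `universe`
#' @param universe character vector of all testable genes
#' @param sets named list of character vectors, each a subset of `universe`
#' @return data.frame `set`, `set_size`, `overlap`, `p_value`, `q_value`
#' @export
geneset_enrichment <- function(genes, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0L) stopf("empty gene universe")
  genes <- unique(genes)
  if (!all(genes %in% universe)) stopf("gene list must be a subset of the universe")
  if (length(sets) && is.null(names(sets))) stopf("sets must be named")
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- unique(sets[[nm]])
    if (!all(s %in% universe)) stopf("set '%s' is not a subset of the universe", nm)
    x <- length(intersect(genes, s))
    p <- phyper(x - 1L, length(s), length(universe) - length(s), length(genes),
                lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = x, p_value = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) return(data.frame(set = character(), set_size = integer(),
                                      overlap = integer(), p_value = double(),
                                      q_value = double()))
  res$q_value <- bh_adjust(res$p_value)
  res
}
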