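# Independent oracles and fixture builders shared across tests.

# Brute-force one-sided Fisher p for the 2x2 table
# [[a, m1 - a], [c, m2 - c]]: enumerate every table with the same margins
# and sum hypergeometric probabilities of tables at least as IP-enriched.
# Uses only lchoose(); independent of phyper()/fisher.test().
fisher_tail_bruteforce <- function(a, c, m1, m2) {
  k <- a + c
  xs <- max(0L, k - m2):min(m1, k)
  pr <- exp(lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k))
  sum(pr[xs >= a])
}

# Brute-force hypergeometric upper tail for gene-set overlap: universe N,
# set size K, draw n, observed overlap x.
hyper_tail_bruteforce <- function(x, K, N, n) {
  xs <- max(0L, n - (N - K)):min(K, n)
  pr <- exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n))
  sum(pr[xs >= x])
}

# Single-exon coding transcript model with given segment lengths.
toy_tm <- function(l5 = 50L, lc = 100L, l3 = 50L, strand = "+",
                   tid = "tx1", gid = "g1", gstart = 1000L) {
  len <- l5 + lc + l3
  transcript_model(tid, gid, "chr1", strand,
                   data.frame(start = gstart, end = gstart + len),
                   cds_start_tx = l5, cds_end_tx = l5 + lc)
}

# Random multi-exon model for coordinate round-trip properties.
random_tm <- function(seed) {
  withr::with_seed(seed, {
    n_exons <- sample(1:4, 1)
    widths <- sample(20:80, n_exons, replace = TRUE)
    gaps <- sample(50:200, n_exons, replace = TRUE)
    starts <- 500L + cumsum(c(0L, head(widths, -1) + head(gaps, -1)))
    blocks <- data.frame(start = starts, end = starts + widths)
    strand <- sample(c("+", "-"), 1)
    exons <- if (strand == "+") blocks else blocks[rev(seq_len(n_exons)), ]
    len <- sum(widths)
    transcript_model("txr", "gr", "chrR", strand, exons,
                     cds_start_tx = max(1L, len %/% 4L),
                     cds_end_tx = len - max(1L, len %/% 4L))
  })
}

# Small window table built by hand: one transcript, explicit counts.
toy_window_table <- function(ip, input, tid = "tx1", window = 100L, step = 10L) {
  n <- length(ip)
  windows <- data.frame(transcript_id = tid,
                        start = seq(0L, by = step, length.out = n),
                        end = seq(0L, by = step, length.out = n) + window)
  counts <- cbind(IP_1 = as.integer(ip), input_1 = as.integer(input))
  samples <- data.frame(sample = c("IP_1", "input_1"),
                        assay = c("IP", "input"),
                        genotype = "WT", replicate = 1L)
  window_table(windows, counts, samples, window = window, step = step)
}

# Overlap of called peaks with planted sites (5-mer interval).
peaks_hit_sites <- function(peaks, sites) {
  vapply(seq_len(nrow(sites)), function(j)
    any(peaks$transcript_id == sites$transcript_id[j] &
          peaks$start < sites$drach_start[j] + 5L &
          peaks$end > sites$drach_start[j]),
    logical(1L))
}

sig_windows_site_overlap <- function(windows, sites) {
  ov <- rep(FALSE, nrow(windows))
  for (j in seq_len(nrow(sites)))
    ov <- ov | (windows$transcript_id == sites$transcript_id[j] &
                  windows$start < sites$drach_start[j] + 5L &
                  windows$end > sites$drach_start[j])
  ov
}
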