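test_that("make_windows tiles the transcript as specified", {
  w <- make_windows(250L)
  expect_equal(nrow(w), 16L)
  expect_equal(w$start[1L], 0L)
  expect_equal(c(w$start[16L], w$end[16L]), c(150L, 250L))
  expect_equal(nrow(make_windows(100L)), 1L)
  expect_equal(as.integer(make_windows(60L)[1L, c("start", "end")]), c(0L, 60L))
  expect_error(make_windows(100L, window = 0L), "positive")
  expect_error(make_windows(100L, step = -1L), "positive")
  # full coverage when length >= window and step <= window
  w2 <- make_windows(537L, window = 100L, step = 10L)
  covered <- sort(unique(unlist(Map(seq, w2$start, w2$end - 1L))))
  expect_equal(covered, 0:536)
})

test_that("exclusion keeps windows above 1/20 of the top in either assay", {
  # top IP 200, top input 100 -> thresholds 10 and 5
  ip <-    c(200L, 4L,  4L, 10L, 9L,  0L)
  input <- c(100L, 3L, 50L,  2L, 5L,  0L)
  wt <- toy_window_table(ip, input)
  kept <- exclusion_filter(wt)
  keep <- attr(kept, "keep")
  expect_false(keep[2L])  # below both thresholds -> excluded
  expect_true(keep[3L])   # fails IP only -> retained (AND rule)
  expect_true(keep[4L])   # exactly 1/20 of top IP: not *less than* -> retained
  expect_true(keep[5L])   # exactly the input threshold -> retained
  expect_false(keep[6L])  # 0,0 below both
  thr <- attr(kept, "thresholds")
  expect_equal(thr$threshold_ip, 10)
  expect_equal(thr$threshold_input, 5)
  # frac = 0 retains everything
  expect_true(all(attr(exclusion_filter(wt, frac = 0), "keep")))
  # "either" mode excludes on a single failing assay
  expect_false(attr(exclusion_filter(wt, mode = "either"), "keep")[3L])
})

test_that("all-zero transcripts are excluded entirely with a warning", {
  wt <- toy_window_table(c(0L, 0L), c(0L, 0L))
  expect_warning(kept <- exclusion_filter(wt), "all-zero")
  expect_equal(nrow(kept$windows), 0L)
})

test_that("window enrichment p equals Fisher and the enumeration oracle", {
  # exhaustive over small margins against the independent lchoose oracle
  for (m1 in c(5L, 9L, 12L)) for (m2 in c(4L, 9L, 11L)) {
    grid <- expand.grid(a = 0:m1, c = 0:m2)
    res <- window_enrichment_test(grid$a, grid$c, m1, m2)
    oracle <- mapply(fisher_tail_bruteforce, grid$a, grid$c, m1, m2)
    expect_equal(res$p_value, unname(oracle), tolerance = 1e-12)
  }
  # spot-check against stats::fisher.test at realistic library scale
  for (case in list(c(12L, 3L, 40L, 40L), c(120L, 60L, 5000L, 4000L),
                    c(0L, 10L, 1000L, 1000L))) {
    ft <- stats::fisher.test(matrix(c(case[1L], case[3L] - case[1L],
                                      case[2L], case[4L] - case[2L]),
                                    2L, byrow = TRUE),
                             alternative = "greater")
    expect_equal(window_enrichment_test(case[1L], case[2L], case[3L], case[4L])$p_value,
                 ft$p.value, tolerance = 1e-10)
  }
})

test_that("enrichment statistic has the documented edge behavior", {
  expect_equal(window_enrichment_test(10L, 10L, 1000L, 1000L)$log2_enrichment, 0)
  expect_equal(window_enrichment_test(0L, 0L, 1000L, 1000L)$p_value, 1)
  expect_error(window_enrichment_test(10L, 1L, 5L, 100L), "exceeds")
  expect_error(window_enrichment_test(-1L, 1L, 5L, 100L), "non-negative")
})

test_that("bh_adjust reproduces the hand-computed step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5L)), rep(0.2, 5L))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.9)),
               c(0.04, 0.04, 0.16 / 3, 0.9))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- runif(50L)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("merge_windows merges overlapping/bookended significant windows", {
  tw <- data.frame(transcript_id = "t1",
                   start = c(0L, 10L, 200L),
                   end = c(100L, 110L, 300L),
                   p_value = c(0.001, 0.0005, 0.002),
                   q_value = c(0.01, 0.01, 0.02),
                   log2_enrichment = c(1, 2, 1.5))
  pk <- merge_windows(tw)
  expect_equal(nrow(pk), 2L)
  expect_equal(c(pk$start[1L], pk$end[1L]), c(0L, 110L))
  expect_equal(pk$summit[1L], 60L)       # midpoint of the min-p window [10,110)
  expect_equal(pk$p_value[1L], 0.0005)
  expect_equal(pk$n_windows, c(2L, 1L))
  # three consecutive windows, min-p in the middle -> middle midpoint
  tw3 <- data.frame(transcript_id = "t1", start = c(0L, 10L, 20L),
                    end = c(100L, 110L, 120L),
                    p_value = c(0.01, 0.0001, 0.01),
                    q_value = rep(0.01, 3L), log2_enrichment = 1)
  expect_equal(merge_windows(tw3)$summit, 60L)
  # q above threshold -> dropped
  expect_equal(nrow(merge_windows(tw, q_threshold = 0.005)), 0L)
})

test_that("call_peaks recovers a deeply covered planted site as one peak", {
  cfg <- sim_config(n_genes = 1L, n_targets = 1L, mean_depth = 100,
                    seed = 301L)
  sim <- simulate_transcriptome(cfg)
  wt <- simulate_merip_counts(sim, cfg, genotypes = "WT")
  pk <- call_peaks(wt)
  site <- sim$truth$sites[1L, ]
  hit <- pk$transcript_id == site$transcript_id &
    pk$start < site$drach_start + 5L & pk$end > site$drach_start
  expect_equal(sum(hit), 1L)
  expect_equal(nrow(pk), 1L)
  prov <- attr(pk, "provenance")
  expect_gt(prov$n_tested, 0L)
  expect_equal(prov$n_windows, nrow(wt$windows))
})

test_that("an all-insignificant table yields an empty peak set", {
  wt <- toy_window_table(c(30L, 31L, 29L), c(30L, 29L, 31L))
  pk <- call_peaks(wt)
  expect_equal(nrow(pk), 0L)
})

test_that("peak calls are invariant to window order and column order", {
  cfg <- sim_config(n_genes = 5L, n_targets = 1L, seed = 302L)
  sim <- simulate_transcriptome(cfg)
  wt <- simulate_merip_counts(sim, cfg, genotypes = "WT")
  pk1 <- call_peaks(wt)
  perm <- withr::with_seed(1L, sample(nrow(wt$windows)))
  wt2 <- window_table(wt$windows[perm, ], wt$counts[perm, ],
                      wt$samples[rev(seq_len(nrow(wt$samples))), ],
                      window = wt$window, step = wt$step)
  pk2 <- call_peaks(wt2)
  attr(pk1, "provenance") <- attr(pk2, "provenance") <- NULL
  attr(pk1, "tested_windows") <- attr(pk2, "tested_windows") <- NULL
  expect_equal(pk1, pk2)
})

test_that("null simulations keep the peak-level false discovery proportion low", {
  # no true enrichment anywhere: any called peak is a false discovery
  fdp <- vapply(1:200, function(r) {
    cfg <- sim_config(n_genes = 15L, n_targets = 1L, site_enrichment = 1,
                      ko_effect = 1, seed = 80000L + r)
    sim <- simulate_transcriptome(cfg)
    wt <- simulate_merip_counts(sim, cfg, genotypes = "WT")
    pk <- suppressWarnings(call_peaks(wt, q_threshold = 0.05))
    if (nrow(pk) > 0L) 1 else 0
  }, numeric(1L))
  expect_lte(mean(fdp), 1.5 * 0.05)
})

test_that("differential methylation is null on identical genotypes and antisymmetric", {
  cfg <- sim_config(n_genes = 4L, n_targets = 2L, seed = 303L)
  sim <- simulate_transcriptome(cfg)
  wt <- simulate_merip_counts(sim, cfg)
  pk <- call_peaks(wt)
  # identical counts in both genotypes -> exactly zero log2 ratio
  wt_dup <- wt
  ko_cols <- wt$samples$genotype == "KO"
  wt_dup$counts[, ko_cols] <- wt$counts[, !ko_cols]
  dm0 <- differential_methylation(pk, wt_dup)
  expect_equal(dm0$log2_ratio, rep(0, nrow(dm0)))
  # label swap negates ratios exactly and keeps p-values
  dm <- differential_methylation(pk, wt)
  dm_sw <- differential_methylation(pk, wt, test = "WT", reference = "KO")
  expect_equal(dm_sw$log2_ratio, -dm$log2_ratio)
  expect_equal(dm_sw$dm_p_value, dm$dm_p_value, tolerance = 1e-12)
  expect_error(differential_methylation(pk, wt, test = "HET"), "absent")
})
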