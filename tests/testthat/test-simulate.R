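test_that("sim_config validates its inputs", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(n_genes = 0L, seed = 1L), "positive integer")
  expect_error(sim_config(site_enrichment = -1, seed = 1L), "positive")
  expect_error(sim_config(decay_timepoints = c(2, 4), seed = 1L), "include 0")
  expect_error(sim_config(n_targets = 99L, n_genes = 5L, seed = 1L), "targets")
  expect_error(sim_config(seed = 2^31), "2\\^31")
  expect_error(sim_config(n_sites = 200L, seed = 1L), "cannot fit")
})

test_that("the transcriptome generator is deterministic and plants DRACH 5-mers", {
  cfg <- sim_config(n_genes = 10L, n_targets = 2L, n_sites = 2L, seed = 601L)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$truth, b$truth)
  for (j in seq_len(nrow(a$truth$sites))) {
    s <- a$truth$sites[j, ]
    mer <- as.character(Biostrings::subseq(a$sequences[[s$transcript_id]],
                                           s$drach_start + 1L, s$drach_start + 5L))
    expect_match(mer, "^[AGT][AG]AC[ACT]$")
    tm <- a$models[[s$transcript_id]]
    expect_true(s$position >= 0 && s$position < tm$length_tx)
  }
  # segment lengths respect the configured ranges
  g <- a$truth$genes
  expect_true(all(g$cds_start_tx >= cfg$utr5_range[1L] &
                    g$cds_start_tx <= cfg$utr5_range[2L]))
})

test_that("site placement matches the configured stop-proximal fraction", {
  cfg <- sim_config(n_genes = 300L, n_targets = 5L, seed = 602L)
  sim <- simulate_transcriptome(cfg)
  g <- sim$truth$genes
  s <- sim$truth$sites
  stop_pos <- g$cds_end_tx[match(s$gene_id, g$gene_id)]
  near <- abs(s$position - stop_pos) <= cfg$stop_flank
  # 80% planted near the stop, plus whatever uniform background lands there:
  # observed fraction must be at least the lower binomial band of 0.8
  expect_gte(mean(near), qbinom(0.025, nrow(s), 0.8) / nrow(s))
  # with p = 1, every site is stop-proximal
  cfg1 <- sim_config(n_genes = 40L, n_targets = 2L, p_stop_proximal = 1,
                     seed = 603L)
  sim1 <- simulate_transcriptome(cfg1)
  g1 <- sim1$truth$genes; s1 <- sim1$truth$sites
  expect_true(all(abs(s1$position - g1$cds_end_tx[match(s1$gene_id, g1$gene_id)])
                  <= cfg1$stop_flank))
})

test_that("unit site enrichment gives equal IP and input means", {
  cfg <- sim_config(n_genes = 30L, n_targets = 2L, site_enrichment = 1,
                    ko_effect = 1, seed = 604L)
  sim <- simulate_transcriptome(cfg)
  wt <- simulate_merip_counts(sim, cfg, genotypes = "WT")
  ip <- wt$counts[, wt$samples$assay == "IP", drop = FALSE]
  input <- wt$counts[, wt$samples$assay == "input", drop = FALSE]
  expect_equal(mean(ip) / mean(input), 1, tolerance = 0.02)
})

test_that("zero dispersion yields Poisson-like window counts", {
  cfg <- sim_config(n_genes = 200L, n_targets = 2L, nb_dispersion = 0,
                    site_enrichment = 1, ko_effect = 1, expr_sdlog = 0,
                    seed = 605L)
  sim <- simulate_transcriptome(cfg)
  wt <- simulate_merip_counts(sim, cfg, genotypes = "WT")
  full <- wt$windows$end - wt$windows$start == cfg$window
  x <- as.vector(wt$counts[full, ])   # iid Poisson(mean_depth) draws
  expect_gt(length(x), 1e5)
  expect_equal(var(x) / mean(x), 1, tolerance = 0.03)
})

test_that("the knockout doubles IP coverage at target sites", {
  cfg0 <- sim_config(n_genes = 2L, n_targets = 2L, seed = 0L)
  sim <- simulate_transcriptome(cfg0)
  ratios <- vapply(1:200, function(s) {
    cfg <- cfg0; cfg$seed <- 70000L + s
    wt <- simulate_merip_counts(sim, cfg)
    ov <- attr(wt, "site_windows")
    ip_ko <- sum(wt$counts[ov, wt$samples$assay == "IP" & wt$samples$genotype == "KO"])
    ip_wt <- sum(wt$counts[ov, wt$samples$assay == "IP" & wt$samples$genotype == "WT"])
    ip_ko / ip_wt
  }, numeric(1L))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 2), 3 * se + 1e-3)
})

test_that("decay simulation honors its closed-form expectations", {
  cfg <- sim_config(n_genes = 3L, n_targets = 1L, decay_cv = 0, seed = 606L)
  sim <- simulate_transcriptome(cfg)
  d <- normalize_decay(simulate_decay(sim, cfg))
  expect_equal(d$fraction[d$time_h == 0], rep(1, sum(d$time_h == 0)))
  # noise-free: non-target half-life 2 h means fraction 0.5 at t = 2
  nt <- d[d$gene == d$gene[1L] & !sim$truth$genes$target[1L], ]
  g_nt <- sim$truth$genes$gene_id[!sim$truth$genes$target][1L]
  f2 <- d$fraction[d$gene == g_nt & d$time_h == 2]
  expect_equal(f2, rep(0.5, length(f2)), tolerance = 1e-12)
})

test_that("qpcr simulation encodes fold changes as Ct shifts", {
  cfg <- sim_config(n_genes = 4L, n_targets = 2L, qpcr_sd = 0, seed = 607L)
  sim <- simulate_transcriptome(cfg)
  ct <- simulate_qpcr(sim, cfg)
  tgt <- sim$truth$genes$gene_id[sim$truth$genes$target][1L]
  d <- ct[ct$gene == tgt, ]
  # 4-fold planted abundance -> Ct lower by exactly 2 cycles, references equal
  expect_equal(mean(d$ct_target[d$group == "WT"]) - mean(d$ct_target[d$group == "KO"]),
               log2(cfg$qpcr_fold), tolerance = 1e-12)
  expect_equal(mean(d$ct_ref[d$group == "WT"]), mean(d$ct_ref[d$group == "KO"]),
               tolerance = 1e-12)
})

test_that("expression simulation is reproducible with planted labels", {
  cfg <- sim_config(de_n_genes = 300L, seed = 608L)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$counts, b$counts)
  expect_equal(table(a$truth$label)[["up"]], 15L)
  expect_equal(table(a$truth$label)[["down"]], 15L)
  # null config -> DEG calls at the nominal false-positive rate
  cfg0 <- sim_config(de_frac = 0, de_n_genes = 2000L, seed = 609L)
  e <- simulate_expression(cfg0)
  res <- classify_deg(de_test(e$counts, e$conditions))
  # p <= 0.05 AND |lfc| >= 1 is rarer than p <= 0.05 alone
  expect_lt(mean(res$class != "ns"), 0.05)
})
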