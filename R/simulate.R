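# Synthetic-data generator: transcriptomes with planted DRACH methylation
# sites, MeRIP IP/input negative-binomial window counts with localized
# enrichment (raised further at target genes in the knockout), actinomycin-D
# decay time courses with genotype-specific half-lives, qPCR Ct tables, and
# expression count matrices with planted up/down genes. Every generator is a
# pure function of (config, seed): stage k draws under seed + k, so the
# stages are reproducible independently.

DRACH_ALPHABET <- list(D = c("A", "G", "T"), R = c("A", "G"), A = "A",
                       C = "C", H = c("A", "C", "T"))

#' Simulation configuration
#'
#' Defaults define the study conditions emulated throughout the test suite:
#' 50 genes, one planted DRACH site per gene (80% of sites stop-codon
#' proximal), 4-fold IP enrichment at sites, a knockout that doubles site
#' methylation at 5 designated target genes, mean sequencing depth of 30
#' reads per window per library drawn as Poisson sequencing-sampling noise
#' (`nb_dispersion = 0`; positive values add negative-binomial biological
#' overdispersion, with consequences for Fisher-test calibration discussed
#' in the methods vignette), two replicates per genotype x assay, decay
#' timepoints 0/2/4/6 h with CV 0.1
#' and 5 replicates (non-target half-life 2 h; targets 4 h in wild type
#' versus 2 h in knockout, i.e. destabilized upon demethylase loss), and an
#' expression experiment with 10% planted DE genes at |log2FC| = 2.
#'
#' @param n_genes number of genes
#' @param utr5_range,cds_range,utr3_range segment length ranges in nt
#' @param n_sites planted methylation sites per gene
#' @param p_stop_proximal probability a site is drawn near the stop codon
#' @param stop_flank half-width (nt) of the stop-proximal placement window
#' @param site_enrichment IP mean multiplier at site-overlapping windows
#' @param ko_effect extra fold applied at target-gene sites in the knockout
#' @param n_targets number of target genes carrying the knockout effect
#' @param mean_depth expected input reads per full-width window per library
#' @param nb_dispersion negative-binomial dispersion of window counts
#'   (0 gives Poisson)
#' @param replicates replicates per genotype x assay
#' @param expr_sdlog log-normal sd of per-gene expression factors
#' @param window,step scan parameters used when deriving windows
#' @param decay_timepoints chase timepoints in hours (must include 0)
#' @param halflife non-target half-life (h), both genotypes
#' @param target_halflife_wt,target_halflife_ko target half-lives (h)
#' @param decay_cv lognormal coefficient of variation of decay measurements
#' @param decay_replicates replicates per genotype in the decay assay
#' @param qpcr_baseline,qpcr_ref_ct,qpcr_sd,qpcr_replicates,qpcr_fold qPCR
#'   simulation parameters; `qpcr_fold` is the knockout/wild-type abundance
#'   fold planted at target genes
#' @param de_n_genes,de_frac,de_log2fc,de_dispersion,de_meanlog,de_sdlog,de_replicates
#'   expression-matrix simulation parameters
#' @param seed mandatory RNG seed (integer below 2^31 - 16)
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_genes = 50L,
                       utr5_range = c(100L, 300L),
                       cds_range = c(300L, 1500L),
                       utr3_range = c(200L, 600L),
                       n_sites = 1L,
                       p_stop_proximal = 0.8,
                       stop_flank = 100L,
                       site_enrichment = 4,
                       ko_effect = 2,
                       n_targets = 5L,
                       mean_depth = 30,
                       nb_dispersion = 0,
                       replicates = 2L,
                       expr_sdlog = 0.5,
                       window = 100L,
                       step = 10L,
                       decay_timepoints = c(0, 2, 4, 6),
                       halflife = 2,
                       target_halflife_wt = 4,
                       target_halflife_ko = 2,
                       decay_cv = 0.1,
                       decay_replicates = 5L,
                       qpcr_baseline = 22,
                       qpcr_ref_ct = 15,
                       qpcr_sd = 0.1,
                       qpcr_replicates = 5L,
                       qpcr_fold = 4,
                       de_n_genes = NULL,
                       de_frac = 0.1,
                       de_log2fc = 2,
                       de_dispersion = 0.05,
                       de_meanlog = log(200),
                       de_sdlog = 1,
                       de_replicates = 3L,
                       seed) {
  if (missing(seed)) stopf("sim_config: seed is mandatory")
  if (!is.numeric(seed) || seed != floor(seed) || abs(seed) >= 2^31 - 16)
    stopf("seed must be an integer below 2^31 - 16 in magnitude")
  cfg <- as.list(environment())
  cfg$de_n_genes <- cfg$de_n_genes %||% n_genes
  for (f in c("n_genes", "n_sites", "replicates", "decay_replicates",
              "qpcr_replicates", "de_replicates", "de_n_genes"))
    if (!is_count(cfg[[f]])) stopf("sim_config: %s must be a positive integer", f)
  for (f in c("site_enrichment", "ko_effect", "mean_depth", "halflife",
              "target_halflife_wt", "target_halflife_ko", "qpcr_fold"))
    if (cfg[[f]] <= 0) stopf("sim_config: %s must be positive", f)
  if (cfg$nb_dispersion < 0 || cfg$de_dispersion < 0)
    stopf("sim_config: dispersions must be >= 0")
  if (!0 %in% cfg$decay_timepoints) stopf("sim_config: decay timepoints must include 0")
  if (cfg$n_targets > cfg$n_genes) stopf("sim_config: more targets than genes")
  for (f in c("utr5_range", "cds_range", "utr3_range"))
    if (length(cfg[[f]]) != 2L || any(cfg[[f]] < 1) || cfg[[f]][1L] > cfg[[f]][2L])
      stopf("sim_config: %s must be an increasing positive length range", f)
  min_len <- cfg$utr5_range[1L] + cfg$cds_range[1L] + cfg$utr3_range[1L]
  if (cfg$n_sites * 5L > min_len)
    stopf("sim_config: %d sites cannot fit in transcripts of length >= %d",
          cfg$n_sites, min_len)
  structure(cfg, class = "sim_config")
}

sample_drach <- function(n) {
  vapply(seq_len(n), function(i)
    paste0(vapply(DRACH_ALPHABET, function(ch)
      if (length(ch) == 1L) ch else sample(ch, 1L), character(1L)), collapse = ""),
    character(1L))
}

#' Simulate a transcriptome with planted DRACH sites
#'
#' Draws, per gene, segment lengths uniformly within the configured ranges,
#' a random 1-3-exon structure on alternating strands, a random sequence,
#' and `n_sites` methylation-site positions (the methylated A of a DRACH
#' 5-mer written into the sequence). With probability `p_stop_proximal` a
#' site is placed uniformly within `stop_flank` nt of the stop codon,
#' otherwise uniformly along the transcript.
#'
#' @param cfg a [sim_config()]
#' @return list of class `sim_transcriptome` with `models` (named list of
#'   `transcript_model`), `sequences` (`DNAStringSet`, transcript
#'   orientation), and `truth` (list with `genes` and `sites` data.frames)
#' @export
simulate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_genes
    targets <- sort(sample(n, cfg$n_targets))
    models <- vector("list", n)
    seqs <- character(n)
    genes <- vector("list", n)
    sites <- vector("list", n)
    offset <- 1000L
    for (i in seq_len(n)) {
      gid <- sprintf("gene%03d", i)
      tid <- sprintf("tx%03d", i)
      l5 <- sample(cfg$utr5_range[1L]:cfg$utr5_range[2L], 1L)
      lc <- sample(cfg$cds_range[1L]:cfg$cds_range[2L], 1L)
      l3 <- sample(cfg$utr3_range[1L]:cfg$utr3_range[2L], 1L)
      len <- l5 + lc + l3
      strand <- if (i %% 2L == 0L) "-" else "+"
      n_exons <- sample(1:3, 1L)
      brk <- if (n_exons > 1L) sort(sample(seq_len(len - 1L), n_exons - 1L)) else integer(0)
      widths <- diff(c(0L, brk, len))
      gstarts <- offset + cumsum(c(0L, head(widths, -1L) + 100L))
      blocks <- data.frame(start = gstarts, end = gstarts + widths)
      offset <- max(blocks$end) + 1000L
      exons <- if (strand == "+") blocks else blocks[rev(seq_len(n_exons)), , drop = FALSE]
      tm <- transcript_model(tid, gid, "chrS", strand, exons,
                             cds_start_tx = l5, cds_end_tx = l5 + lc)
      sq <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      # site positions: A of the DRACH 5-mer [pos-2, pos+3); keep the 5-mers
      # disjoint so planted motifs never clobber each other
      pos <- integer(0)
      tries <- 0L
      while (length(pos) < cfg$n_sites) {
        stop_prox <- runif(1) < cfg$p_stop_proximal
        cand <- if (stop_prox)
          sample(max(2L, tm$cds_end_tx - cfg$stop_flank):
                   min(len - 3L, tm$cds_end_tx + cfg$stop_flank - 1L), 1L)
        else sample(2L:(len - 3L), 1L)
        if (all(abs(cand - pos) >= 5L)) pos <- c(pos, cand)
        tries <- tries + 1L
        if (tries > 1000L)
          stopf("could not place %d disjoint sites on transcript '%s'", cfg$n_sites, tid)
      }
      pos <- sort(pos)
      for (p in pos) sq[(p - 1L):(p + 3L)] <- strsplit(sample_drach(1L), "")[[1L]]
      models[[i]] <- tm
      seqs[i] <- paste0(sq, collapse = "")
      genes[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                               length_tx = len, cds_start_tx = l5,
                               cds_end_tx = l5 + lc,
                               expr_factor = rlnorm(1L, 0, cfg$expr_sdlog),
                               target = i %in% targets,
                               halflife_wt = if (i %in% targets) cfg$target_halflife_wt else cfg$halflife,
                               halflife_ko = if (i %in% targets) cfg$target_halflife_ko else cfg$halflife,
                               stringsAsFactors = FALSE)
      sites[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                               position = pos, drach_start = pos - 2L,
                               stringsAsFactors = FALSE)
    }
    models <- setNames(models, vapply(models, `[[`, character(1L), "transcript_id"))
    sequences <- Biostrings::DNAStringSet(setNames(seqs, names(models)))
    structure(list(models = models, sequences = sequences,
                   truth = list(genes = do.call(rbind, genes),
                                sites = do.call(rbind, sites))),
              class = "sim_transcriptome")
  })
}

site_window_overlap <- function(windows, sites) {
  ov <- rep(FALSE, nrow(windows))
  for (j in seq_len(nrow(sites))) {
    hit <- windows$transcript_id == sites$transcript_id[j] &
      windows$start < sites$drach_start[j] + 5L &
      windows$end > sites$drach_start[j]
    ov <- ov | hit
  }
  ov
}

#' Simulate MeRIP IP/input window counts
#'
#' Input window means are proportional to gene expression times window
#' width; IP means equal the input mean times `site_enrichment` on windows
#' overlapping a planted site (times `ko_effect` additionally at target
#' genes in the knockout) and times 1 elsewhere. Counts are drawn
#' NB(mean, dispersion); dispersion 0 gives Poisson draws.
#'
#' @param sim a `sim_transcriptome` from [simulate_transcriptome()]
#' @param cfg the same [sim_config()]
#' @param genotypes genotype labels to simulate (default `c("WT","KO")`)
#' @return a [window_table()] over all transcripts; attribute `site_windows`
#'   flags windows overlapping a planted site
#' @export
simulate_merip_counts <- function(sim, cfg, genotypes = c("WT", "KO")) {
  stopifnot(inherits(sim, "sim_transcriptome"), inherits(cfg, "sim_config"))
  windows <- do.call(rbind, lapply(sim$models, make_windows,
                                   window = cfg$window, step = cfg$step))
  rownames(windows) <- NULL
  ov <- site_window_overlap(windows, sim$truth$sites)
  expr <- setNames(sim$truth$genes$expr_factor, sim$truth$genes$transcript_id)
  base_mu <- cfg$mean_depth * expr[windows$transcript_id] *
    (windows$end - windows$start) / cfg$window
  target_tx <- sim$truth$genes$transcript_id[sim$truth$genes$target]
  samples <- expand.grid(replicate = seq_len(cfg$replicates),
                         assay = c("input", "IP"), genotype = genotypes,
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_%d", samples$genotype, samples$assay,
                            samples$replicate)
  samples <- samples[, c("sample", "assay", "genotype", "replicate")]
  counts <- withr::with_seed(cfg$seed + 1L, {
    m <- matrix(0L, nrow(windows), nrow(samples),
                dimnames = list(NULL, samples$sample))
    for (j in seq_len(nrow(samples))) {
      enrich <- rep(1, nrow(windows))
      if (samples$assay[j] == "IP") {
        enrich[ov] <- cfg$site_enrichment
        if (samples$genotype[j] == "KO") {
          tko <- ov & windows$transcript_id %in% target_tx
          enrich[tko] <- cfg$site_enrichment * cfg$ko_effect
        }
      }
      mu <- base_mu * enrich
      m[, j] <- if (cfg$nb_dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    }
    m
  })
  wt <- window_table(windows, counts, samples, window = cfg$window, step = cfg$step)
  attr(wt, "site_windows") <- ov
  wt
}

lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an actinomycin-D decay time course
#'
#' Target abundance decays as `A0 * 2^(-t / halflife)` with multiplicative
#' lognormal noise of the configured CV; the reference species (an 18S
#' rRNA stand-in, untouched by transcription inhibition on this time scale)
#' is constant in expectation.
#'
#' @param sim a `sim_transcriptome`
#' @param cfg the same [sim_config()]
#' @return data.frame `gene`, `genotype`, `replicate`, `time_h`, `value`,
#'   `reference_value`; feed to [normalize_decay()]
#' @export
simulate_decay <- function(sim, cfg) {
  stopifnot(inherits(sim, "sim_transcriptome"), inherits(cfg, "sim_config"))
  g <- sim$truth$genes
  grid <- expand.grid(gene = g$gene_id, genotype = c("WT", "KO"),
                      replicate = seq_len(cfg$decay_replicates),
                      time_h = sort(cfg$decay_timepoints),
                      stringsAsFactors = FALSE)
  hl <- ifelse(grid$genotype == "WT",
               g$halflife_wt[match(grid$gene, g$gene_id)],
               g$halflife_ko[match(grid$gene, g$gene_id)])
  a0 <- 100 * g$expr_factor[match(grid$gene, g$gene_id)]
  withr::with_seed(cfg$seed + 2L, {
    grid$value <- a0 * 2^(-grid$time_h / hl) * lnorm_noise(nrow(grid), cfg$decay_cv)
    grid$reference_value <- 1000 * lnorm_noise(nrow(grid), cfg$decay_cv)
  })
  grid
}

#' Simulate a qPCR Ct table
#'
#' `Ct = baseline - log2(relative abundance) + N(0, sd)`; target genes carry
#' a `qpcr_fold` abundance change in the knockout, the reference gene is
#' constant across groups in expectation.
#'
#' @param sim a `sim_transcriptome`
#' @param cfg the same [sim_config()]
#' @return data.frame `gene`, `group`, `replicate`, `ct_target`, `ct_ref`
#' @export
simulate_qpcr <- function(sim, cfg) {
  stopifnot(inherits(sim, "sim_transcriptome"), inherits(cfg, "sim_config"))
  g <- sim$truth$genes
  grid <- expand.grid(gene = g$gene_id, group = c("WT", "KO"),
                      replicate = seq_len(cfg$qpcr_replicates),
                      stringsAsFactors = FALSE)
  fold <- ifelse(grid$group == "KO" & g$target[match(grid$gene, g$gene_id)],
                 cfg$qpcr_fold, 1)
  abund <- g$expr_factor[match(grid$gene, g$gene_id)] * fold
  withr::with_seed(cfg$seed + 3L, {
    grid$ct_target <- cfg$qpcr_baseline - log2(abund) + rnorm(nrow(grid), 0, cfg$qpcr_sd)
    grid$ct_ref <- cfg$qpcr_ref_ct + rnorm(nrow(grid), 0, cfg$qpcr_sd)
  })
  grid
}

#' Simulate an expression count matrix with planted DE genes
#'
#' Negative-binomial counts for two conditions; a configured fraction of
#' genes carries a planted log2 fold change (half up, half down), the rest
#' are null.
#'
#' @param cfg a [sim_config()]; fields `de_*` control this generator
#' @param n_genes optional override of `cfg$de_n_genes`
#' @return list with `counts` (gene x sample), `conditions` (factor with
#'   levels WT, KO), `lengths` (nt), and `truth` (data.frame `gene`,
#'   `label`, `log2fc`)
#' @export
simulate_expression <- function(cfg, n_genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- as.integer(n_genes %||% cfg$de_n_genes)
  r <- cfg$de_replicates
  withr::with_seed(cfg$seed + 4L, {
    n_de <- round(cfg$de_frac * n)
    lfc <- rep(0, n)
    if (n_de > 0) {
      de_idx <- sample(n, n_de)
      lfc[de_idx] <- rep_len(c(cfg$de_log2fc, -cfg$de_log2fc), n_de)
    }
    base <- rlnorm(n, cfg$de_meanlog, cfg$de_sdlog)
    lengths <- sample(500:3000, n, replace = TRUE)
    mu <- cbind(matrix(rep(base, r), n, r),
                matrix(rep(base * 2^lfc, r), n, r))
    draws <- if (cfg$de_dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / cfg$de_dispersion)
    counts <- matrix(draws, n,
                     dimnames = list(sprintf("g%05d", seq_len(n)),
                                     c(sprintf("WT_%d", seq_len(r)),
                                       sprintf("KO_%d", seq_len(r)))))
    label <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "null"))
    list(counts = counts,
         conditions = factor(rep(c("WT", "KO"), each = r), levels = c("WT", "KO")),
         lengths = lengths,
         truth = data.frame(gene = rownames(counts), label = label,
                            log2fc = lfc, stringsAsFactors = FALSE))
  })
}
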