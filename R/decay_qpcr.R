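# Actinomycin-D decay analysis and qPCR relative quantification: target
# abundance is normalized to a reference species (18S rRNA in the assay this
# models), residual fractions are normalized to t = 0 h, half-lives come from
# a log-linear least-squares fit, and genotypes are compared per timepoint
# (Welch t) and on the half-life difference (bootstrap CI).

#' Delta-delta-Ct relative expression
#'
#' `2^-((ct_target - ct_ref) - (calibrator_target - calibrator_ref))`: the
#' fold change of the target, normalized to a reference gene (e.g. GAPDH),
#' relative to a calibrator sample. One extra target cycle halves the result.
#'
#' @param ct_target,ct_ref sample Ct values (target and reference gene)
#' @param calibrator_target,calibrator_ref calibrator Ct values
#' @return relative expression (vectorized)
#' @export
ddct <- function(ct_target, ct_ref, calibrator_target, calibrator_ref) {
  vals <- c(ct_target, ct_ref, calibrator_target, calibrator_ref)
  if (any(!is.finite(vals))) stopf("ddct: all Ct values must be finite")
  2^-((ct_target - ct_ref) - (calibrator_target - calibrator_ref))
}

#' Normalize a decay time course to residual fractions
#'
#' Within each (gene, genotype, replicate) series the target abundance is
#' divided by the reference species, then by the t = 0 ratio, so that the
#' residual fraction at t = 0 is 1 by construction and multiplicative batch
#' effects on the reference cancel.
#'
#' @param series data.frame with columns `gene`, `genotype`, `replicate`,
#'   `time_h`, `value`, `reference_value`
#' @return the input with an added `fraction` column, class `decay_series`
#' @export
normalize_decay <- function(series) {
  need <- c("gene", "genotype", "replicate", "time_h", "value", "reference_value")
  if (!all(need %in% names(series)))
    stopf("decay series must have columns: %s", paste(need, collapse = ", "))
  if (any(series$reference_value <= 0)) stopf("reference abundance must be positive")
  key <- interaction(series$gene, series$genotype, series$replicate, drop = TRUE)
  ratio <- series$value / series$reference_value
  series$fraction <- NA_real_
  for (k in levels(key)) {
    idx <- which(key == k)
    at0 <- idx[series$time_h[idx] == 0]
    if (length(at0) != 1L)
      stopf("series '%s' must contain exactly one t = 0 measurement", k)
    series$fraction[idx] <- ratio[idx] / ratio[at0]
  }
  class(series) <- c("decay_series", "data.frame")
  series
}

#' Fit an exponential decay half-life
#'
#' Ordinary least squares of `log(fraction)` on time with a free intercept
#' (replicate series pooled). The decay rate is `k = -slope` (per hour) and
#' `t1/2 = ln(2)/k`. A non-decaying series (slope >= 0) is reported with
#' `k <= 0` and `halflife = Inf` rather than raising an error. Exact on
#' noise-free exponential input.
#'
#' @param series data.frame with columns `time_h` and `fraction`
#'   (e.g. one gene x genotype slice of [normalize_decay()] output)
#' @return object of class `decay_fit`: list with `k`, `halflife`,
#'   `intercept`, `r_squared`, `se_k`, `n`, `decaying`
#' @export
fit_halflife <- function(series) {
  if (!all(c("time_h", "fraction") %in% names(series)))
    stopf("fit_halflife needs columns time_h and fraction")
  if (length(unique(series$time_h)) < 3L)
    stopf("fit_halflife requires >= 3 distinct timepoints")
  if (any(series$fraction <= 0)) stopf("fractions must be positive for the log-linear fit")
  fit <- lm(log(series$fraction) ~ series$time_h)
  slope <- unname(coef(fit)[2L])
  k <- -slope
  sm <- suppressWarnings(summary(fit))  # noise-free input trips "perfect fit"
  structure(list(k = k,
                 halflife = if (k > 0) log(2) / k else Inf,
                 intercept = unname(coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 se_k = unname(sm$coefficients[2L, "Std. Error"]),
                 n = nrow(series), decaying = k > 0),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> k = %.4g /h, t1/2 = %.4g h (se_k %.3g, R2 %.3f, n %d)\n",
              x$k, x$halflife, x$se_k, x$r_squared, x$n))
  invisible(x)
}

#' Compare mRNA stability between genotypes
#'
#' Per post-treatment timepoint, a two-tailed Welch t test on residual
#' fractions between the two groups; globally, the difference of pooled-fit
#' half-lives (test - reference) with a percentile bootstrap confidence
#' interval obtained by resampling replicate series within each group.
#' Negative differences mean the transcript is destabilized in the test
#' group. Swapping the groups negates the difference exactly.
#'
#' @param reference,test data.frames with columns `replicate`, `time_h`,
#'   `fraction` (reference = wild type by convention)
#' @param n_boot bootstrap resamples (default 2000)
#' @param seed RNG seed for the bootstrap
#' @param conf confidence level (default 0.95)
#' @return list with `timepoints` (data.frame `time_h`, `p_value`),
#'   `halflife_ref`, `halflife_test`, `halflife_diff`, `ci` (length-2), and
#'   the bootstrap draws in `boot`
#' @export
compare_stability <- function(reference, test, n_boot = 2000L, seed = 1L,
                              conf = 0.95) {
  for (d in list(reference, test))
    if (!all(c("replicate", "time_h", "fraction") %in% names(d)))
      stopf("compare_stability needs columns replicate, time_h, fraction")
  times <- sort(intersect(unique(reference$time_h), unique(test$time_h)))
  times <- times[times > 0]
  if (length(times) == 0L) stopf("no shared post-treatment timepoints")
  pvals <- vapply(times, function(t0) {
    a <- reference$fraction[reference$time_h == t0]
    b <- test$fraction[test$time_h == t0]
    if (length(a) < 2L || length(b) < 2L)
      stopf("need >= 2 replicates per group at every timepoint")
    t.test(a, b)$p.value
  }, numeric(1L))
  # closed-form OLS slope of log(fraction) on time: same estimator as
  # fit_halflife(), without lm() overhead in the bootstrap loop
  hl <- function(d) {
    t <- d$time_h; y <- log(d$fraction)
    k <- -sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
    if (k > 0) log(2) / k else Inf
  }
  hl_ref <- hl(reference); hl_test <- hl(test)
  reps_ref <- unique(reference$replicate); reps_test <- unique(test$replicate)
  boot <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    rr <- sample(reps_ref, length(reps_ref), replace = TRUE)
    rt <- sample(reps_test, length(reps_test), replace = TRUE)
    dref <- do.call(rbind, lapply(rr, function(r) reference[reference$replicate == r, ]))
    dtst <- do.call(rbind, lapply(rt, function(r) test[test$replicate == r, ]))
    hl(dtst) - hl(dref)
  }, numeric(1L)))
  alpha <- (1 - conf) / 2
  list(timepoints = data.frame(time_h = times, p_value = pvals),
       halflife_ref = hl_ref, halflife_test = hl_test,
       halflife_diff = hl_test - hl_ref,
       ci = unname(quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)),
       boot = boot)
}
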