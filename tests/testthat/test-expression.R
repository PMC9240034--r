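test_that("tpm matches the hand-derived formula and column-sum invariant", {
  m1 <- matrix(5L, 1L, 2L, dimnames = list("g1", c("a", "b")))
  expect_equal(unname(tpm(m1, 1000L)[1L, ]), c(1e6, 1e6))
  m2 <- matrix(c(10L, 10L), 2L, 1L, dimnames = list(c("g1", "g2"), "s"))
  out <- tpm(m2, c(1000L, 2000L))
  expect_equal(unname(out[, 1L]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  rnd <- withr::with_seed(7L, matrix(rpois(60L, 20L), 10L))
  expect_equal(unname(colSums(tpm(rnd, rep(500L, 10L)))), rep(1e6, 6L),
               tolerance = 1e-9)
  zero <- rnd; zero[, 2L] <- 0L
  expect_error(tpm(zero, rep(500L, 10L)), "all-zero")
  expect_error(tpm(rnd, c(0L, rep(1L, 9L))), "positive")
})

test_that("size factors are median-of-ratios and scale-equivariant", {
  m <- withr::with_seed(8L, matrix(rpois(300L, 50L), 100L, 3L))
  expect_equal(unname(size_factors(cbind(m[, 1L], m[, 1L]))), c(1, 1))
  doubled <- cbind(s1 = m[, 1L], s2 = 2L * m[, 1L])
  sf <- size_factors(doubled)
  expect_equal(unname(sf[2L] / sf[1L]), 2, tolerance = 1e-9)
  perm <- withr::with_seed(9L, sample(nrow(m)))
  expect_equal(unname(size_factors(m)), unname(size_factors(m[perm, ])))
  expect_error(size_factors(diag(0L, 3L)), "nonzero")
})

test_that("de_test agrees with stats::t.test gene by gene", {
  m <- withr::with_seed(10L, matrix(rpois(48L, 60L), 8L, 6L,
                                    dimnames = list(sprintf("g%d", 1:8), NULL)))
  cond <- factor(rep(c("WT", "KO"), each = 3L), levels = c("WT", "KO"))
  res <- de_test(m, cond)
  sf <- size_factors(m)
  x <- log2(sweep(m, 2L, sf, "/") + 0.5)
  for (g in 1:8) {
    tt <- stats::t.test(x[g, 4:6], x[g, 1:3])
    expect_equal(res$p_value[g], tt$p.value, tolerance = 1e-10)
    expect_equal(res$log2fc[g], unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
  # identical groups -> zero log2FC
  dup <- cbind(m[, 1:3], m[, 1:3])
  expect_equal(de_test(dup, cond)$log2fc, rep(0, 8L))
  expect_error(de_test(m, rep("a", 6L)), "two conditions")
  expect_error(de_test(m[, 1:3], factor(c("a", "a", "b"))), "2 replicates")
})

test_that("a strong planted effect is recovered and classified up", {
  cfg <- sim_config(de_frac = 0, de_n_genes = 200L, seed = 77L)
  e <- simulate_expression(cfg)
  counts <- e$counts
  counts[1L, e$conditions == "KO"] <- counts[1L, e$conditions == "KO"] * 8L
  res <- classify_deg(de_test(counts, e$conditions))
  expect_equal(res$class[1L], "up")
  expect_equal(res$log2fc[1L], 3, tolerance = 0.3)
})

test_that("DEG classification honors the stated inclusive thresholds", {
  fixture <- data.frame(
    p_value = c(0.04, 0.04, 0.051, 0.05, 0.01, 0.04, 1e-5),
    q_value = c(0.2, 0.2, 0.2, 0.05, 0.2, 0.2, 1e-3),
    log2fc = c(1.0, 0.9, -3, -1, -1.2, -0.99, 5))
  cls <- classify_deg(fixture)$class
  expect_equal(cls, c("up", "ns", "ns", "down", "down", "ns", "up"))
  expect_equal(sum(cls == "up"), 2L)
  expect_equal(sum(cls == "down"), 2L)
  # q-based mode
  expect_equal(classify_deg(fixture, use_adjusted = TRUE)$class[1L], "ns")
})

test_that("gene-set enrichment p equals exhaustive enumeration", {
  withr::with_seed(11L, {
    universe <- sprintf("g%02d", 1:25)
    for (rep in 1:10) {
      deg <- sample(universe, sample(3:12, 1L))
      set <- sample(universe, sample(2:15, 1L))
      res <- geneset_enrichment(deg, universe, list(s = set))
      expect_equal(res$p_value,
                   hyper_tail_bruteforce(length(intersect(deg, set)),
                                         length(set), 25L, length(deg)),
                   tolerance = 1e-12)
    }
  })
  # extreme overlap: the set equal to the gene list is the most enriched
  universe <- sprintf("g%02d", 1:20)
  deg <- universe[1:5]
  sets <- list(exact = deg, other = universe[6:10], half = universe[3:7])
  res <- geneset_enrichment(deg, universe, sets)
  expect_equal(res$set[which.min(res$p_value)], "exact")
  expect_equal(res$p_value[res$set == "other"], 1, tolerance = 1e-9)
  expect_error(geneset_enrichment(deg, character(0), sets), "empty")
  expect_error(geneset_enrichment(c(deg, "zz"), universe, sets), "subset")
})

test_that("null selections give uniform gene-set p-values", {
  universe <- sprintf("g%03d", 1:200)
  set <- universe[1:40]
  pvals <- withr::with_seed(12L, vapply(1:400, function(i)
    geneset_enrichment(sample(universe, 30L), universe, list(s = set))$p_value,
    numeric(1L)))
  # discrete p-values are super-uniform; check the tail is not inflated
  expect_lt(mean(pvals <= 0.05), 0.08)
  expect_gt(mean(pvals), 0.4)
})
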