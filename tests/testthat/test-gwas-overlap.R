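test_that("sentinel pruning enforces the 10 Mb separation greedily by p-value", {
  sig <- function(pos, p) data.frame(trait_id = "T1", chrom = "1",
                                     pos = pos, p = p)
  # 5 Mb apart: the weaker signal is dropped
  s <- prune_signals(sig(c(1e6, 6e6), c(1e-20, 1e-10)))
  expect_equal(s$pos, 1e6)
  # 11 Mb apart: both kept
  s <- prune_signals(sig(c(1e6, 12e6), c(1e-20, 1e-10)))
  expect_equal(sort(s$pos), c(1e6, 12e6))
  # colinear at 0/8/16 Mb with p increasing by position: ends kept
  s <- prune_signals(sig(c(1, 8e6, 16e6), c(1e-30, 1e-20, 1e-10)))
  expect_setequal(s$pos, c(1, 16e6))

  # property check of the greedy rule on random signal sets:
  # kept signals are pairwise separated, and every dropped signal is within
  # the separation of a kept signal with a smaller p-value
  set.seed(2)
  for (rep in 1:20) {
    k <- sample(3:10, 1)
    sg <- data.frame(trait_id = "T1", chrom = "1",
                     pos = sample.int(5e7, k), p = 10^-runif(k, 5, 40))
    kept <- prune_signals(sg, min_separation = 1e7)
    if (nrow(kept) > 1) {
      dmat <- abs(outer(kept$pos, kept$pos, "-"))
      expect_true(all(dmat[upper.tri(dmat)] > 1e7))
    }
    dropped <- sg[!sg$pos %in% kept$pos, , drop = FALSE]
    for (i in seq_len(nrow(dropped))) {
      better <- kept[kept$p < dropped$p[i], , drop = FALSE]
      expect_true(any(abs(better$pos - dropped$pos[i]) <= 1e7))
    }
  }
})

test_that("gene sets around sentinels follow distance and nearest-gene rules", {
  genes <- data.frame(gene_id = c("A", "B", "C"), chrom = "1",
                      start = c(1e6, 4e6, 9e6), end = c(1.2e6, 4.2e6, 9.2e6))
  sig <- data.frame(trait_id = "T1", chrom = "1", pos = 1.1e6, p = 1e-20)

  # gene containing the sentinel: distance 0, in every rule's set
  w <- assign_gene_set(genes, sig, rule = list(type = "within", d = 0))
  expect_true(w$in_set[w$gene_id == "A"])
  nr <- assign_gene_set(genes, sig, rule = list(type = "nearest", k = 1))
  expect_true(nr$in_set[nr$gene_id == "A"])
  expect_equal(sum(nr$in_set), 1)

  # gene 1.5 Mb away is outside a 1 Mb window, one 0.8 Mb away is inside
  sig2 <- data.frame(trait_id = "T1", chrom = "1", pos = 2.7e6, p = 1e-20)
  w2 <- assign_gene_set(genes, sig2, rule = list(type = "within", d = 1e6))
  expect_false(w2$in_set[w2$gene_id == "A"])    # 1.5 Mb from gene A's end
  sig3 <- data.frame(trait_id = "T1", chrom = "1", pos = 3.2e6, p = 1e-20)
  w3 <- assign_gene_set(genes, sig3, rule = list(type = "within", d = 1e6))
  expect_true(w3$in_set[w3$gene_id == "B"])     # 0.8 Mb from gene B's start
  expect_false(w3$in_set[w3$gene_id == "C"])

  # monotone gene-set ladder in d
  set.seed(4)
  genes_r <- data.frame(gene_id = sprintf("G%03d", 1:50), chrom = "1",
                        start = sort(sample.int(1e8, 50)))
  genes_r$end <- genes_r$start + 2e4
  sig_r <- data.frame(trait_id = "T1", chrom = "1",
                      pos = sample.int(1e8, 5), p = 1e-20)
  prev <- NULL
  for (d in c(5e5, 1e6, 5e6, 1e7)) {
    cur <- assign_gene_set(genes_r, sig_r, rule = list(type = "within",
                                                       d = d))$in_set
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }

  # genes on a chromosome with no signals land in the out-set
  genes_x <- rbind(genes, data.frame(gene_id = "X1", chrom = "2",
                                     start = 1e6, end = 1.2e6))
  wx <- assign_gene_set(genes_x, sig, rule = list(type = "within", d = 1e7))
  expect_false(wx$in_set[wx$gene_id == "X1"])
})

test_that("nearest-gene assignment matches construction on a synthetic landscape", {
  genes <- data.frame(gene_id = c("near", "mid", "far"), chrom = "1",
                      start = c(10e6, 20e6, 40e6),
                      end = c(10.02e6, 20.02e6, 40.02e6))
  sig <- data.frame(trait_id = "T1", chrom = "1", pos = 10.5e6, p = 1e-30)
  n1 <- assign_gene_set(genes, sig, rule = list(type = "nearest", k = 1))
  expect_identical(n1$gene_id[n1$in_set], "near")
  n2 <- assign_gene_set(genes, sig, rule = list(type = "nearest", k = 2))
  expect_setequal(n2$gene_id[n2$in_set], c("near", "mid"))
})

test_that("fold enrichment follows (a/b)/(c/d) with explicit undefined flags", {
  expect_equal(enrichment_fold(5, 5, 7, 7)$fold, 1)
  expect_equal(enrichment_fold(2, 8, 10, 980)$fold, 24.5)
  expect_equal(enrichment_fold(0, 8, 10, 980)$fold, 0)
  u <- enrichment_fold(2, 0, 10, 980)
  expect_false(u$defined); expect_true(is.na(u$fold))
  expect_false(enrichment_fold(2, 8, 0, 980)$defined)
})

test_that("Mantel-Haenszel combination reduces, replicates and matches the base-R cross-check", {
  # single stratum: the sample odds ratio
  one <- data.frame(a = 6, b = 14, c = 10, d = 970)
  mh1 <- mantel_haenszel(one)
  expect_equal(mh1$or, (6 * 970) / (14 * 10), tolerance = 1e-12)
  # duplicated strata: same OR
  mh2 <- mantel_haenszel(rbind(one, one))
  expect_equal(mh2$or, mh1$or, tolerance = 1e-12)

  # independent cross-check: stats::mantelhaen.test on random strata
  set.seed(6)
  strata <- gen_enrichment_strata(12, true_or = 3, seed = 6)
  arr <- array(0, dim = c(2, 2, nrow(strata)))
  for (i in seq_len(nrow(strata)))
    arr[, , i] <- matrix(c(strata$a[i], strata$c[i],
                           strata$b[i], strata$d[i]), 2)
  ref <- stats::mantelhaen.test(arr, correct = FALSE)
  mine <- mantel_haenszel(strata)
  expect_equal(mine$chisq, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-8)

  # the combined OR lies between the extreme defined stratum ORs
  ors <- with(strata, (a * d) / (b * c))
  ors <- ors[is.finite(ors) & ors > 0]
  expect_gte(mine$or, min(ors)); expect_lte(mine$or, max(ors))

  expect_error(mantel_haenszel(data.frame(a = 0, b = 0, c = 0, d = 0)),
               "degenerate")
})

test_that("the MH chi-square rejects at the nominal rate with no planted enrichment", {
  set.seed(9)
  rej <- vapply(1:200, function(s) {
    st <- gen_enrichment_strata(20, true_or = 1, seed = s)
    mantel_haenszel(st)$p <= 0.05
  }, logical(1))
  ci <- stats::binom.test(sum(rej), length(rej), p = 0.05,
                          conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})

test_that("chance-overlap expectation reproduces the printed arithmetic and is linear in k", {
  # rounded p_hat reproduces the published-table arithmetic
  e <- expected_by_chance(8865, 311080453, 131077005, round_p = TRUE)
  expect_equal(e$p_hat, 2.85e-5)
  expect_equal(round(e$expected), 3736)
  # unrounded arithmetic lands one lower
  e2 <- expected_by_chance(8865, 311080453, 131077005, round_p = FALSE)
  expect_equal(round(e2$expected), 3735)
  # exact linearity in k at fixed p_hat
  expect_equal(expected_by_chance(10, 1000, 400)$expected,
               2 * expected_by_chance(10, 1000, 200)$expected)
  expect_equal(expected_by_chance(10, 1000, 0)$expected, 0)
})

test_that("2x2 odds ratios and Fisher p-values behave at the boundaries", {
  r <- two_by_two_or(36, 528, 345, 17972)
  expect_equal(signif(r$or, 2), 3.6)
  expect_equal(r$p, stats::fisher.test(matrix(c(36, 528, 345, 17972), 2,
                                              byrow = TRUE))$p.value)
  s <- two_by_two_or(5, 5, 5, 5)
  expect_equal(s$or, 1); expect_equal(s$p, 1)
  # zero denominator: flagged, p from exact enumeration
  u <- two_by_two_or(10, 0, 0, 10)
  expect_false(u$defined)
  # hypergeometric enumeration oracle: only the two diagonal tables are as
  # extreme, each with probability 1/choose(20, 10)
  expect_equal(u$p, 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("trait-disease matching selects the most significant passing correlation", {
  rg <- data.frame(
    trait_id = c("eos", "eos", "eos", "iop", "bmd"),
    disease_id = c("asthma", "copd", "t2d", "glaucoma", "fracture"),
    rg = c(0.37, 0.20, 0.05, 0.66, -0.3),
    p = c(1e-8, 1e-5, 0.4, 1e-12, 0.01))
  m <- match_trait_to_disease(rg, denominator = 357)
  expect_equal(m$disease_id[m$trait_id == "eos"], "asthma")
  expect_equal(m$disease_id[m$trait_id == "iop"], "glaucoma")
  expect_false(m$matched[m$trait_id == "bmd"])   # 0.01 > 0.05/357
})

test_that("the protective screen filters by direction, matching and significance", {
  quant <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    trait_id = c("eos", "eos", "nodir", "eos"),
    effect = c(-0.3, +0.3, -0.5, -0.2),
    p = rep(1e-12, 4))
  beneficial <- data.frame(trait_id = "eos", direction = -1)
  matches <- data.frame(trait_id = "eos", disease_id = "asthma",
                        matched = TRUE)
  disease <- data.frame(
    gene_id = c("g1", "g4"), disease_id = "asthma",
    logor = c(-0.4, +0.2), p = c(1e-5, 1e-5))
  out <- screen_protective(quant, beneficial, matches, disease)
  # g3 excluded at step 1 (no consensus direction), g2 at step 2 (wrong
  # direction), g4 at step 4 (risk-increasing disease effect)
  expect_equal(unname(out$counts),
               c(3, 2, 2, 1))
  expect_equal(out$candidates$gene_id, "g1")
})
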