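test_that("cohort generation is deterministic and respects basic structure", {
  sp <- cohort_spec(n_samples = 300, n_genes = 4, variants_per_gene = 8,
                    seed = 11)
  a <- gen_cohort(sp)
  b <- gen_cohort(sp)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$variants, b$variants)
  expect_identical(a$DP, b$DP)
  expect_identical(a$AD, b$AD)

  expect_true(all(colSums(a$genotypes) >= 1))        # per-variant MAC >= 1
  expect_true(all(a$AD <= a$DP))
  expect_true(all(a$DP >= 0))
  expect_equal(nrow(a$variants), 4 * 8)

  # configuration errors
  expect_error(cohort_spec(n_samples = 1, n_genes = 2,
                           variants_per_gene = 2), "n_samples")
  expect_error(cohort_spec(n_samples = 10, n_genes = 0,
                           variants_per_gene = 2), "n_genes")
})

test_that("a degenerate class mix annotates every variant with that class", {
  mix <- c(synonymous = 0, missense = 0, inframe_indel = 0, start_lost = 0,
           stop_gained = 0, stop_lost = 0, splice_donor = 0,
           splice_acceptor = 0, frameshift = 1)
  co <- gen_cohort(cohort_spec(n_samples = 50, n_genes = 2,
                               variants_per_gene = 10, class_mix = mix,
                               seed = 3))
  expect_true(all(co$variants$class == "frameshift"))
  expect_true(all(co$variants$type == "indel"))
})

test_that("the singleton point mass is realized within binomial noise", {
  # full point mass: every variant must be a singleton
  co1 <- gen_cohort(cohort_spec(n_samples = 1000, n_genes = 4,
                                variants_per_gene = 25,
                                singleton_mass = 1, seed = 5))
  mac <- colSums(co1$genotypes)
  expect_true(all(mac == 1))
  expect_true(all(colSums(co1$genotypes == 1) == 1))

  # default mass: realized fraction within 3 binomial SEs of requested
  m <- 800
  co2 <- gen_cohort(cohort_spec(n_samples = 500, n_genes = 20,
                                variants_per_gene = 40, seed = 6))
  st <- site_stats(co2$genotypes)
  frac <- mean(st$n_carriers == 1 & st$mac == 1)
  p0 <- 0.4686
  se <- sqrt(p0 * (1 - p0) / m)
  expect_lt(abs(frac - p0), 3 * se)
})

test_that("null binary phenotypes hit the requested prevalence and null quantitative traits standardize", {
  co <- default_test_cohort()
  ph <- gen_phenotypes(co, trait_spec("binary", prevalence = 0.10), seed = 2)
  se <- sqrt(0.1 * 0.9 / 400)
  expect_lt(abs(mean(ph$phenotype) - 0.10), 3 * se)

  pq <- gen_phenotypes(co, trait_spec("quantitative"), seed = 2)
  expect_lt(abs(stats::var(pq$phenotype) - 1), 0.25)
  expect_lt(abs(mean(pq$phenotype)), 0.2)

  # pooled prevalence over seeded replicates sits inside the exact
  # binomial 99% CI of K
  hits <- 0L; total <- 0L
  for (s in 1:50) {
    p <- gen_phenotypes(co, trait_spec("binary", prevalence = 0.10),
                        seed = s)
    hits <- hits + sum(p$phenotype); total <- total + length(p$phenotype)
  }
  ci <- stats::binom.test(hits, total, p = 0.10,
                          conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.10 && 0.10 <= ci[2])
})

test_that("mu calibration errors on unachievable prevalence and meets tolerance", {
  eta <- rep(0, 1000)
  mu <- calibrate_mu(eta, 0.25)
  expect_lt(abs(mean(stats::plogis(mu + eta)) - 0.25), 1e-8)
  expect_equal(mu, stats::qlogis(0.25), tolerance = 1e-6)
  expect_error(calibrate_mu(rep(100, 5), 1e-6), "not achievable")
})

test_that("a planted log(2) effect on a common variant yields a case/control allele odds ratio near 2", {
  # oracle: direct large-n simulation through the generator itself
  n <- 1e6
  set.seed(77)
  G <- cbind(Vcommon = stats::rbinom(n, 2, 0.3))
  co <- make_cohort(G, classes = "synonymous")
  ph <- gen_phenotypes(co, trait_spec("binary", prevalence = 0.1,
                                      variant_effects = c(Vcommon = log(2))),
                       seed = 9)
  y <- ph$phenotype
  eaf_case <- mean(G[y == 1, 1]) / 2
  eaf_ctrl <- mean(G[y == 0, 1]) / 2
  or_allele <- (eaf_case / (1 - eaf_case)) / (eaf_ctrl / (1 - eaf_ctrl))
  expect_lt(abs(or_allele - 2), 0.1)
})

test_that("phenotype generation validates its effect maps", {
  co <- default_test_cohort()
  expect_error(gen_phenotypes(co, trait_spec("binary", prevalence = 0.1,
                                             gene_effects = c(NOPE = 1))),
               "unknown gene ids")
  expect_error(gen_phenotypes(co, trait_spec("quantitative",
                                             variant_effects = c(VX = 1))),
               "unknown variant ids")
  expect_error(trait_spec("binary", prevalence = 0), "prevalence")
})

test_that("GWAS landscape placement tracks the requested density ratio", {
  r <- 6
  ls <- gen_gwas_landscape(n_traits = 40, n_signals = 6,
                           genome_length = 2e8, n_genes = 400,
                           causal_per_trait = 25, near_ratio = r,
                           near_dist = 1e6, seed = 21)
  tr <- ls$truth
  # realized causal densities in and out of windows (direct counting oracle)
  dens_in <- sum(tr$causal & tr$near_signal) / sum(tr$near_signal)
  dens_out <- sum(tr$causal & !tr$near_signal) / sum(!tr$near_signal)
  expect_gt(dens_in / dens_out, r * 0.6)
  expect_lt(dens_in / dens_out, r * 1.6)

  # no preference: densities comparable
  ls0 <- gen_gwas_landscape(n_traits = 40, n_signals = 6,
                            genome_length = 2e8, n_genes = 400,
                            causal_per_trait = 25, near_ratio = 1,
                            seed = 22)
  t0 <- ls0$truth
  d_in <- sum(t0$causal & t0$near_signal) / sum(t0$near_signal)
  d_out <- sum(t0$causal & !t0$near_signal) / sum(!t0$near_signal)
  expect_lt(abs(d_in / d_out - 1), 0.35)
  expect_identical(ls$signals,
                   gen_gwas_landscape(40, 6, 2e8, 400, 25, r, 1e6,
                                      seed = 21)$signals)
})

test_that("carrier tables follow the beta-binomial mixture they are drawn from", {
  # single component: mean carrier count matches the closed-form mean
  a <- 2; b <- 998; N <- 5000; G <- 4000
  tab <- gen_carrier_table(weights = 1, shapes = c(a, b), n_genes = G,
                           n_samples = N, seed = 13)
  expect_true(all(tab$het_carriers <= N))
  mean_expected <- N * a / (a + b)
  # SD of the per-gene count dominated by the beta spread
  se <- stats::sd(tab$het_carriers) / sqrt(G)
  expect_lt(abs(mean(tab$het_carriers) - mean_expected), 4 * se)

  # degenerate weight vector equals single-component generation
  t1 <- gen_carrier_table(weights = c(1, 0),
                          shapes = rbind(c(a, b), c(50, 50)),
                          n_genes = 200, n_samples = N, seed = 4)
  t2 <- gen_carrier_table(weights = 1, shapes = c(a, b),
                          n_genes = 200, n_samples = N, seed = 4)
  expect_identical(t1$het_carriers, t2$het_carriers)

  expect_identical(tab, gen_carrier_table(weights = 1, shapes = c(a, b),
                                          n_genes = G, n_samples = N,
                                          seed = 13))
  expect_error(gen_carrier_table(weights = 1, shapes = c(-1, 2),
                                 n_genes = 5, n_samples = 10), "positive")
  expect_error(gen_carrier_table(weights = c(0.6, 0.6),
                                 shapes = rbind(c(1, 1), c(2, 2)),
                                 n_genes = 5, n_samples = 10), "sum to 1")
})

test_that("accuracy curves are exact when noiseless and monotone for b > 0", {
  ns <- c(5e4, 1e5, 2e5, 3e5, 4e5)
  pts <- gen_accuracy_curve(a = -15, b = 1.3, c = 0.95, panel_sizes = ns,
                            noise_sd = 0)
  expect_equal(pts$r2, 0.95 / (1 + exp(-(-15 + 1.3 * log(ns)))),
               tolerance = 1e-12)
  expect_true(all(diff(pts$r2) > 0))
  expect_true(all(pts$r2 >= 0 & pts$r2 <= 1))
  noisy <- gen_accuracy_curve(-15, 1.3, 0.95, ns, noise_sd = 0.05, seed = 2)
  expect_true(all(noisy$r2 >= 0 & noisy$r2 <= 1))
  expect_error(gen_accuracy_curve(0, 1, 1.2, ns), "c")
})

test_that("generated tables round-trip losslessly through the writers and readers", {
  co <- default_test_cohort()
  vcf <- tempfile(fileext = ".vcf.gz")
  write_cohort_vcf(co, vcf)
  rt <- read_cohort_vcf(vcf)
  expect_identical(unname(rt$genotypes), unname(co$genotypes))
  expect_identical(unname(rt$DP), unname(co$DP))
  expect_identical(unname(rt$AD), unname(co$AD))
  expect_identical(rt$variants$ID, co$variants$variant_id)

  tsv <- tempfile(fileext = ".tsv")
  write_table_tsv(co$variants, tsv)
  back <- read_table_tsv(tsv)
  expect_equal(back$pos, co$variants$pos)
  expect_identical(back$class, co$variants$class)

  # missing genotypes survive the VCF round trip as no-calls
  co$genotypes[1, 1] <- NA
  write_cohort_vcf(co, vcf)
  expect_true(is.na(read_cohort_vcf(vcf)$genotypes[1, 1]))
})
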