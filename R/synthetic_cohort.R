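# Seeded generators for every input the pipeline consumes: genotypes with
# per-call read evidence, functional annotations, phenotypes, a GWAS sentinel
# landscape, per-gene carrier-count tables and imputation-accuracy curves.

#' Default consequence-class mixture for generated variants
#'
#' Proportions over functional consequence classes, defaulting to the class
#' composition observed in large exome-sequencing cohorts: mostly missense and
#' synonymous variants, a thin tail of in-frame indels, and six pLOF
#' subclasses (stop gained, frameshift, splice donor/acceptor, start/stop
#' lost).
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
default_class_mix <- function() {
  counts <- c(
    synonymous      = 3457173,
    missense        = 7878586,
    inframe_indel   = 75096,
    start_lost      = 26453,
    stop_gained     = 279913,
    stop_lost       = 12843,
    splice_donor    = 104328,
    splice_acceptor = 86083,
    frameshift      = 405669
  )
  counts / sum(counts)
}

#' Default deleteriousness-vote distribution for missense variants
#'
#' Probability that a missense variant is called deleterious by 0--5 of the
#' five prediction algorithms. Mass at 0 ("likely benign") and 5 ("likely
#' deleterious") follows the composition seen in large exome catalogues; the
#' "possibly deleterious" mass is spread uniformly over 1--4 votes.
#'
#' @return Numeric vector of length 6 (votes 0 to 5) summing to 1.
#' @export
default_vote_distribution <- function() {
  p0 <- 1532129 / 7878586
  p5 <- 1789828 / 7878586
  mid <- (1 - p0 - p5) / 4
  c(p0, rep(mid, 4), p5)
}

#' Read-evidence generator settings
#'
#' @param mean_depth Mean per-call read depth.
#' @param depth_size Negative-binomial size (inverse-dispersion) of depth;
#'   larger values give tighter depth distributions.
#' @param het_ab Allele-balance centre for germline heterozygotes.
#' @param hom_alt_ab Alternate-read fraction for homozygous-alternate calls.
#' @param ref_error Alternate-read error fraction for homozygous-reference
#'   calls.
#' @return A list of class `exb_read_spec`.
#' @export
read_evidence_spec <- function(mean_depth = 30, depth_size = 10,
                               het_ab = 0.5, hom_alt_ab = 0.98,
                               ref_error = 0.002) {
  stopifnot(mean_depth > 0, depth_size > 0,
            het_ab > 0, het_ab < 1, hom_alt_ab > 0, hom_alt_ab <= 1)
  structure(list(mean_depth = mean_depth, depth_size = depth_size,
                 het_ab = het_ab, hom_alt_ab = hom_alt_ab,
                 ref_error = ref_error),
            class = "exb_read_spec")
}

#' Somatic (CHIP-like) variant generator settings
#'
#' Somatic variants are generated as age-dependent heterozygous carriers with
#' a skewed variant allele fraction, emulating clonal haematopoiesis: carrier
#' probability is logistic in age and the VAF parameter sits outside the
#' germline band (below 0.35 or above 0.65).
#'
#' @param n_variants Number of generated variants to make somatic.
#' @param vaf Alternate-read fraction used for somatic carriers. Must be
#'   < 0.35 or > 0.65.
#' @param intercept,age_slope,age_center Carrier probability is
#'   `plogis(intercept + age_slope * (age - age_center))`.
#' @return A list of class `exb_somatic_spec`.
#' @export
somatic_spec <- function(n_variants = 0, vaf = 0.2, intercept = -3,
                         age_slope = 0.1, age_center = 55) {
  stopifnot(n_variants >= 0, vaf > 0, vaf < 1)
  if (vaf >= 0.35 && vaf <= 0.65)
    stop("somatic VAF parameter must be < 0.35 or > 0.65")
  structure(list(n_variants = as.integer(n_variants), vaf = vaf,
                 intercept = intercept, age_slope = age_slope,
                 age_center = age_center),
            class = "exb_somatic_spec")
}

#' Cohort generator settings
#'
#' Describes a synthetic exome cohort: sample size, gene models on a single
#' synthetic chromosome, a rare-allele frequency spectrum with an explicit
#' point mass at the singleton frequency `1/(2 * n_samples)`, the
#' consequence-class mixture, the deleteriousness-vote distribution for
#' missense variants, and per-call read evidence.
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_genes Number of genes (>= 1).
#' @param variants_per_gene Variants generated per gene.
#' @param singleton_mass Probability that a variant is a singleton
#'   (default 0.4686, the singleton fraction typical of coding variation at
#'   biobank scale).
#' @param maf_range Range for non-singleton allele frequencies, drawn
#'   log-uniformly. The lower bound defaults to `5 / (2 * n_samples)` so that
#'   non-singleton variants are well separated from the singleton mass.
#' @param class_mix Named proportions over consequence classes; must sum to 1.
#' @param vote_distribution Length-6 probability vector over 0--5 deleterious
#'   votes for missense variants.
#' @param read_evidence An [read_evidence_spec()].
#' @param somatic An optional [somatic_spec()].
#' @param gene_length,gene_spacing Gene interval length and start-to-start
#'   spacing (1-based closed intervals on a single synthetic chromosome).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `exb_cohort_spec`.
#' @export
cohort_spec <- function(n_samples, n_genes, variants_per_gene,
                        singleton_mass = 0.4686,
                        maf_range = c(NA, 0.01),
                        class_mix = default_class_mix(),
                        vote_distribution = default_vote_distribution(),
                        read_evidence = read_evidence_spec(),
                        somatic = NULL,
                        gene_length = 20000L, gene_spacing = 100000L,
                        seed = 1L) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (n_genes < 1 || variants_per_gene < 1)
    stop("n_genes and variants_per_gene must be >= 1")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (length(vote_distribution) != 6 || abs(sum(vote_distribution) - 1) > 1e-8)
    stop("vote_distribution must be 6 probabilities summing to 1")
  if (singleton_mass < 0 || singleton_mass > 1)
    stop("singleton_mass must be in [0, 1]")
  if (is.na(maf_range[1]))
    maf_range[1] <- min(5 / (2 * n_samples), maf_range[2] / 5)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("invalid maf_range")
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    variants_per_gene = as.integer(variants_per_gene),
    singleton_mass = singleton_mass, maf_range = maf_range,
    class_mix = class_mix, vote_distribution = vote_distribution,
    read_evidence = read_evidence, somatic = somatic,
    gene_length = as.integer(gene_length),
    gene_spacing = as.integer(gene_spacing),
    seed = as.integer(seed)
  ), class = "exb_cohort_spec")
}

PLOF_CLASSES <- c("start_lost", "stop_gained", "stop_lost",
                  "splice_donor", "splice_acceptor", "frameshift")
INDEL_CLASSES <- c("inframe_indel", "frameshift")

#' Generate a synthetic exome cohort
#'
#' Draws genotypes, functional annotations and per-call read evidence from a
#' [cohort_spec()]. Each variant is either a singleton (exactly one
#' heterozygous carrier) with probability `singleton_mass`, or a rare variant
#' whose allele frequency is drawn log-uniformly from `maf_range` and whose
#' genotypes are binomial(2, EAF) per sample; non-singleton variants are
#' forced to a minor allele count of at least 2 so that the realized singleton
#' fraction tracks the requested mass. Read depth is negative-binomial and
#' alternate-allele depth is binomial given depth, centred at 0.5 for germline
#' heterozygotes and at the somatic VAF parameter for somatic carriers.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `exb_cohort` with elements `genotypes` (samples x
#'   variants integer dosage matrix), `variants` (annotation data frame:
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene_id`, `class`, `votes`,
#'   `type`, `is_somatic`), `samples` (`sample_id`, `sex`, `age`), `genes`
#'   (`gene_id`, `chrom`, `start`, `end`), and `DP`/`AD` read-evidence
#'   matrices (AD is the alternate-allele depth).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "exb_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  m <- spec$n_genes * spec$variants_per_gene

  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = sample(40:70, n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  starts <- (seq_len(spec$n_genes) - 1L) * spec$gene_spacing + 1L
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(spec$n_genes)),
    chrom = "1",
    start = starts,
    end = starts + spec$gene_length - 1L,
    stringsAsFactors = FALSE
  )

  gene_of <- rep(seq_len(spec$n_genes), each = spec$variants_per_gene)
  pos <- unlist(lapply(seq_len(spec$n_genes), function(g)
    sort(sample(seq(genes$start[g], genes$end[g]),
                spec$variants_per_gene))), use.names = FALSE)

  cls <- sample(names(spec$class_mix), m, replace = TRUE,
                prob = spec$class_mix)
  votes <- rep(NA_integer_, m)
  is_mis <- cls == "missense"
  votes[is_mis] <- sample(0:5, sum(is_mis), replace = TRUE,
                          prob = spec$vote_distribution)
  type <- ifelse(cls %in% INDEL_CLASSES, "indel", "SNV")

  variants <- data.frame(
    variant_id = sprintf("V%06d", seq_len(m)),
    chrom = "1", pos = pos,
    ref = ifelse(type == "indel", "AT", "A"),
    alt = ifelse(type == "indel", "A", "G"),
    gene_id = genes$gene_id[gene_of],
    class = cls, votes = votes, type = type,
    is_somatic = FALSE,
    stringsAsFactors = FALSE
  )

  # genotypes: singleton point mass, otherwise HWE draws at a log-uniform EAF
  is_singleton <- as.logical(stats::rbinom(m, 1, spec$singleton_mass))
  G <- matrix(0L, n, m, dimnames = list(samples$sample_id,
                                        variants$variant_id))
  eaf <- rep(NA_real_, m)
  lo <- log10(spec$maf_range[1]); hi <- log10(spec$maf_range[2])
  eaf[!is_singleton] <- 10^stats::runif(sum(!is_singleton), lo, hi)
  for (j in seq_len(m)) {
    if (is_singleton[j]) {
      G[sample.int(n, 1), j] <- 1L
    } else {
      g <- stats::rbinom(n, 2, eaf[j])
      mac <- sum(g)
      if (mac < 2) {          # keep non-singletons out of the singleton bin
        extra <- sample.int(n, 2 - mac)
        g[extra] <- pmax(g[extra], 1L)
      }
      G[, j] <- g
    }
  }

  # somatic overrides: age-dependent heterozygous carriers
  if (!is.null(spec$somatic) && spec$somatic$n_variants > 0) {
    so <- spec$somatic
    k <- min(so$n_variants, m)
    idx <- sample.int(m, k)
    variants$is_somatic[idx] <- TRUE
    pr <- stats::plogis(so$intercept +
                          so$age_slope * (samples$age - so$age_center))
    for (j in idx) {
      g <- stats::rbinom(n, 1, pr)
      if (sum(g) == 0) g[which.max(samples$age)] <- 1L
      G[, j] <- as.integer(g)
    }
  }

  rs <- spec$read_evidence
  DP <- matrix(stats::rnbinom(n * m, mu = rs$mean_depth, size = rs$depth_size),
               n, m, dimnames = dimnames(G))
  storage.mode(DP) <- "integer"
  pab <- matrix(rs$ref_error, n, m)
  pab[G == 2L] <- rs$hom_alt_ab
  het_p <- matrix(rep(ifelse(variants$is_somatic,
                             spec$somatic$vaf %||% rs$het_ab, rs$het_ab),
                      each = n), n, m)
  pab[G == 1L] <- het_p[G == 1L]
  AD <- matrix(stats::rbinom(n * m, as.vector(DP), as.vector(pab)),
               n, m, dimnames = dimnames(G))

  structure(list(genotypes = G, variants = variants, samples = samples,
                 genes = genes, DP = DP, AD = AD, spec = spec),
            class = "exb_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trait generator settings
#'
#' @param kind `"binary"` or `"quantitative"`.
#' @param prevalence Target prevalence K for binary traits (0 < K < 1).
#' @param gene_effects Named vector of per-gene effects (log-odds for binary,
#'   s.d. units for quantitative), applied to a carrier burden over the
#'   gene's pLOF and 5-vote missense variants.
#' @param variant_effects Named vector of per-variant effects applied to the
#'   raw allele dosage.
#' @param covariate_effects Named vector with entries `age`, `age2`, `sex`,
#'   `age_sex` (coefficients on standardized age, its square, male indicator
#'   and their product). Defaults to all zero.
#' @return A list of class `exb_trait_spec`.
#' @export
trait_spec <- function(kind = c("binary", "quantitative"),
                       prevalence = NULL, gene_effects = NULL,
                       variant_effects = NULL,
                       covariate_effects = c(age = 0, age2 = 0, sex = 0,
                                             age_sex = 0)) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1)
      stop("binary traits need 0 < prevalence < 1")
  }
  structure(list(kind = kind, prevalence = prevalence,
                 gene_effects = gene_effects,
                 variant_effects = variant_effects,
                 covariate_effects = covariate_effects),
            class = "exb_trait_spec")
}

#' Calibrate the trait-model intercept to a target prevalence
#'
#' Solves `mean(plogis(mu + eta)) == K` for `mu` on the realized linear
#' predictor by one-dimensional root finding (prevalence tolerance 1e-8).
#'
#' @param eta Numeric vector of per-sample linear predictors (without
#'   intercept).
#' @param K Target prevalence.
#' @return The calibrated intercept `mu`.
#' @export
calibrate_mu <- function(eta, K) {
  stopifnot(K > 0, K < 1, length(eta) >= 1, all(is.finite(eta)))
  f <- function(mu) mean(stats::plogis(mu + eta)) - K
  lo <- -45; hi <- 45
  if (f(lo) > 0 || f(hi) < 0)
    stop("prevalence K is not achievable for this linear predictor")
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  if (abs(f(r$root)) > 1e-8)
    stop("mu calibration did not reach the prevalence tolerance")
  r$root
}

#' Generate phenotypes and covariates for a cohort
#'
#' Binary traits are drawn Bernoulli from `logit(p) = mu + G beta + covariate
#' terms`, with `mu` calibrated so the expected prevalence equals the
#' requested K. Quantitative traits are Gaussian with unit noise variance
#' around the genetic plus covariate mean.
#'
#' @param cohort An `exb_cohort` (or any list with `genotypes`, `variants`,
#'   `samples` of the same shape).
#' @param trait A [trait_spec()].
#' @param seed Integer seed.
#' @return A list with `phenotype` (numeric vector), `covariates` (data frame
#'   with `age`, `age2`, `sex`, `age_sex`; age standardized), `mu`, and the
#'   realized `eta` linear predictor.
#' @export
gen_phenotypes <- function(cohort, trait, seed = 1L) {
  stopifnot(inherits(trait, "exb_trait_spec"))
  set.seed(as.integer(seed))
  G <- cohort$genotypes
  n <- nrow(G)

  eta <- numeric(n)
  if (!is.null(trait$variant_effects)) {
    ids <- names(trait$variant_effects)
    miss <- setdiff(ids, colnames(G))
    if (length(miss)) stop("unknown variant ids in effect map: ",
                           paste(miss, collapse = ", "))
    eta <- eta + as.vector(G[, ids, drop = FALSE] %*% trait$variant_effects)
  }
  if (!is.null(trait$gene_effects)) {
    ids <- names(trait$gene_effects)
    miss <- setdiff(ids, unique(cohort$variants$gene_id))
    if (length(miss)) stop("unknown gene ids in effect map: ",
                           paste(miss, collapse = ", "))
    for (g in ids) {
      v <- cohort$variants
      sel <- v$gene_id == g &
        (v$class %in% PLOF_CLASSES |
           (v$class == "missense" & !is.na(v$votes) & v$votes == 5L))
      if (!any(sel)) next
      burden <- collapse_burden(G[, v$variant_id[sel], drop = FALSE])
      eta <- eta + trait$gene_effects[[g]] * burden
    }
  }

  age_std <- as.numeric(scale(cohort$samples$age))
  if (all(is.nan(age_std))) age_std <- rep(0, n)  # constant age
  male <- as.numeric(cohort$samples$sex == "M")
  covariates <- data.frame(age = age_std, age2 = age_std^2, sex = male,
                           age_sex = age_std * male)
  ce <- trait$covariate_effects
  eta_cov <- as.vector(as.matrix(covariates) %*%
                         ce[c("age", "age2", "sex", "age_sex")])
  eta <- eta + eta_cov

  if (trait$kind == "binary") {
    mu <- calibrate_mu(eta, trait$prevalence)
    y <- stats::rbinom(n, 1, stats::plogis(mu + eta))
  } else {
    mu <- 0
    y <- eta + stats::rnorm(n)
  }
  list(phenotype = y, covariates = covariates, mu = mu, eta = eta)
}

#' Generate a synthetic GWAS sentinel landscape with embedded causal genes
#'
#' Lays `n_genes` gene intervals and, per trait, `n_signals` sentinel
#' positions on a single synthetic chromosome. Causal genes for each trait
#' are sampled with weight `near_ratio` for genes within `near_dist` of one
#' of the trait's sentinels and weight 1 elsewhere, so the realized
#' in-window/out-of-window density ratio of causal genes tracks `near_ratio`.
#'
#' @param n_traits,n_signals Number of traits and sentinels per trait.
#' @param genome_length Chromosome length in base pairs.
#' @param n_genes Number of genes.
#' @param causal_per_trait Causal genes per trait.
#' @param near_ratio Sampling-weight ratio for near-sentinel genes (1 = no
#'   placement preference).
#' @param near_dist Distance in bp defining "near a sentinel".
#' @param gene_length Gene interval length.
#' @param seed Integer seed.
#' @return A list with `signals` (`trait_id`, `chrom`, `pos`, `p`), `genes`
#'   (`gene_id`, `chrom`, `start`, `end`) and `truth` (`trait_id`, `gene_id`,
#'   `causal`, `near_signal`).
#' @export
gen_gwas_landscape <- function(n_traits, n_signals, genome_length, n_genes,
                               causal_per_trait, near_ratio = 1,
                               near_dist = 1e6, gene_length = 20000L,
                               seed = 1L) {
  stopifnot(n_traits >= 1, n_signals >= 1, n_genes >= 1,
            causal_per_trait <= n_genes, near_ratio > 0,
            genome_length > gene_length)
  set.seed(as.integer(seed))
  genes <- data.frame(
    gene_id = sprintf("G%05d", seq_len(n_genes)),
    chrom = "1",
    start = sort(sample.int(genome_length - gene_length, n_genes)),
    stringsAsFactors = FALSE
  )
  genes$end <- genes$start + gene_length - 1L

  signals <- do.call(rbind, lapply(seq_len(n_traits), function(t) {
    data.frame(trait_id = sprintf("T%03d", t), chrom = "1",
               pos = sample.int(genome_length, n_signals),
               p = 10^-stats::runif(n_signals, 8, 60),
               stringsAsFactors = FALSE)
  }))

  mid <- (genes$start + genes$end) / 2
  truth <- do.call(rbind, lapply(seq_len(n_traits), function(t) {
    sp <- signals$pos[signals$trait_id == sprintf("T%03d", t)]
    near <- vapply(seq_len(n_genes), function(i) {
      any(abs(sp - genes$start[i]) <= near_dist |
            abs(sp - genes$end[i]) <= near_dist |
            (sp >= genes$start[i] & sp <= genes$end[i]))
    }, logical(1))
    w <- ifelse(near, near_ratio, 1)
    causal_idx <- sample.int(n_genes, causal_per_trait, prob = w)
    data.frame(trait_id = sprintf("T%03d", t), gene_id = genes$gene_id,
               causal = seq_len(n_genes) %in% causal_idx,
               near_signal = near, stringsAsFactors = FALSE)
  }))
  list(signals = signals, genes = genes, truth = truth)
}

#' Generate a per-gene carrier-count table from a beta-binomial mixture
#'
#' Per-gene carrier frequencies are drawn from a mixture of beta
#' distributions and carrier counts binomially given frequency and sample
#' size; heterozygous and homozygous carriers are generated as independent
#' processes.
#'
#' @param weights Mixture weights (sum to 1).
#' @param shapes Matrix (components x 2) or list of `(alpha, beta)` shape
#'   pairs for the heterozygous-carrier frequency.
#' @param n_genes Number of genes.
#' @param n_samples Cohort size N.
#' @param hom_weights,hom_shapes Optional mixture for the homozygous-carrier
#'   process; if omitted, homozygous counts are 0.
#' @param seed Integer seed.
#' @return Data frame (`gene_id`, `het_carriers`, `hom_carriers`) with
#'   attributes `n_samples` and `truth` (component index and frequency per
#'   gene for the heterozygous process).
#' @export
gen_carrier_table <- function(weights, shapes, n_genes, n_samples,
                              hom_weights = NULL, hom_shapes = NULL,
                              seed = 1L) {
  shapes <- .as_shape_matrix(shapes)
  if (length(weights) != nrow(shapes)) stop("weights/shapes length mismatch")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(shapes <= 0)) stop("beta shapes must be positive")
  set.seed(as.integer(seed))
  draw <- function(w, sh) {
    comp <- sample.int(nrow(sh), n_genes, replace = TRUE, prob = w)
    f <- stats::rbeta(n_genes, sh[comp, 1], sh[comp, 2])
    list(comp = comp, f = f,
         k = stats::rbinom(n_genes, n_samples, f))
  }
  het <- draw(weights, shapes)
  hom_k <- rep(0L, n_genes)
  if (!is.null(hom_shapes)) {
    hom_shapes <- .as_shape_matrix(hom_shapes)
    if (is.null(hom_weights)) hom_weights <- rep(1 / nrow(hom_shapes),
                                                 nrow(hom_shapes))
    hom_k <- draw(hom_weights, hom_shapes)$k
  }
  out <- data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
                    het_carriers = het$k, hom_carriers = hom_k,
                    stringsAsFactors = FALSE)
  attr(out, "n_samples") <- as.integer(n_samples)
  attr(out, "truth") <- data.frame(component = het$comp, frequency = het$f)
  out
}

.as_shape_matrix <- function(shapes) {
  if (is.list(shapes)) shapes <- do.call(rbind, shapes)
  shapes <- matrix(as.numeric(shapes), ncol = 2)
  shapes
}

#' Generate (panel size, imputation r-squared) points from a logistic curve
#'
#' Points follow `r2 = c / (1 + exp(-(a + b * log(n)))) + noise`, truncated
#' to \[0, 1\].
#'
#' @param a,b,c Curve parameters; `0 < c <= 1`.
#' @param panel_sizes Vector of reference-panel sizes n.
#' @param noise_sd Gaussian noise standard deviation (0 for noiseless).
#' @param seed Integer seed.
#' @return Data frame with columns `n` and `r2`.
#' @export
gen_accuracy_curve <- function(a, b, c, panel_sizes, noise_sd = 0, seed = 1L) {
  stopifnot(c > 0, c <= 1, all(panel_sizes > 0), noise_sd >= 0)
  set.seed(as.integer(seed))
  r2 <- c / (1 + exp(-(a + b * log(panel_sizes))))
  if (noise_sd > 0) r2 <- r2 + stats::rnorm(length(panel_sizes), 0, noise_sd)
  data.frame(n = panel_sizes, r2 = pmin(pmax(r2, 0), 1))
}

#' Generate stratified 2x2 enrichment tables with a common true odds ratio
#'
#' Per stratum (trait), a baseline significant-gene rate is drawn uniformly
#' from `base_rate`, out-of-window significant counts are binomial at that
#' rate, and in-window counts are binomial at the rate whose odds are
#' `true_or` times the baseline odds.
#'
#' @param n_strata Number of strata.
#' @param true_or Common odds ratio.
#' @param n_in,n_out Genes in and out of the GWAS window per stratum.
#' @param base_rate Length-2 range of baseline rates.
#' @param seed Integer seed.
#' @return Data frame with columns `a`, `b`, `c`, `d`.
#' @export
gen_enrichment_strata <- function(n_strata, true_or, n_in = 40, n_out = 2000,
                                  base_rate = c(0.005, 0.05), seed = 1L) {
  stopifnot(n_strata >= 1, true_or > 0, n_in >= 1, n_out >= 1)
  set.seed(as.integer(seed))
  q <- stats::runif(n_strata, base_rate[1], base_rate[2])
  odds_in <- true_or * q / (1 - q)
  q_in <- odds_in / (1 + odds_in)
  a <- stats::rbinom(n_strata, n_in, q_in)
  cc <- stats::rbinom(n_strata, n_out, q)
  data.frame(a = a, b = n_in - a, c = cc, d = n_out - cc)
}
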