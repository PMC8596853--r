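# Case-control power: empirical simulation under a calibrated logistic model
# (score test with Firth fallback, mirroring the discovery pipeline) and the
# closed-form score-test non-centrality parameter, plus the expected number
# of chance replications.

#' Power-simulation settings
#'
#' @param N Total sample size.
#' @param K Disease prevalence (0 < K < 1).
#' @param EAF Effect allele frequency (0 < EAF < 1).
#' @param OR Odds ratio of the causal marker (`beta = log(OR)`).
#' @param alpha Significance level.
#' @param n_marker_reps Genotype-vector replicates (default 10).
#' @param n_pheno_reps Phenotype replicates per marker (default 100), so the
#'   default replicate total is 1,000.
#' @param seed Integer seed.
#' @return A list of class `exb_power_spec`.
#' @export
power_spec <- function(N, K, EAF, OR, alpha, n_marker_reps = 10L,
                       n_pheno_reps = 100L, seed = 1L) {
  stopifnot(N >= 2, K > 0, K < 1, EAF > 0, EAF < 1, OR > 0,
            alpha > 0, alpha < 1, n_marker_reps >= 1, n_pheno_reps >= 1)
  structure(list(N = as.integer(N), K = K, EAF = EAF, OR = OR,
                 alpha = alpha, n_marker_reps = as.integer(n_marker_reps),
                 n_pheno_reps = as.integer(n_pheno_reps),
                 seed = as.integer(seed)),
            class = "exb_power_spec")
}

#' Simulate one case-control replicate
#'
#' Genotypes are drawn Binomial(2, EAF) independently per sample; the binary
#' trait follows `logit(p) = mu + G log(OR)` with `mu` calibrated on the
#' realized genotypes so the expected prevalence is K, and
#' `Y | p ~ Bernoulli(p)`.
#'
#' @param spec A [power_spec()].
#' @param seed Seed for this replicate (defaults to the spec seed).
#' @return List with genotype vector `G`, case status `y`, and `mu`.
#' @export
simulate_case_control <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "exb_power_spec"))
  set.seed(as.integer(seed))
  G <- stats::rbinom(spec$N, 2, spec$EAF)
  eta <- G * log(spec$OR)
  mu <- calibrate_mu(eta, spec$K)
  y <- stats::rbinom(spec$N, 1, stats::plogis(mu + eta))
  list(G = G, y = y, mu = mu)
}

# p-value only fast path: intercept-only score test, Firth LRT fallback
.binary_pvalue <- function(g, y, firth_threshold = 0.05) {
  n <- length(y)
  p0 <- mean(y)
  if (p0 <= 0 || p0 >= 1) return(1)
  U <- sum(g * (y - p0))
  V <- p0 * (1 - p0) * (sum(g^2) - sum(g)^2 / n)
  if (V <= 0) return(1)
  p_score <- stats::pchisq(U^2 / V, 1, lower.tail = FALSE)
  if (p_score >= firth_threshold) return(p_score)
  X <- cbind(1, g)
  full <- firth_logistic(X, y)
  nullf <- firth_logistic(X, y, fixed = 2L)
  lr <- 2 * (full$loglik_penalized - nullf$loglik_penalized)
  stats::pchisq(max(lr, 0), 1, lower.tail = FALSE)
}

#' Empirical power by simulation
#'
#' Runs `n_marker_reps x n_pheno_reps` replicates of
#' [simulate_case_control()], tests each with the score test and Firth
#' fallback at 0.05 (the same decision rule as [test_binary()]), and
#' estimates power as the fraction of replicates with p below `alpha`, with
#' an exact binomial 95% confidence interval.
#'
#' @param spec A [power_spec()].
#' @param firth_threshold Score p-value fallback threshold.
#' @return List with `power`, `ci` (exact binomial 95% CI), `n_reps`,
#'   `alpha`.
#' @export
empirical_power <- function(spec, firth_threshold = 0.05) {
  stopifnot(inherits(spec, "exb_power_spec"))
  set.seed(spec$seed)
  beta <- log(spec$OR)
  hits <- 0L; total <- 0L
  for (mk in seq_len(spec$n_marker_reps)) {
    G <- stats::rbinom(spec$N, 2, spec$EAF)
    eta <- G * beta
    mu <- calibrate_mu(eta, spec$K)
    pr <- stats::plogis(mu + eta)
    for (ph in seq_len(spec$n_pheno_reps)) {
      y <- stats::rbinom(spec$N, 1, pr)
      pv <- .binary_pvalue(G, y, firth_threshold)
      hits <- hits + (pv <= spec$alpha)
      total <- total + 1L
    }
  }
  ci <- stats::binom.test(hits, total)$conf.int
  list(power = hits / total, ci = as.numeric(ci), n_reps = total,
       alpha = spec$alpha)
}

#' Case allele frequency implied by an odds ratio
#'
#' Uses the odds identity `p_case = OR * p / (1 - p + OR * p)`, with the
#' control allele frequency approximated by the population frequency.
#'
#' @param p Population (~ control) effect allele frequency.
#' @param OR Odds ratio.
#' @return The case allele frequency.
#' @export
case_eaf_from_or <- function(p, OR) {
  stopifnot(p > 0, p < 1, OR > 0)
  OR * p / (1 - p + OR * p)
}

#' Theoretical power of the logistic-regression score test
#'
#' Power is the upper-tail probability, beyond the central 1-df chi-square
#' `(1 - alpha)` quantile, of a 1-df noncentral chi-square with
#' non-centrality parameter
#' `eta = 2 N0 N1 (p_case - p)^2 / ((N0 + N1) pbar (1 - pbar))`, where
#' `pbar` is the case/control-weighted average allele frequency.
#'
#' @param N0,N1 Numbers of controls and cases.
#' @param p Control (~ population) effect allele frequency.
#' @param p_case Case effect allele frequency (see [case_eaf_from_or()]).
#' @param alpha Significance level.
#' @return List with `power` and the non-centrality parameter `ncp`.
#' @export
theoretical_power <- function(N0, N1, p, p_case, alpha) {
  stopifnot(N0 > 0, N1 > 0, p > 0, p < 1, p_case > 0, p_case < 1,
            alpha > 0, alpha < 1)
  pbar <- (N1 * p_case + N0 * p) / (N1 + N0)
  ncp <- 2 * N0 * N1 * (p_case - p)^2 / ((N0 + N1) * pbar * (1 - pbar))
  crit <- stats::qchisq(1 - alpha, df = 1)
  list(power = stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE),
       ncp = ncp)
}

#' Expected number of chance replications
#'
#' For `n_tested` associations tested for replication at level `alpha`, the
#' expected number that are both nominally significant and directionally
#' consistent by chance is `n_tested * alpha * 0.5` (the 0.5 being the
#' probability of a directionally consistent sign under the null).
#'
#' @param n_tested Number of associations tested.
#' @param alpha Replication significance level.
#' @return Expected chance replication count.
#' @export
expected_replications_by_chance <- function(n_tested, alpha = 0.05) {
  stopifnot(n_tested >= 0, alpha > 0, alpha < 1)
  n_tested * alpha * 0.5
}
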