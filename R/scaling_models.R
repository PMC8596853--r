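# Forward-projection models: a beta-binomial mixture over per-gene carrier
# frequencies, used to project loss-of-function carrier saturation at larger
# cohort sizes, and logistic-curve extrapolation of imputation accuracy
# versus reference-panel size.

.log_bb <- function(k, N, alpha, beta) {
  lchoose(N, k) + lbeta(k + alpha, N - k + beta) - lbeta(alpha, beta)
}

.logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# weighted single-component beta-binomial MLE, warm-started at `start`.
# Shapes are bounded to [1e-10, 1e8]: beyond that the lgamma-difference
# likelihood loses precision (and the distribution is numerically binomial).
.bb_mstep <- function(k, N, w, start) {
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    v <- -sum(w * .log_bb(k, N, a, b))
    if (!is.finite(v)) 1e300 else v
  }
  start <- pmin(pmax(start, 1e-9), 1e7)
  fit <- tryCatch(stats::optim(log(start), nll, method = "L-BFGS-B",
                               lower = log(1e-10), upper = log(1e8),
                               control = list(maxit = 200)),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e299)
    return(start)
  if (fit$value > nll(log(start))) return(start)  # never step downhill
  exp(fit$par)
}

#' Fit a beta-binomial mixture to per-gene carrier counts
#'
#' Maximum-likelihood fit by expectation-maximization with log-domain
#' responsibilities. The M-step re-estimates each component's beta shapes by
#' warm-started numerical maximization of the weighted beta-binomial
#' likelihood, so the observed-data log-likelihood is non-decreasing across
#' iterations. `n_components = "auto"` selects 1--`max_components` by BIC;
#' each component count is fitted from `n_starts` seeded initializations and
#' the best likelihood is kept. Identical counts are aggregated before
#' fitting, so cost scales with the number of distinct counts.
#'
#' @param counts Per-gene carrier counts (e.g. heterozygous pLOF carriers).
#' @param n_samples Cohort size N the counts were observed in.
#' @param n_components Integer, or `"auto"` for BIC selection.
#' @param max_components Upper bound for `"auto"` (default 5).
#' @param n_starts Seeded restarts per component count (default 10).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @param seed Integer seed for the restarts.
#' @return A list of class `exb_bbmix`: `n_components`, `weights`, `shapes`
#'   (components x 2 matrix of (alpha, beta)), `loglik`, `loglik_trace`,
#'   `bic`, `iterations`, `converged`, `n_samples`, and for auto mode
#'   `bic_by_components`.
#' @export
fit_bbmix <- function(counts, n_samples, n_components = "auto",
                      max_components = 5L, n_starts = 10L,
                      max_iter = 500L, tol = 1e-8, seed = 1L) {
  stopifnot(length(counts) >= 1, all(counts >= 0), all(counts <= n_samples))
  n_genes <- length(counts)
  agg <- as.data.frame(table(counts), stringsAsFactors = FALSE)
  k <- as.numeric(agg$counts)
  wt <- as.numeric(agg$Freq)
  N <- n_samples

  fit_j <- function(J, start_seed) {
    set.seed(start_seed)
    # seeded init: spread component means over the count quantiles
    qs <- stats::quantile(counts + 0.5, probs = (seq_len(J) - 0.5) / J)
    mu <- pmin(pmax(as.numeric(qs) / N * stats::runif(J, 0.5, 2), 1e-8),
               1 - 1e-8)
    conc <- 10^stats::runif(J, 0, 2)
    shapes <- cbind(mu * conc, (1 - mu) * conc)
    weights <- rep(1 / J, J)
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      lf <- vapply(seq_len(J), function(j)
        log(weights[j]) + .log_bb(k, N, shapes[j, 1], shapes[j, 2]),
        numeric(length(k)))
      lf <- matrix(lf, nrow = length(k))
      lse <- .logsumexp_rows(lf)
      ll <- sum(wt * lse)
      trace <- c(trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      r <- exp(lf - lse)                       # responsibilities
      for (j in seq_len(J)) {
        wj <- wt * r[, j]
        weights[j] <- sum(wj) / n_genes
        if (sum(wj) < 1e-12) next
        shapes[j, ] <- .bb_mstep(k, N, wj, shapes[j, ])
      }
      weights <- weights / sum(weights)
    }
    ord <- order(shapes[, 1] / rowSums(shapes))   # stable component order
    list(weights = weights[ord], shapes = shapes[ord, , drop = FALSE],
         loglik = trace[length(trace)], loglik_trace = trace,
         iterations = length(trace), converged = converged)
  }

  best_for_J <- function(J) {
    fits <- lapply(seq_len(n_starts), function(s) fit_j(J, seed + 1000L * s))
    fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  }

  if (identical(n_components, "auto")) {
    cand <- lapply(seq_len(max_components), best_for_J)
    bics <- vapply(seq_along(cand), function(J)
      -2 * cand[[J]]$loglik + (3 * J - 1) * log(n_genes), numeric(1))
    J <- which.min(bics)
    fit <- cand[[J]]
    extra <- list(bic_by_components = bics)
  } else {
    J <- as.integer(n_components)
    fit <- best_for_J(J)
    extra <- list()
  }
  structure(c(list(n_components = J,
                   weights = fit$weights, shapes = fit$shapes,
                   loglik = fit$loglik, loglik_trace = fit$loglik_trace,
                   bic = -2 * fit$loglik + (3 * J - 1) * log(n_genes),
                   iterations = fit$iterations, converged = fit$converged,
                   n_samples = as.integer(N), n_genes = n_genes),
              extra),
            class = "exb_bbmix")
}

# P(X <= q) for X ~ BetaBinomial(M, alpha, beta), vectorized over nothing
.pbb_upper <- function(q, M, alpha, beta) {
  # returns P(X >= q); exact sum over the lower tail (q is small here)
  if (q <= 0) return(1)
  if (q > M) return(0)
  x <- 0:(q - 1)
  1 - sum(exp(.log_bb(x, M, alpha, beta)))
}

#' Project the number of genes reaching a carrier-count threshold
#'
#' Empirical-Bayes posterior-predictive projection: for each gene with
#' observed carrier count k out of N, the posterior over mixture components
#' and the component-wise Beta posterior `(alpha + k, beta + N - k)` give
#' the predictive distribution of additional carriers among `target_n - N`
#' new samples (beta-binomial). The projected number of genes with at least
#' K carriers at `target_n` is the sum over genes of the predictive
#' probability of reaching K.
#'
#' @param fit An `exb_bbmix` from [fit_bbmix()].
#' @param counts The observed per-gene carrier counts used in the fit (or a
#'   comparable column, e.g. homozygous counts for a hom-process fit).
#' @param target_n Projected cohort size (>= the fitted `n_samples`).
#' @param thresholds Vector of carrier-count thresholds K.
#' @return Data frame (`target_n`, `K`, `expected_genes`).
#' @export
project_carriers <- function(fit, counts, target_n, thresholds) {
  stopifnot(inherits(fit, "exb_bbmix"))
  N <- fit$n_samples
  if (target_n < N) stop("target_n must be at least the fitted cohort size")
  M <- target_n - N
  agg <- as.data.frame(table(counts), stringsAsFactors = FALSE)
  ks <- as.numeric(agg$counts)
  mult <- as.numeric(agg$Freq)
  J <- fit$n_components
  lpost <- vapply(seq_len(J), function(j)
    log(fit$weights[j]) + .log_bb(ks, N, fit$shapes[j, 1], fit$shapes[j, 2]),
    numeric(length(ks)))
  lpost <- matrix(lpost, nrow = length(ks))
  post <- exp(lpost - .logsumexp_rows(lpost))

  out <- lapply(thresholds, function(K) {
    prob <- vapply(seq_along(ks), function(i) {
      need <- K - ks[i]
      if (need <= 0 || M == 0) return(as.numeric(need <= 0))
      pj <- vapply(seq_len(J), function(j)
        .pbb_upper(need, M, fit$shapes[j, 1] + ks[i],
                   fit$shapes[j, 2] + N - ks[i]), numeric(1))
      sum(post[i, ] * pj)
    }, numeric(1))
    data.frame(target_n = target_n, K = K,
               expected_genes = sum(mult * prob))
  })
  do.call(rbind, out)
}

#' Fit a logistic curve of imputation accuracy versus panel size
#'
#' Nonlinear least squares of `r2 ~ c / (1 + exp(-(a + b * log(n))))`, with
#' the curve parameterized on the log(n) scale. The two-parameter model
#' fixes the asymptote at `c = 1`; the three-parameter model estimates `c`
#' under the restriction `c <= 1`. The parameter covariance comes from the
#' Jacobian at the optimum.
#'
#' @param points Data frame with columns `n` (panel size) and `r2`.
#' @param model `"2p"` or `"3p"`.
#' @return A list of class `exb_logcurve`: `model`, `a`, `b`, `c`, `vcov`
#'   (rows/columns `a`, `b` and, for 3p, `c`), `fitted`, `points`.
#' @export
fit_logistic_curve <- function(points, model = c("2p", "3p")) {
  model <- match.arg(model)
  stopifnot(all(c("n", "r2") %in% names(points)), all(points$n > 0))
  need <- if (model == "2p") 3 else 4
  if (nrow(points) < need)
    stop("need at least ", need, " points for the ", model, " model")
  d <- data.frame(logn = log(points$n), r2 = points$r2)

  c0 <- if (model == "2p") 1 else min(1, max(points$r2) * 1.02 + 1e-6)
  yl <- stats::qlogis(pmin(pmax(d$r2 / c0, 1e-6), 1 - 1e-6))
  init <- stats::coef(stats::lm(yl ~ d$logn))
  if (model == "2p") {
    fit <- minpack.lm::nlsLM(r2 ~ 1 / (1 + exp(-(a + b * logn))), data = d,
                             start = list(a = init[[1]], b = init[[2]]))
  } else {
    fit <- minpack.lm::nlsLM(r2 ~ cc / (1 + exp(-(a + b * logn))), data = d,
                             start = list(a = init[[1]], b = init[[2]],
                                          cc = c0),
                             lower = c(-Inf, -Inf, 1e-6),
                             upper = c(Inf, Inf, 1))
  }
  cf <- stats::coef(fit)
  V <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, length(cf), length(cf))
  })
  nm <- if (model == "2p") c("a", "b") else c("a", "b", "c")
  dimnames(V) <- list(nm, nm)
  structure(list(model = model, a = cf[["a"]], b = cf[["b"]],
                 c = if (model == "2p") 1 else cf[["cc"]],
                 vcov = V, fitted = stats::fitted(fit), points = points),
            class = "exb_logcurve")
}

#' Extrapolate imputation accuracy to a larger panel size
#'
#' Plug-in prediction from a fitted logistic curve with a delta-method
#' confidence interval on the r-squared scale, truncated to \[0, 1\].
#'
#' @param fit An `exb_logcurve` from [fit_logistic_curve()].
#' @param n Target panel size(s).
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame (`n`, `r2`, `ci_lower`, `ci_upper`, `se`).
#' @export
extrapolate_r2 <- function(fit, n, conf_level = 0.95) {
  stopifnot(inherits(fit, "exb_logcurve"), all(n > 0))
  logn <- log(n)
  L <- stats::plogis(fit$a + fit$b * logn)
  pred <- fit$c * L
  dLd <- L * (1 - L)
  grad <- cbind(a = fit$c * dLd, b = fit$c * dLd * logn)
  if (fit$model == "3p") grad <- cbind(grad, c = L)
  se <- sqrt(pmax(rowSums((grad %*% fit$vcov) * grad), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(n = n, r2 = pred,
             ci_lower = pmax(pred - z * se, 0),
             ci_upper = pmin(pred + z * se, 1),
             se = se)
}
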