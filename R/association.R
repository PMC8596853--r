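# Phenotype preparation and covariate-adjusted association tests: ordinary
# least squares for quantitative traits, a logistic score test with Firth
# penalized-likelihood fallback for binary traits, and conditional analysis
# with common-variant dosages as extra covariates.

#' Rank-based inverse-normal transformation
#'
#' Maps average ranks through the normal quantile function with the Blom
#' offset: `qnorm((rank - 3/8) / (n + 1/4))`. Missing values are preserved.
#'
#' @param x Numeric vector with at least two distinct non-missing values.
#' @return Transformed vector.
#' @export
rint <- function(x) {
  ok <- !is.na(x)
  if (length(unique(x[ok])) < 2)
    stop("rank-inverse-normal transform needs >= 2 distinct values")
  n <- sum(ok)
  r <- rank(x, na.last = "keep", ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Prepare a raw trait for association testing
#'
#' Quantitative traits: per-participant values are averaged across visits,
#' then the trait is rejected when its mode is observed in >= 20% of samples,
#' or when the mode is observed in \[0.5%, 20%) of samples and the number of
#' unique values is below 100 or above 10,000; surviving traits are
#' rank-inverse-normal transformed. Binary traits are rejected when they have
#' fewer than 100 cases.
#'
#' @param values Numeric vector, or a matrix with one column per visit.
#' @param kind `"quantitative"` or `"binary"`.
#' @param min_cases Minimum case count for binary traits (default 100).
#' @param mode_reject Mode-fraction rejection threshold (default 0.20).
#' @param mode_flag Lower edge of the suspicious mode-fraction band
#'   (default 0.005).
#' @param min_unique,max_unique Unique-value bounds applied inside the
#'   suspicious band (defaults 100 and 10,000).
#' @return A list of class `exb_trait`: `kind`, `values` (transformed, or
#'   case indicators), `qc_status` (`"pass"`/`"rejected"`), `reason`, and
#'   for binary traits `n_cases`/`n_controls`.
#' @export
prepare_trait <- function(values, kind = c("quantitative", "binary"),
                          min_cases = 100L, mode_reject = 0.20,
                          mode_flag = 0.005, min_unique = 100L,
                          max_unique = 10000L) {
  kind <- match.arg(kind)
  out <- function(vals, status, reason = NA_character_, n1 = NA, n0 = NA)
    structure(list(kind = kind, values = vals, qc_status = status,
                   reason = reason, n_cases = n1, n_controls = n0),
              class = "exb_trait")
  if (is.matrix(values) || is.data.frame(values)) {
    values <- rowMeans(as.matrix(values), na.rm = TRUE)
    values[is.nan(values)] <- NA
  }
  if (all(is.na(values))) return(out(values, "rejected", "all_missing"))

  if (kind == "binary") {
    if (!all(values[!is.na(values)] %in% c(0, 1)))
      stop("binary trait values must be 0/1")
    n1 <- sum(values == 1, na.rm = TRUE)
    n0 <- sum(values == 0, na.rm = TRUE)
    if (n1 < min_cases)
      return(out(values, "rejected", "too_few_cases", n1, n0))
    return(out(values, "pass", NA_character_, n1, n0))
  }

  nm <- sum(!is.na(values))
  tab <- table(values)
  mode_frac <- max(tab) / nm
  n_unique <- length(tab)
  if (mode_frac >= mode_reject)
    return(out(values, "rejected", "mode_fraction"))
  if (mode_frac >= mode_flag && n_unique < min_unique)
    return(out(values, "rejected", "few_unique_values"))
  if (mode_frac >= mode_flag && n_unique > max_unique)
    return(out(values, "rejected", "many_unique_values"))
  out(rint(values), "pass")
}

assoc_result <- function(effect, se, p, n_carriers, model_used,
                         conditioned_on = character(), flags = character()) {
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else
    effect + c(-1, 1) * stats::qnorm(0.975) * se
  structure(list(effect = effect, se = se, ci95 = ci, p = p,
                 n_carriers = n_carriers, model_used = model_used,
                 conditioned_on = conditioned_on, flags = flags),
            class = "exb_assoc")
}

#' @export
print.exb_assoc <- function(x, ...) {
  cat(sprintf("%s test: effect = %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
              x$model_used, x$effect, x$ci95[1], x$ci95[2], x$p))
  cat(sprintf("  carriers: %d", x$n_carriers))
  if (length(x$conditioned_on))
    cat("; conditioned on:", paste(x$conditioned_on, collapse = ", "))
  if (length(x$flags)) cat("; flags:", paste(x$flags, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.exb_assoc <- function(x, ...) {
  data.frame(effect = x$effect, se = x$se, ci_lower = x$ci95[1],
             ci_upper = x$ci95[2], p = x$p, n_carriers = x$n_carriers,
             model_used = x$model_used,
             conditioned_on = paste(x$conditioned_on, collapse = ","),
             flags = paste(x$flags, collapse = ","),
             stringsAsFactors = FALSE)
}

.covar_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  Z <- as.matrix(covariates)
  stopifnot(nrow(Z) == n)
  storage.mode(Z) <- "double"
  if (is.null(colnames(Z))) colnames(Z) <- paste0("covar", seq_len(ncol(Z)))
  Z
}

.check_full_rank <- function(X) {
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
}

#' Covariate-adjusted linear association test for a quantitative trait
#'
#' Ordinary least squares of the (transformed) trait on the allele or burden
#' dosage plus covariates, with Wald confidence interval and p-value. The
#' effect is in trait s.d. units when the trait was rank-inverse-normal
#' transformed.
#'
#' @param dosage Per-sample dosage (0/1/2 or burden dosage).
#' @param trait Numeric trait vector (or `exb_trait` with `qc_status`
#'   "pass").
#' @param covariates Optional data frame/matrix of covariates.
#' @return An `exb_assoc` result with `model_used = "linear"`.
#' @export
test_quantitative <- function(dosage, trait, covariates = NULL) {
  if (inherits(trait, "exb_trait")) {
    if (trait$qc_status != "pass") stop("trait did not pass QC")
    trait <- trait$values
  }
  n <- length(trait)
  stopifnot(length(dosage) == n)
  Z <- .covar_matrix(covariates, n)
  X <- cbind(intercept = 1, dosage = dosage, Z)
  ok <- stats::complete.cases(X, trait)
  X <- X[ok, , drop = FALSE]; y <- trait[ok]
  .check_full_rank(X)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- length(y) - ncol(X)
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- fit$coefficients[["dosage"]]
  p <- 2 * stats::pt(abs(beta / se), df, lower.tail = FALSE)
  assoc_result(beta, se, p, sum(dosage[ok] > 0, na.rm = TRUE), "linear")
}

# score test for the dosage given a fitted null logistic model
.score_test <- function(g, y, Z, null_fit = NULL) {
  if (is.null(null_fit)) {
    null_fit <- stats::glm.fit(Z, y, family = stats::binomial())
  }
  mu <- null_fit$fitted.values
  W <- mu * (1 - mu)
  U <- sum(g * (y - mu))
  gW <- g * W
  ZtWZ <- crossprod(Z, Z * W)
  ZtWg <- crossprod(Z, gW)
  V <- sum(g * gW) - drop(crossprod(ZtWg, solve(ZtWZ, ZtWg)))
  if (V <= 0) return(list(stat = 0, p = 1))
  stat <- U^2 / V
  list(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Binary-trait association test: logistic score test with Firth fallback
#'
#' The dosage is first tested with a covariate-adjusted logistic score test.
#' When the score p-value falls below `firth_threshold` (default 0.05), the
#' model is refitted by exact Firth penalized likelihood and the reported
#' effect, standard error, confidence interval and p-value (penalized
#' likelihood-ratio test) come from the Firth fit; otherwise the score-test
#' p-value is reported alongside the maximum-likelihood effect estimate.
#'
#' @param dosage Per-sample dosage.
#' @param y 0/1 case status (or a passing binary `exb_trait`).
#' @param covariates Optional covariate data frame/matrix.
#' @param firth_threshold Score p-value below which the Firth refit is used.
#' @return An `exb_assoc` with `model_used` `"score"` or `"firth"` and the
#'   effect on the log-odds scale.
#' @export
test_binary <- function(dosage, y, covariates = NULL,
                        firth_threshold = 0.05) {
  if (inherits(y, "exb_trait")) {
    if (y$qc_status != "pass") stop("trait did not pass QC")
    y <- y$values
  }
  n <- length(y)
  stopifnot(length(dosage) == n)
  Z <- .covar_matrix(covariates, n)
  X <- cbind(intercept = 1, Z, dosage = dosage)
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]; g <- X[, "dosage"]
  if (sum(y == 1) < 1 || sum(y == 0) < 1)
    stop("need at least one case and one control")
  .check_full_rank(X)
  Znull <- X[, setdiff(colnames(X), "dosage"), drop = FALSE]
  null_fit <- stats::glm.fit(Znull, y, family = stats::binomial())
  sc <- .score_test(g, y, Znull, null_fit)
  n_car <- sum(g > 0, na.rm = TRUE)

  if (sc$p < firth_threshold) {
    full <- firth_logistic(X, y)
    nullf <- firth_logistic(X, y, fixed = "dosage")
    if (!full$converged || !nullf$converged)
      stop("Firth fit did not converge; iterations = ", full$iterations)
    lr <- 2 * (full$loglik_penalized - nullf$loglik_penalized)
    p <- stats::pchisq(max(lr, 0), 1, lower.tail = FALSE)
    beta <- full$coefficients[["dosage"]]
    se <- sqrt(full$vcov["dosage", "dosage"])
    return(assoc_result(beta, se, p, n_car, "firth"))
  }
  # ML effect via the full logistic fit, p from the score test
  full_ml <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  beta <- full_ml$coefficients[["dosage"]]
  W <- full_ml$fitted.values * (1 - full_ml$fitted.values)
  info <- crossprod(X, X * W)
  se <- tryCatch(sqrt(solve(info)["dosage", "dosage"]),
                 error = function(e) NA_real_)
  assoc_result(beta, se, sc$p, n_car, "score")
}

#' Association test conditioning on common-variant dosages
#'
#' Identical to the unconditional test but with the conditioning dosage
#' vectors appended to the covariates. When the test dosage is collinear
#' with the conditioning set (for example conditioning on the test variant
#' itself), the result is flagged `"collinear_with_conditioning"` and
#' reported with effect 0 and p 1 rather than crashing. With an empty
#' conditioning set the result is identical to the unconditional test.
#'
#' @param dosage Per-sample test dosage.
#' @param trait Trait vector (binary 0/1 or quantitative) or `exb_trait`.
#' @param covariates Optional covariates.
#' @param condition_on Matrix/data frame of conditioning dosage vectors
#'   (columns named by variant id), or NULL.
#' @param kind `"auto"` (binary when the trait is 0/1), `"binary"` or
#'   `"quantitative"`.
#' @param firth_threshold Passed to [test_binary()].
#' @return An `exb_assoc` with `conditioned_on` populated.
#' @export
conditional_test <- function(dosage, trait, covariates = NULL,
                             condition_on = NULL,
                             kind = c("auto", "binary", "quantitative"),
                             firth_threshold = 0.05) {
  kind <- match.arg(kind)
  tv <- if (inherits(trait, "exb_trait")) trait$values else trait
  if (kind == "auto")
    kind <- if (all(tv[!is.na(tv)] %in% c(0, 1))) "binary" else "quantitative"
  run <- function(covs) {
    if (kind == "binary")
      test_binary(dosage, trait, covs, firth_threshold = firth_threshold)
    else test_quantitative(dosage, trait, covs)
  }
  if (is.null(condition_on) || NCOL(condition_on) == 0) return(run(covariates))

  C <- as.matrix(condition_on)
  if (is.null(colnames(C))) colnames(C) <- paste0("cond", seq_len(ncol(C)))
  ids <- colnames(C)
  Z <- .covar_matrix(covariates, length(dosage))
  base <- cbind(1, Z, C)
  resid <- stats::lm.fit(base, dosage)$residuals
  if (stats::var(resid) < 1e-12 * max(stats::var(dosage), 1e-300)) {
    res <- assoc_result(0, NA_real_, 1, sum(dosage > 0, na.rm = TRUE),
                        if (kind == "binary") "score" else "linear",
                        conditioned_on = ids,
                        flags = "collinear_with_conditioning")
    return(res)
  }
  res <- run(cbind(Z, C))
  res$conditioned_on <- ids
  res
}
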