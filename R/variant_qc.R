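# Genotype- and site-level quality filters and the somatic-origin (CHIP)
# screen. All filters are idempotent and only ever increase missingness or
# remove rows/columns; an append-only exclusion log carries machine-readable
# reason codes.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: the probability of the observed heterozygote count
#' plus that of all equally or less probable heterozygote counts, conditional
#' on the allele counts. Probabilities are built by the numerically stable
#' recurrence anchored at the modal heterozygote count (no mid-p
#' adjustment).
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) return(1)
  rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (rare == 0) return(1)
  probs <- numeric(rare + 1)           # index h+1 = prob of h heterozygotes
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if ((mid %% 2) != (rare %% 2)) mid <- mid + 1
  probs[mid + 1] <- 1
  hom_r <- (rare - mid) / 2
  hom_c <- n - mid - hom_r
  h <- mid; hr <- hom_r; hc <- hom_c
  while (h >= 2) {                     # recurse towards fewer heterozygotes
    probs[h - 1] <- probs[h + 1] * h * (h - 1) /
      (4 * (hr + 1) * (hc + 1))
    h <- h - 2; hr <- hr + 1; hc <- hc + 1
  }
  h <- mid; hr <- hom_r; hc <- hom_c
  while (h <= rare - 2) {              # recurse towards more heterozygotes
    probs[h + 3] <- probs[h + 1] * 4 * hr * hc / ((h + 2) * (h + 1))
    h <- h + 2; hr <- hr - 1; hc <- hc - 1
  }
  probs <- probs / sum(probs)
  min(1, sum(probs[probs <= probs[n_het + 1] * (1 + 1e-7)]))
}

#' Per-variant site statistics
#'
#' @param genotypes Samples x variants dosage matrix (0/1/2, NA for
#'   no-calls).
#' @return Data frame with `variant_id`, `mac` (minor allele count), `maf`
#'   (= MAC / (2 x non-missing samples)), `missingness`, `n_carriers`
#'   (samples with at least one alternate allele) and `hwe_p`.
#' @export
site_stats <- function(genotypes) {
  m <- ncol(genotypes)
  out <- data.frame(
    variant_id = colnames(genotypes) %||% sprintf("V%06d", seq_len(m)),
    mac = NA_real_, maf = NA_real_, missingness = NA_real_,
    n_carriers = NA_integer_, hwe_p = NA_real_,
    stringsAsFactors = FALSE
  )
  n <- nrow(genotypes)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    nm <- sum(!is.na(g))
    out$missingness[j] <- 1 - nm / n
    if (nm == 0) next
    alt <- sum(g, na.rm = TRUE)
    out$mac[j] <- min(alt, 2 * nm - alt)
    out$maf[j] <- out$mac[j] / (2 * nm)
    out$n_carriers[j] <- sum(g > 0, na.rm = TRUE)
    out$hwe_p[j] <- hwe_exact_test(sum(g == 0, na.rm = TRUE),
                                   sum(g == 1, na.rm = TRUE),
                                   sum(g == 2, na.rm = TRUE))
  }
  out
}

#' Genotype-level read-depth filter
#'
#' Sets sub-threshold genotype calls to missing: SNV calls with DP < 7 and
#' indel calls with DP < 10. Retained calls are never altered, so the filter
#' is idempotent.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param DP Matching read-depth matrix.
#' @param variant_type Character vector (`"SNV"` or `"indel"`) per variant.
#' @param snv_min,indel_min Minimum retained depth (defaults 7 and 10).
#' @return The dosage matrix with failing calls set to NA.
#' @export
genotype_depth_filter <- function(genotypes, DP, variant_type,
                                  snv_min = 7L, indel_min = 10L) {
  if (!all(variant_type %in% c("SNV", "indel")))
    stop("variant_type must be 'SNV' or 'indel'")
  stopifnot(length(variant_type) == ncol(genotypes),
            all(dim(DP) == dim(genotypes)))
  thr <- ifelse(variant_type == "SNV", snv_min, indel_min)
  fail <- sweep(DP, 2, thr, `<`)
  genotypes[fail] <- NA_integer_
  genotypes
}

#' Variant-level allele-balance filter
#'
#' A variant is retained if it has at least one homozygous-alternate carrier,
#' or at least one heterozygote whose allele balance AB = AD/DP meets the
#' type-specific cutoff (AB >= 0.15 for SNVs, AB >= 0.20 for indels). Should
#' be applied after [genotype_depth_filter()].
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param DP,AD Read depth and alternate-allele depth matrices.
#' @param variant_type `"SNV"`/`"indel"` per variant.
#' @param snv_ab,indel_ab Allele-balance cutoffs.
#' @return Data frame with `variant_id`, `retain` and a `reason` code
#'   (`"pass_hom_alt"`, `"pass_het_ab"`, `"fail_allele_balance"`,
#'   `"fail_no_calls"`).
#' @export
allele_balance_filter <- function(genotypes, DP, AD, variant_type,
                                  snv_ab = 0.15, indel_ab = 0.20) {
  if (!all(variant_type %in% c("SNV", "indel")))
    stop("variant_type must be 'SNV' or 'indel'")
  m <- ncol(genotypes)
  cut <- ifelse(variant_type == "SNV", snv_ab, indel_ab)
  retain <- logical(m); reason <- character(m)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    if (all(is.na(g))) {
      retain[j] <- FALSE; reason[j] <- "fail_no_calls"; next
    }
    if (any(g == 2, na.rm = TRUE)) {
      retain[j] <- TRUE; reason[j] <- "pass_hom_alt"; next
    }
    het <- which(!is.na(g) & g == 1)
    ab <- AD[het, j] / DP[het, j]
    if (length(het) && any(ab >= cut[j], na.rm = TRUE)) {
      retain[j] <- TRUE; reason[j] <- "pass_het_ab"
    } else {
      retain[j] <- FALSE; reason[j] <- "fail_allele_balance"
    }
  }
  data.frame(variant_id = colnames(genotypes) %||% sprintf("V%06d", 1:m),
             retain = retain, reason = reason, stringsAsFactors = FALSE)
}

#' Site- and sample-level matrix filters
#'
#' Removes, in order: variants with missingness > `miss_threshold`; variants
#' with Hardy-Weinberg exact p below `hwe_threshold`; monomorphic variants;
#' then samples with missingness > `miss_threshold` over the remaining
#' variants. Thresholds are strict inequalities. An empty matrix after
#' filtering produces a warning, not an error.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param miss_threshold Missingness threshold (default 0.1).
#' @param hwe_threshold Hardy-Weinberg p-value threshold (default 1e-15).
#' @return List with `genotypes` (filtered matrix) and `exclusions` (data
#'   frame `unit` ("variant"/"sample"), `id`, `reason`).
#' @export
site_filters <- function(genotypes, miss_threshold = 0.1,
                         hwe_threshold = 1e-15) {
  log <- data.frame(unit = character(), id = character(),
                    reason = character(), stringsAsFactors = FALSE)
  add <- function(unit, id, reason) {
    if (length(id))
      log <<- rbind(log, data.frame(unit = unit, id = id, reason = reason,
                                    stringsAsFactors = FALSE))
  }
  vid <- function(g) colnames(g) %||% sprintf("V%06d", seq_len(ncol(g)))
  ss <- site_stats(genotypes)

  drop <- ss$missingness > miss_threshold
  add("variant", vid(genotypes)[drop], "variant_missingness")
  genotypes <- genotypes[, !drop, drop = FALSE]
  ss <- ss[!drop, , drop = FALSE]

  drop <- !is.na(ss$hwe_p) & ss$hwe_p < hwe_threshold
  add("variant", vid(genotypes)[drop], "hwe_failure")
  genotypes <- genotypes[, !drop, drop = FALSE]
  ss <- ss[!drop, , drop = FALSE]

  drop <- is.na(ss$mac) | ss$mac == 0
  add("variant", vid(genotypes)[drop], "monomorphic")
  genotypes <- genotypes[, !drop, drop = FALSE]

  if (ncol(genotypes)) {
    smiss <- rowMeans(is.na(genotypes))
    drop <- smiss > miss_threshold
    sid <- rownames(genotypes) %||% sprintf("S%05d", seq_len(nrow(genotypes)))
    add("sample", sid[drop], "sample_missingness")
    genotypes <- genotypes[!drop, , drop = FALSE]
  }
  if (ncol(genotypes) == 0 || nrow(genotypes) == 0)
    warning("no variants or samples remain after site filters")
  list(genotypes = genotypes, exclusions = log)
}

#' Somatic-origin screen for a variant or burden carrier vector
#'
#' Reports the evidence used to judge whether an association is driven by
#' somatic (CHIP-like) rather than germline variation: the fraction of
#' heterozygous carriers whose variant allele fraction (VAF = AD/DP) lies
#' outside \[0.35, 0.65\], and the logistic-regression association between
#' carrier status and age. The screen reports evidence; it does not
#' classify.
#'
#' @param dosage Per-sample dosage vector (0/1/2, NA allowed).
#' @param dp,ad Per-sample read depth and alternate-allele depth for the
#'   variant (for a burden, the depth evidence of the carried variant).
#' @param age Per-sample age.
#' @param vaf_low,vaf_high Germline VAF band (defaults 0.35 and 0.65).
#' @return A list of class `exb_somatic_report`: `fraction_extreme_vaf`,
#'   `n_het_carriers`, `age_effect`, `age_p`, `flagged` (TRUE when fewer
#'   than 2 carriers leave the regression undefined).
#' @export
somatic_screen <- function(dosage, dp, ad, age,
                           vaf_low = 0.35, vaf_high = 0.65) {
  carrier <- !is.na(dosage) & dosage >= 1
  if (any(carrier & is.na(age)))
    stop("ages must be available for all carriers")
  het <- which(!is.na(dosage) & dosage == 1)
  vaf <- (ad[het] / dp[het])[dp[het] > 0]
  frac <- if (length(vaf)) mean(vaf < vaf_low | vaf > vaf_high) else NA_real_
  n_car <- sum(carrier)
  if (n_car < 2) {
    return(structure(list(fraction_extreme_vaf = frac,
                          n_het_carriers = length(het),
                          age_effect = NA_real_, age_p = NA_real_,
                          flagged = TRUE),
                     class = "exb_somatic_report"))
  }
  # few carriers can separate on age; estimates are still reported as
  # evidence, so convergence chatter is silenced
  fit <- suppressWarnings(stats::glm(carrier ~ age,
                                     family = stats::binomial()))
  cf <- summary(fit)$coefficients
  if (!"age" %in% rownames(cf)) {     # constant age: regression undefined
    return(structure(list(fraction_extreme_vaf = frac,
                          n_het_carriers = length(het),
                          age_effect = NA_real_, age_p = NA_real_,
                          flagged = TRUE),
                     class = "exb_somatic_report"))
  }
  structure(list(fraction_extreme_vaf = frac,
                 n_het_carriers = length(het),
                 age_effect = unname(cf["age", "Estimate"]),
                 age_p = unname(cf["age", "Pr(>|z|)"]),
                 flagged = FALSE),
            class = "exb_somatic_report")
}
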