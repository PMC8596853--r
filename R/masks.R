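# Functional-annotation tiers and gene-burden mask construction: M1 (pLOF
# only) and M3 (pLOF + likely-deleterious missense), each crossed with five
# frequency bins (MAF <= 1%, 0.1%, 0.01%, 0.001%, singletons only).

#' Missense deleteriousness tier from the five-algorithm vote
#'
#' A missense variant is "likely deleterious" if predicted deleterious by all
#' five algorithms, "possibly deleterious" if by at least one, and "likely
#' benign" if by none.
#'
#' @param votes Integer vector of deleterious votes in 0--5.
#' @return Character vector of tiers.
#' @export
classify_missense <- function(votes) {
  if (any(is.na(votes)) || any(votes < 0 | votes > 5) ||
      any(votes != round(votes)))
    stop("votes must be integers in 0..5")
  ifelse(votes == 5, "likely_deleterious",
         ifelse(votes == 0, "likely_benign", "possibly_deleterious"))
}

#' Burden mask definition
#'
#' @param class_set `"M1"` (pLOF only) or `"M3"` (pLOF plus likely
#'   deleterious missense, i.e. missense with all five deleterious votes).
#' @param freq_bin One of `"maf_1pct"`, `"maf_0.1pct"`, `"maf_0.01pct"`,
#'   `"maf_0.001pct"`, `"singleton"`. The singleton bin is defined by carrier
#'   count (exactly one carrier in the dataset, heterozygous or homozygous),
#'   not by frequency.
#' @return A list of class `exb_mask_spec` with the MAF threshold (NA for
#'   the singleton bin).
#' @export
mask_spec <- function(class_set = c("M1", "M3"),
                      freq_bin = c("maf_1pct", "maf_0.1pct", "maf_0.01pct",
                                   "maf_0.001pct", "singleton")) {
  class_set <- match.arg(class_set)
  freq_bin <- match.arg(freq_bin)
  thr <- c(maf_1pct = 0.01, maf_0.1pct = 0.001, maf_0.01pct = 1e-4,
           maf_0.001pct = 1e-5, singleton = NA_real_)[[freq_bin]]
  structure(list(class_set = class_set, freq_bin = freq_bin,
                 maf_threshold = thr),
            class = "exb_mask_spec")
}

#' Select the variants entering a gene burden mask
#'
#' A variant enters the mask if it matches the mask's class set (M1: pLOF;
#' M3: pLOF or 5-vote missense) and its frequency bin. Frequency bins use the
#' in-cohort MAF computed after QC; the singleton bin takes variants carried
#' by exactly one sample (one heterozygote, or one minor-allele homozygote
#' with no other carrier).
#'
#' @param variants Annotation data frame with `variant_id`, `class`, `votes`.
#' @param stats Site statistics from [site_stats()] (needs `variant_id`,
#'   `maf`, `n_carriers`).
#' @param mask A [mask_spec()].
#' @return Character vector of selected variant ids (possibly empty).
#' @export
select_mask_variants <- function(variants, stats, mask) {
  stopifnot(inherits(mask, "exb_mask_spec"))
  plof <- variants$class %in% PLOF_CLASSES
  in_class <- if (mask$class_set == "M1") plof else
    plof | (variants$class == "missense" & !is.na(variants$votes) &
              variants$votes == 5L)
  st <- stats[match(variants$variant_id, stats$variant_id), ]
  in_bin <- if (mask$freq_bin == "singleton") {
    !is.na(st$n_carriers) & st$n_carriers == 1L
  } else {
    !is.na(st$maf) & st$maf <= mask$maf_threshold & st$maf > 0
  }
  variants$variant_id[in_class & in_bin]
}

#' Collapse genotypes over a variant subset into a gene burden genotype
#'
#' Per sample: dosage 0 when homozygous reference at every subset variant,
#' 2 when homozygous alternate at one or more subset variants, otherwise 1
#' when heterozygous at one or more (unphased compound heterozygotes count
#' as heterozygous). Missing genotypes are treated as homozygous reference
#' when `na_as_ref = TRUE` (the default); the number of non-missing calls per
#' sample is recorded.
#'
#' @param genotypes Samples x variants dosage matrix restricted to the mask's
#'   variant subset.
#' @param na_as_ref Treat missing calls as reference (default TRUE).
#' @return Integer dosage vector (one per sample, named) with attributes
#'   `n_carried` (variants with >= 1 alternate allele per sample) and
#'   `n_nonmissing` (non-missing subset calls per sample).
#' @export
collapse_burden <- function(genotypes, na_as_ref = TRUE) {
  if (is.null(dim(genotypes))) genotypes <- cbind(genotypes)
  if (ncol(genotypes) == 0) stop("variant subset is empty")
  G <- genotypes
  n_nonmiss <- rowSums(!is.na(G))
  if (na_as_ref) G[is.na(G)] <- 0L
  any_hom <- rowSums(G == 2L, na.rm = TRUE) > 0
  any_het <- rowSums(G == 1L, na.rm = TRUE) > 0
  dose <- ifelse(any_hom, 2L, ifelse(any_het, 1L, 0L))
  if (!na_as_ref) dose[rowSums(is.na(genotypes)) == ncol(genotypes)] <- NA
  dose <- as.integer(dose)
  names(dose) <- rownames(genotypes)
  attr(dose, "n_carried") <- as.integer(rowSums(G >= 1L, na.rm = TRUE))
  attr(dose, "n_nonmissing") <- as.integer(n_nonmiss)
  dose
}

#' Minor-allele-count filter for a burden (or single-variant) genotype
#'
#' A test is performed only when the collapsed minor allele count is at
#' least `min_mac` (default 5).
#'
#' @param dosage Burden or variant dosage vector.
#' @param min_mac Minimum minor allele count.
#' @return TRUE (keep) or FALSE (skip).
#' @export
burden_mac_filter <- function(dosage, min_mac = 5L) {
  sum(dosage, na.rm = TRUE) >= min_mac
}

#' Sex-aware dosage encoding for chromosome X
#'
#' Applies the dosage-compensation model for the non-pseudoautosomal X: male
#' samples are coded 0 when homozygous reference and 2 when carrying the
#' alternate allele (hemizygous). Autosomal variants and female samples are
#' unchanged.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param sex Character vector per sample (`"M"`/`"F"`).
#' @param chrom Chromosome per variant.
#' @param x_chrom Chromosome label(s) treated as X (default `c("X","chrX")`).
#' @return Recoded dosage matrix.
#' @export
encode_chrx <- function(genotypes, sex, chrom, x_chrom = c("X", "chrX")) {
  stopifnot(length(sex) == nrow(genotypes),
            length(chrom) == ncol(genotypes))
  male <- sex == "M"
  xv <- chrom %in% x_chrom
  if (any(male) && any(xv)) {
    sub <- genotypes[male, xv, drop = FALSE]
    sub[!is.na(sub) & sub >= 1] <- 2L
    genotypes[male, xv] <- sub
  }
  genotypes
}
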