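# VCF and TSV round-trips for the pipeline's tables. VCF reading/writing is
# delegated to vcfR; per-call read evidence travels in the DP and AD FORMAT
# fields (AD as ref,alt depths).

#' Write cohort genotypes and read evidence to VCF
#'
#' @param cohort An `exb_cohort` (or compatible list with `genotypes`,
#'   `variants`, and optionally `DP`/`AD`).
#' @param file Output path; `.vcf.gz` is appended behaviourally by vcfR's
#'   writer, so a path ending in `.vcf.gz` is recommended.
#' @return `file`, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_cohort_vcf <- function(cohort, file) {
  G <- cohort$genotypes
  v <- cohort$variants
  n <- nrow(G); m <- ncol(G)
  stopifnot(m == nrow(v))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">"
  )
  fix <- cbind(CHROM = v$chrom, POS = as.character(v$pos), ID = v$variant_id,
               REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = "PASS",
               INFO = ".")
  gt_code <- c("0/0", "0/1", "1/1")
  gmat <- matrix(".", n, m)
  ok <- !is.na(G)
  gmat[ok] <- gt_code[G[ok] + 1L]
  gmat[!ok] <- "./."
  if (!is.null(cohort$DP) && !is.null(cohort$AD)) {
    dp <- cohort$DP; ad <- cohort$AD
    cells <- paste0(gmat, ":", dp, ":", dp - ad, ",", ad)
  } else {
    cells <- gmat
  }
  cell_mat <- t(matrix(cells, n, m, dimnames = dimnames(G)))
  gt <- cbind(FORMAT = if (is.null(cohort$DP)) "GT" else "GT:DP:AD",
              cell_mat)
  colnames(gt) <- c("FORMAT", rownames(G))
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = file)
  invisible(file)
}

#' Read genotypes and read evidence from a VCF
#'
#' @param file Path to a VCF (optionally gzipped) with GT and, optionally,
#'   DP/AD FORMAT fields.
#' @return List with `genotypes` (samples x variants dosage matrix, NA for
#'   no-calls), `DP`, `AD` (alternate-allele depths; NULL when absent) and
#'   `variants` (CHROM/POS/ID/REF/ALT data frame).
#' @export
read_cohort_vcf <- function(file) {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L
  DP <- AD <- NULL
  fmt <- vcf@gt[1, "FORMAT"]
  if (grepl("DP", fmt)) {
    dpc <- vcfR::extract.gt(vcf, element = "DP")
    DP <- matrix(as.integer(dpc), nrow(dpc), ncol(dpc),
                 dimnames = dimnames(dpc))
    DP <- t(DP)
  }
  if (grepl("AD", fmt)) {
    adc <- vcfR::extract.gt(vcf, element = "AD")
    AD <- matrix(vapply(strsplit(as.vector(adc), ","),
                        function(x) as.integer(x[2]), integer(1)),
                 nrow(adc), ncol(adc), dimnames = dimnames(adc))
    AD <- t(AD)
  }
  fx <- as.data.frame(vcf@fix[, c("CHROM", "POS", "ID", "REF", "ALT"),
                              drop = FALSE], stringsAsFactors = FALSE)
  fx$POS <- as.integer(fx$POS)
  list(genotypes = t(dose),
       DP = DP, AD = AD, variants = fx)
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_table_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV written by [write_table_tsv()]
#'
#' @param file Input path.
#' @return Data frame.
#' @export
read_table_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
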