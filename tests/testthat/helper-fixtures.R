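# Shared fixture builders: everything is generated in code at test time.

# a minimal cohort-shaped list from a plain genotype matrix
make_cohort <- function(G, classes = NULL, votes = NULL, sex = NULL,
                        age = NULL) {
  n <- nrow(G); m <- ncol(G)
  if (is.null(colnames(G))) colnames(G) <- sprintf("V%06d", seq_len(m))
  if (is.null(rownames(G))) rownames(G) <- sprintf("S%05d", seq_len(n))
  if (is.null(classes)) classes <- rep("missense", m)
  if (is.null(votes)) votes <- ifelse(classes == "missense", 5L, NA_integer_)
  list(
    genotypes = G,
    variants = data.frame(
      variant_id = colnames(G), chrom = "1", pos = seq_len(m) * 100L,
      ref = "A", alt = "G", gene_id = "G0001", class = classes,
      votes = votes, type = "SNV", is_somatic = FALSE,
      stringsAsFactors = FALSE),
    samples = data.frame(
      sample_id = rownames(G),
      sex = sex %||% rep("F", n),
      age = age %||% rep(55L, n), stringsAsFactors = FALSE),
    genes = data.frame(gene_id = "G0001", chrom = "1", start = 1L,
                       end = m * 100L + 1L, stringsAsFactors = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard small generated cohort reused across tests
default_test_cohort <- function(seed = 42L) {
  gen_cohort(cohort_spec(n_samples = 400, n_genes = 6,
                         variants_per_gene = 12, seed = seed))
}
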