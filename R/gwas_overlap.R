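# GWAS-locus machinery: sentinel pruning, gene-set assignment around
# sentinels, per-trait 2x2 enrichment folds combined across traits by the
# Mantel-Haenszel method, expected-by-chance overlap arithmetic, generic
# 2x2 odds ratios, and trait-to-disease matching from a genetic-correlation
# table.

#' Prune GWAS sentinels to a minimum pairwise separation
#'
#' Greedy selection per trait by ascending p-value: a signal is kept only if
#' it lies strictly more than `min_separation` base pairs from every
#' already-kept signal on the same chromosome, ensuring each gene can be
#' matched to at most one sentinel.
#'
#' @param signals Data frame with `trait_id`, `chrom`, `pos`, `p`.
#' @param min_separation Minimum separation in bp (default 10 Mb).
#' @return The pruned subset, in the original row order.
#' @export
prune_signals <- function(signals, min_separation = 1e7) {
  keep <- logical(nrow(signals))
  for (tr in unique(signals$trait_id)) {
    idx <- which(signals$trait_id == tr)
    idx <- idx[order(signals$p[idx])]
    kept <- integer(0)
    for (i in idx) {
      same <- kept[signals$chrom[kept] == signals$chrom[i]]
      if (!length(same) ||
          all(abs(signals$pos[same] - signals$pos[i]) > min_separation)) {
        kept <- c(kept, i)
      }
    }
    keep[kept] <- TRUE
  }
  signals[keep, , drop = FALSE]
}

# minimum distance from a position to a closed gene interval (0 if inside)
.gene_distance <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos > end, pos - end, 0))
}

#' Assign genes to in-window / out-of-window sets around GWAS sentinels
#'
#' Distance is the minimum base-pair distance from the sentinel position to
#' the gene's closed interval (0 when the sentinel falls inside the gene).
#' Under the `"within"` rule a gene is in-set when its distance to any of the
#' trait's sentinels is at most `d`; under the `"nearest"` rule the in-set is
#' the union, over the trait's sentinels, of each sentinel's `k` nearest
#' genes. Genes on chromosomes without signals for a trait fall in the
#' out-set.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param signals Pruned signal data frame (`trait_id`, `chrom`, `pos`).
#' @param rule List: `list(type = "within", d = <bp>)` or
#'   `list(type = "nearest", k = <count>)`.
#' @return Data frame (`trait_id`, `gene_id`, `in_set`).
#' @export
assign_gene_set <- function(genes, signals, rule = list(type = "within",
                                                        d = 1e6)) {
  stopifnot(rule$type %in% c("within", "nearest"))
  out <- lapply(unique(signals$trait_id), function(tr) {
    sg <- signals[signals$trait_id == tr, , drop = FALSE]
    in_set <- logical(nrow(genes))
    for (ch in unique(sg$chrom)) {
      gi <- which(genes$chrom == ch)
      if (!length(gi)) next
      sp <- sg$pos[sg$chrom == ch]
      D <- vapply(sp, function(p)
        .gene_distance(p, genes$start[gi], genes$end[gi]),
        numeric(length(gi)))
      D <- matrix(D, nrow = length(gi))
      if (rule$type == "within") {
        in_set[gi] <- in_set[gi] | apply(D <= rule$d, 1, any)
      } else {
        k <- min(rule$k %||% 1, length(gi))
        for (s in seq_along(sp)) {
          nearest <- gi[order(D[, s])[seq_len(k)]]
          in_set[nearest] <- TRUE
        }
      }
    }
    data.frame(trait_id = tr, gene_id = genes$gene_id, in_set = in_set,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fold-enrichment of a single 2x2 stratum
#'
#' Returns `(a/b) / (c/d)` for a stratum with `a` in-window significant
#' genes, `b` in-window non-significant, `c` out-of-window significant and
#' `d` out-of-window non-significant. The fold is undefined (flagged) when
#' `b = 0` or `c = 0`; no continuity correction is applied.
#'
#' @param a,b,c,d Stratum counts.
#' @return List with `fold` (NA when undefined) and `defined`.
#' @export
enrichment_fold <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (b == 0 || c == 0)
    return(list(fold = NA_real_, defined = FALSE))
  list(fold = (a / b) / (c / d), defined = TRUE)
}

#' Mantel-Haenszel combination of stratified 2x2 tables
#'
#' Combined odds ratio `sum(a d / n) / sum(b c / n)`, the 1-df
#' Mantel-Haenszel chi-square statistic (without continuity correction by
#' default) and a confidence interval from the Robins-Breslow-Greenland
#' variance of the log odds ratio.
#'
#' @param strata Data frame or matrix with columns `a`, `b`, `c`, `d`.
#' @param correct Apply the 0.5 continuity correction to the chi-square
#'   (default FALSE).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `ci`, `chisq`, `p`, `n_strata`.
#' @export
mantel_haenszel <- function(strata, correct = FALSE, conf_level = 0.95) {
  s <- as.data.frame(strata)
  stopifnot(all(c("a", "b", "c", "d") %in% names(s)))
  n <- s$a + s$b + s$c + s$d
  use <- n > 0
  if (!any(use)) stop("all strata are degenerate")
  s <- s[use, ]; n <- n[use]
  R <- s$a * s$d / n
  S <- s$b * s$c / n
  if (sum(R) == 0 && sum(S) == 0) stop("all strata are degenerate")
  or <- sum(R) / sum(S)

  # chi-square on the a-cell margins
  E <- (s$a + s$b) * (s$a + s$c) / n
  V <- (s$a + s$b) * (s$c + s$d) * (s$a + s$c) * (s$b + s$d) /
    (n^2 * pmax(n - 1, 1))
  dev <- abs(sum(s$a) - sum(E))
  if (correct) dev <- max(dev - 0.5, 0)
  chisq <- dev^2 / sum(V)
  p <- stats::pchisq(chisq, 1, lower.tail = FALSE)

  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (s$a + s$d) / n
  Q <- (s$b + s$c) / n
  sR <- sum(R); sS <- sum(S)
  var_log <- sum(P * R) / (2 * sR^2) +
    sum(P * S + Q * R) / (2 * sR * sS) +
    sum(Q * S) / (2 * sS^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * sqrt(var_log))
  list(or = or, ci = ci, chisq = chisq, p = p, n_strata = nrow(s))
}

#' Expected number of significant associations in GWAS windows by chance
#'
#' The chance expectation is `p_hat * k_tests`, where `p_hat = a_sig /
#' n_tests` is the overall proportion of significant tests and `k_tests` is
#' the number of tests within the GWAS windows. `p_hat` may optionally be
#' rounded to 3 significant figures before multiplying, reproducing
#' published-table arithmetic; the default uses the unrounded proportion.
#'
#' @param a_sig Total significant associations.
#' @param n_tests Total association tests performed.
#' @param k_tests In-window association tests.
#' @param round_p Round `p_hat` to 3 significant figures first (default
#'   FALSE).
#' @return A list of class `exb_chance`: `p_hat_raw`, `p_hat` (possibly
#'   rounded), `k_tests`, `expected`.
#' @export
expected_by_chance <- function(a_sig, n_tests, k_tests, round_p = FALSE) {
  stopifnot(a_sig >= 0, n_tests > 0, a_sig <= n_tests, k_tests >= 0)
  p_raw <- a_sig / n_tests
  p_hat <- if (round_p) signif(p_raw, 3) else p_raw
  structure(list(p_hat_raw = p_raw, p_hat = p_hat, k_tests = k_tests,
                 expected = p_hat * k_tests),
            class = "exb_chance")
}

#' Sample odds ratio and Fisher exact p for a 2x2 table
#'
#' @param n11,n12,n21,n22 Table counts (rows: group, columns: outcome).
#' @return List with `or` (sample odds ratio `n11 n22 / (n12 n21)`; NA with
#'   `defined = FALSE` when a denominator cell is 0) and the two-sided
#'   Fisher exact `p`.
#' @export
two_by_two_or <- function(n11, n12, n21, n22) {
  stopifnot(n11 >= 0, n12 >= 0, n21 >= 0, n22 >= 0)
  tab <- matrix(c(n11, n12, n21, n22), 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  if (n12 == 0 || n21 == 0)
    return(list(or = NA_real_, defined = FALSE, p = p))
  list(or = (n11 * n22) / (n12 * n21), defined = TRUE, p = p)
}

#' Match quantitative traits to their most genetically correlated disease
#'
#' For each trait, diseases with genetic-correlation p-value below
#' `0.05 / denominator` are eligible and the one with the smallest p-value
#' is selected; traits with no eligible disease are left unmatched.
#'
#' @param rg_table Data frame with `trait_id`, `disease_id`, `rg`, `p`.
#' @param denominator Bonferroni denominator (default 357, the number of
#'   candidate disease outcomes).
#' @return Data frame (`trait_id`, `disease_id`, `rg`, `p`, `matched`), one
#'   row per trait; unmatched traits carry NA disease fields.
#' @export
match_trait_to_disease <- function(rg_table, denominator = 357) {
  thr <- 0.05 / denominator
  out <- lapply(unique(rg_table$trait_id), function(tr) {
    sub <- rg_table[rg_table$trait_id == tr & rg_table$p < thr, ,
                    drop = FALSE]
    if (!nrow(sub))
      return(data.frame(trait_id = tr, disease_id = NA_character_,
                        rg = NA_real_, p = NA_real_, matched = FALSE,
                        stringsAsFactors = FALSE))
    best <- sub[which.min(sub$p), ]
    data.frame(trait_id = tr, disease_id = best$disease_id, rg = best$rg,
               p = best$p, matched = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Screen quantitative-trait associations for protective disease effects
#'
#' Four-step filter over gene-trait quantitative associations: (1) the trait
#' has a known beneficial direction; (2) the association's effect direction
#' is favourable (its sign equals the beneficial direction); (3) the trait
#' is matched to a genetically correlated disease; (4) the gene's
#' association with that disease is protective (negative log-odds) and
#' significant at `alpha`.
#'
#' @param quant_results Data frame `gene_id`, `trait_id`, `effect`, `p`.
#' @param beneficial Data frame `trait_id`, `direction` (+1 when higher
#'   trait values are beneficial, -1 when lower; traits absent or NA have no
#'   consensus direction).
#' @param matches Output of [match_trait_to_disease()].
#' @param disease_results Data frame `gene_id`, `disease_id`, `logor`, `p`.
#' @param alpha Disease-association significance level (default 0.05/129).
#' @return List with `candidates` (surviving rows joined with disease
#'   results) and `counts` (rows surviving each step).
#' @export
screen_protective <- function(quant_results, beneficial, matches,
                              disease_results, alpha = 0.05 / 129) {
  q <- quant_results
  dir <- beneficial$direction[match(q$trait_id, beneficial$trait_id)]
  step1 <- !is.na(dir)
  q1 <- q[step1, , drop = FALSE]; d1 <- dir[step1]

  step2 <- sign(q1$effect) == d1
  q2 <- q1[step2, , drop = FALSE]

  dz <- matches$disease_id[match(q2$trait_id, matches$trait_id)]
  step3 <- !is.na(dz)
  q3 <- q2[step3, , drop = FALSE]; dz3 <- dz[step3]

  key <- paste(q3$gene_id, dz3)
  dr <- disease_results[match(key, paste(disease_results$gene_id,
                                         disease_results$disease_id)), ]
  step4 <- !is.na(dr$logor) & dr$logor < 0 & dr$p < alpha
  cand <- cbind(q3[step4, , drop = FALSE],
                disease_id = dz3[step4],
                disease_logor = dr$logor[step4],
                disease_p = dr$p[step4])
  list(candidates = cand,
       counts = c(known_direction = nrow(q1), favourable = nrow(q2),
                  matched = nrow(q3), protective = sum(step4)))
}
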