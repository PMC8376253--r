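#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Point-probability two-sided rule: the p-value is the sum of
#' hypergeometric probabilities of every table with the observed margins
#' whose probability does not exceed that of the observed table. For the
#' within-litter table \[\[5,0\],\[0,5\]\] this gives 2/252 = 0.0079.
#'
#' @param t 2x2 matrix (or length-4 vector, row-major) of nonnegative
#'   integer cells.
#' @return The two-tailed p-value.
#' @export
#' @examples
#' fisher_exact_two_tailed(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
fisher_exact_two_tailed <- function(t) {
  if (!is.matrix(t)) t <- matrix(as.numeric(t), 2L, 2L, byrow = TRUE)
  if (!all(dim(t) == 2L)) sv_stop("need a 2x2 table")
  if (any(t < 0) || any(t != floor(t))) sv_stop("cells must be nonnegative integers")
  if (sum(t) == 0) sv_stop("all-zero table")
  stats::fisher.test(t)$p.value
}

#' Within-litter smallest-male concordance test
#'
#' For litters containing at least one male of each of two genotypes (e.g.
#' *Naa10* +/Y and *Naa10* -/Y), records which genotype held the smallest
#' body weight, builds the 2x2 table \[\[k, n-k\], \[n-k, k\]\] (mutant-smallest
#' vs wildtype-smallest against the complementary classification) and applies
#' the two-tailed Fisher exact test. With the mutant smallest in all 5 of 5
#' litters this reproduces p = 0.0079.
#'
#' @param smallest character vector, one entry per qualifying litter:
#'   `"mutant"` if the mutant-genotype male was the smallest, `"wildtype"`
#'   otherwise. (A logical vector, `TRUE` = mutant smallest, also works.)
#' @return List with the contingency `table`, `n_litters`, `k_mutant` and
#'   `p_value`.
#' @export
#' @examples
#' runt_concordance(rep("mutant", 5))$p_value          # 0.0079
#' runt_concordance(c(rep("mutant", 12), "wildtype"))  # p < 1e-4
runt_concordance <- function(smallest) {
  if (is.logical(smallest))
    smallest <- ifelse(smallest, "mutant", "wildtype")
  if (!length(smallest)) sv_stop("no qualifying litters")
  if (!all(smallest %in% c("mutant", "wildtype")))
    sv_stop("entries must be 'mutant' or 'wildtype'")
  n <- length(smallest)
  k <- sum(smallest == "mutant")
  tab <- matrix(c(k, n - k, n - k, k), 2L, 2L, byrow = TRUE,
                dimnames = list(classification = c("mutant_smallest", "wildtype_smallest"),
                                complement = c("mutant", "wildtype")))
  list(table = tab, n_litters = n, k_mutant = k,
       p_value = fisher_exact_two_tailed(tab))
}
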