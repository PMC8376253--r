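#' Survival-adjusted genotype frequencies
#'
#' Renormalizes the Mendelian fractions Mx of a cross under genotype- and
#' age-specific cumulative survival Sx, giving the frequency of each class
#' among the offspring expected to be present (live, or at least intact) at
#' that age:
#' \deqn{G_x = \frac{M_x S_x}{1 - \sum_j (1 - S_j) M_j} = \frac{M_x S_x}{\sum_j M_j S_j}.}
#' The denominator is the total fractional survival of the litter; the
#' adjusted frequencies always sum to 1. With full survival (all Sx = 1) the
#' Mendelian distribution is recovered exactly.
#'
#' @param M a `mendelian_distribution` from [enumerate_offspring()].
#' @param S a [survival_schedule()] covering the same class numbers.
#' @param age one age-stage label (see [age_stages()]).
#' @return Named numeric vector Gx over class numbers (sums to 1).
#' @export
#' @examples
#' cr <- cross_spec("cross1", dam = c(Naa10 = "+/-", Naa12 = "+/-"),
#'                  sire = c(Naa10 = "+/Y", Naa12 = "+/-"))
#' M <- enumerate_offspring(cr)
#' adjusted_frequencies(M, model_preset("B"), "E10.5")[["5"]]  # 2/15
adjusted_frequencies <- function(M, S, age) {
  age <- normalize_age(age)
  stopifnot(length(age) == 1L)
  cls <- as.character(M$class_number)
  if (!all(cls %in% rownames(S)))
    sv_stop("survival schedule does not cover all classes of the distribution")
  m <- M$mendelian_fraction
  s <- unclass(S)[cls, age]
  denom <- sum(m * s)
  if (denom <= 0) sv_stop("no surviving genotypes: total fractional survival is 0")
  stats::setNames(m * s / denom, cls)
}

#' Expected genotype counts at one age
#'
#' @param G adjusted frequencies from [adjusted_frequencies()].
#' @param n_genotyped number of genotyped offspring observed at that age.
#' @return Named numeric vector of expected counts (sums to `n_genotyped`).
#' @export
expected_counts <- function(G, n_genotyped) {
  if (n_genotyped < 0) sv_stop("n_genotyped must be >= 0")
  G * n_genotyped
}

#' Cumulative expected counts across harvest ages
#'
#' Each embryonic age is a distinct cross-sectional sample (a different set of
#' litters), so cumulative expectations up to an age are the plain sum of the
#' per-age expectations.
#'
#' @param per_age named list of per-age expected-count vectors (names are age
#'   labels), all over the same class set.
#' @param up_to stage label: include all ages at or before this one.
#' @return Named numeric vector of cumulative expected counts.
#' @export
cumulative_expected <- function(per_age, up_to = NULL) {
  ages <- normalize_age(names(per_age))
  if (is.null(up_to)) up_to <- ages[which.max(age_rank(ages))]
  keep <- age_rank(ages) <= age_rank(up_to)
  if (!any(keep)) sv_stop("no ages at or before ", up_to)
  cls <- names(per_age[[1]])
  if (!all(vapply(per_age, function(e) identical(names(e), cls), TRUE)))
    sv_stop("per-age tables must share one class set")
  Reduce(`+`, per_age[keep])
}

#' Implied litter size under genotype-specific mortality
#'
#' Genotype-specific loss shrinks litters: the total fractional survival of a
#' cross at an age is \eqn{\sum_x M_x S_x}. Dividing an observed (post-loss)
#' mean litter size by it recovers the implied litter size at conception;
#' multiplying a reference wildtype litter size by it projects the litter
#' size the schedule predicts.
#'
#' @param mean_observed_litter observed mean litter size (pups); must be > 0.
#' @param M a `mendelian_distribution`.
#' @param S a [survival_schedule()].
#' @param age stage at which the litters were observed.
#' @param reference_wt_litter optional wildtype-cross mean litter size used
#'   for the forward projection.
#' @return List with `survival_fraction`, `conception_litter` and (when a
#'   reference is given) `predicted_litter`.
#' @export
#' @examples
#' cr <- cross_spec("cross1", dam = c(Naa10 = "+/-", Naa12 = "+/-"),
#'                  sire = c(Naa10 = "+/Y", Naa12 = "+/-"))
#' implied_litter_size(4.9, enumerate_offspring(cr), model_preset("D4"),
#'                     "P3", reference_wt_litter = 8.6)
implied_litter_size <- function(mean_observed_litter, M, S, age,
                                reference_wt_litter = NULL) {
  if (mean_observed_litter <= 0) sv_stop("mean_observed_litter must be > 0")
  age <- normalize_age(age)
  cls <- as.character(M$class_number)
  sf <- sum(M$mendelian_fraction * unclass(S)[cls, age])
  if (sf <= 0) sv_stop("total fractional survival is 0")
  out <- list(survival_fraction = sf,
              conception_litter = mean_observed_litter / sf)
  if (!is.null(reference_wt_litter))
    out$predicted_litter <- reference_wt_litter * sf
  out
}
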