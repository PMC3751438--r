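# Somatic loss of heterozygosity: heterozygous in the normal genome,
# homozygous (in either direction) in the tumor genome.

#' Probability of somatic loss of heterozygosity from paired pileup counts
#'
#' Scores the joint event "the normal genome is heterozygous and the tumor
#' genome is not":
#' \deqn{P(\mathrm{LOH}) = P(\mathrm{het}_n \mid D_n) \times
#'   P(\neg\mathrm{het}_t \mid \mathrm{het}_n, D_t)}
#' Here `k` counts the non-reference allele of the candidate heterozygous
#' site in each sample. The first factor is the heterozygous component of
#' [germline_posterior()]. The second compares the two homozygous directions
#' (likelihoods under the reference- and variant-homozygous betas, summed)
#' against the heterozygous model, weighted by `pi_loh`:
#' \deqn{P(\neg\mathrm{het}_t \mid \cdot) =
#'   \frac{\pi_{LOH} L_{hom}}{\pi_{LOH} L_{hom} + (1 - \pi_{LOH}) L_{het}}}
#'
#' By default the heterozygous-tumor likelihood uses the flat
#' (`alpha_nonhom`, `beta_nonhom`) beta *without* updating it by the normal
#' counts: the relative alignment affinity of the two alleles shifts
#' systematically between datasets, and propagating the normal sample's exact
#' allele ratio into the tumor expectation inflates the false-positive rate.
#' Set `update_het = TRUE` to conjugately update the heterozygous expectation
#' by the normal counts instead; this sharply increases the probability
#' assigned to genuine losses (the flat model caps the posterior near
#' `700 * pi_loh`) at the cost of sensitivity to those systematic shifts.
#'
#' @param data A data frame with columns `n_normal`, `k_normal`, `n_tumor`,
#'   `k_tumor` (`k` = non-reference-allele counts).
#' @param priors A [pair_priors()] object.
#' @param update_het Conjugately update the heterozygous-tumor beta with the
#'   normal counts (default `FALSE`, see Details).
#' @param min_coverage Coverage gate applied to both samples.
#' @return The input tibble with columns `p_loh` and `retained_allele`
#'   (`"ref"` or `"alt"`, the homozygous direction favoured by the tumor
#'   counts) appended. Gated rows get `NA`.
#' @examples
#' loh_probability(
#'   tibble::tibble(n_normal = 60, k_normal = 30, n_tumor = 60, k_tumor = 0),
#'   update_het = TRUE
#' )
#' @export
loh_probability <- function(data, priors = pair_priors(), update_het = FALSE,
                            min_coverage = 5) {
  stopifnot(
    is.data.frame(data),
    all(c("n_normal", "k_normal", "n_tumor", "k_tumor") %in% names(data))
  )
  stopifnot(inherits(priors, "pair_priors"))
  out <- tibble::as_tibble(data)
  if (nrow(out) == 0L) {
    return(dplyr::mutate(out, p_loh = numeric(0), retained_allele = character(0)))
  }
  covered <- out$n_normal >= min_coverage & out$n_tumor >= min_coverage
  p <- rep(NA_real_, nrow(out))
  retained <- rep(NA_character_, nrow(out))
  if (any(covered)) {
    n_n <- out$n_normal[covered]
    k_n <- out$k_normal[covered]
    n_t <- out$n_tumor[covered]
    k_t <- out$k_tumor[covered]

    p_het_n <- germline_posterior(pileup_summary(n_n, k_n), priors)$p_het

    l_hom_ref <- beta_binomial_pmf(n_t, k_t, priors$alpha_ref, priors$beta_ref, log = TRUE)
    l_hom_var <- beta_binomial_pmf(n_t, k_t, priors$alpha_var, priors$beta_var, log = TRUE)
    l_hom <- row_log_sum_exp(cbind(l_hom_ref, l_hom_var))
    if (update_het) {
      l_het <- beta_binomial_pmf(
        n_t, k_t,
        priors$alpha_nonhom + k_n, priors$beta_nonhom + (n_n - k_n),
        log = TRUE
      )
    } else {
      l_het <- beta_binomial_pmf(n_t, k_t, priors$alpha_nonhom, priors$beta_nonhom, log = TRUE)
    }
    num <- log(priors$pi_loh) + l_hom
    den <- row_log_sum_exp(cbind(num, log(1 - priors$pi_loh) + l_het))
    p[covered] <- exp(log(p_het_n) + num - den)
    retained[covered] <- ifelse(l_hom_var > l_hom_ref, "alt", "ref")
  }
  dplyr::mutate(out, p_loh = p, retained_allele = retained)
}
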