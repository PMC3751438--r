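# Somatic point-mutation / small-indel scoring: the joint probability that
# the normal genome is reference-homozygous and the tumor genome is not,
# with the tumor's reference model conjugately updated by the normal counts.

#' Phred-scaled quality of a posterior probability
#'
#' `-10 * log10(1 - p)`, capped (default 255) so that probabilities at or
#' near 1 stay representable.
#'
#' @param probability Posterior probabilities in `[0, 1]`.
#' @param cap Maximum quality.
#' @return Numeric Phred qualities.
#' @examples
#' phred_quality(c(0.9, 0.99, 1))
#' @export
phred_quality <- function(probability, cap = 255) {
  if (any(probability < 0 | probability > 1, na.rm = TRUE)) {
    rlang::abort("probability must lie in [0, 1]")
  }
  pmin(-10 * log10(1 - probability), cap)
}

# Tumor-side posterior that the tumor is NOT reference-homozygous, given a
# reference-homozygous normal. The tumor genotype classes are reduced to
# {reference-homozygous, somatic variant}: the somatic class uses the
# uninformative beta (no allele fraction presumed), the reference class uses
# the error-skewed beta updated by the normal counts.
log_p_nonref_tumor <- function(n_n, k_n, n_t, k_t, priors) {
  l_som <- beta_binomial_pmf(n_t, k_t, priors$alpha_somatic, priors$beta_somatic, log = TRUE)
  l_ref <- beta_binomial_pmf(
    n_t, k_t,
    priors$alpha_ref + k_n, priors$beta_ref + (n_n - k_n),
    log = TRUE
  )
  num <- log(priors$pi_somatic) + l_som
  den <- row_log_sum_exp(cbind(num, log(1 - priors$pi_somatic) + l_ref))
  num - den
}

#' Probability of a somatic variant from paired pileup counts
#'
#' Scores the joint event "the normal genome matches the reference and the
#' tumor genome does not":
#' \deqn{P(\mathrm{somatic}) = P(\mathrm{ref}_n \mid D_n) \times
#'   P(\neg\mathrm{ref}_t \mid \mathrm{ref}_n, D_n, D_t)}
#' The first factor is the reference-homozygous component of
#' [germline_posterior()]. The second reduces the tumor genotype classes to
#' reference-homozygous versus somatic variant; the somatic likelihood uses
#' the uninformative beta (`alpha_somatic`, `beta_somatic`) so no tumor
#' allele fraction is presumed, while the reference likelihood uses the
#' error-model beta conjugately updated by the normal counts
#' (`alpha_ref + K_n`, `beta_ref + N_n - K_n`) — which is why additional
#' normal coverage sharpens both rejection of false positives and detection
#' of low-frequency variants.
#'
#' Rows where either sample fails the coverage gate get `NA` (the site is
#' skipped, not an error).
#'
#' @param data A data frame with columns `n_normal`, `k_normal`, `n_tumor`,
#'   `k_tumor` — trial/success counts for the tested evidence subclass in
#'   each sample.
#' @param priors A [pair_priors()] object.
#' @param min_coverage Minimum filtered trials required in each sample
#'   (default 5).
#' @return The input tibble with a `p_somatic` column appended.
#' @examples
#' somatic_probability(
#'   tibble::tibble(n_normal = 60, k_normal = 0, n_tumor = 60, k_tumor = 30)
#' )
#' @export
somatic_probability <- function(data, priors = pair_priors(), min_coverage = 5) {
  stopifnot(
    is.data.frame(data),
    all(c("n_normal", "k_normal", "n_tumor", "k_tumor") %in% names(data))
  )
  stopifnot(inherits(priors, "pair_priors"))
  out <- tibble::as_tibble(data)
  if (nrow(out) == 0L) return(dplyr::mutate(out, p_somatic = numeric(0)))
  covered <- out$n_normal >= min_coverage & out$n_tumor >= min_coverage
  p <- rep(NA_real_, nrow(out))
  if (any(covered)) {
    n_n <- out$n_normal[covered]
    k_n <- out$k_normal[covered]
    n_t <- out$n_tumor[covered]
    k_t <- out$k_tumor[covered]
    gp <- germline_posterior(pileup_summary(n_n, k_n), priors)
    lp <- log(gp$p_ref) + log_p_nonref_tumor(n_n, k_n, n_t, k_t, priors)
    p[covered] <- exp(lp)
  }
  dplyr::mutate(out, p_somatic = p)
}

#' Score one locus from raw read observations
#'
#' The full per-locus pipeline: quality-filter both samples' observations,
#' enumerate candidate variant subclasses from the tumor pileup, score each
#' with [somatic_probability()], and emit the best-scoring subclass as a call
#' when its posterior exceeds the emission threshold. The strand-bias filter,
#' when enabled, is recorded in `filters_failed` rather than suppressing the
#' record, so downstream consumers can re-filter.
#'
#' @param contig,position Locus coordinates (`position` is 1-based).
#' @param reference_base Reference base at the locus.
#' @param normal_observations,tumor_observations Observation tibbles from
#'   [read_observations()].
#' @param priors A [pair_priors()] object.
#' @param min_coverage Coverage gate applied to both filtered pileups.
#' @param min_mapping_quality,min_base_quality,use_adjusted_quality Passed to
#'   [filter_observations()].
#' @param strand_filter Apply the strand-bias filter to the call's tumor
#'   variant observations.
#' @param emission_threshold Minimum posterior probability to emit a call.
#' @param phred_cap Quality cap for [phred_quality()].
#' @return A one-row tibble (a somatic call) or `NULL` when no subclass
#'   reaches the emission threshold or the locus fails the coverage gate.
#' @export
call_site <- function(contig, position, reference_base,
                      normal_observations, tumor_observations,
                      priors = pair_priors(),
                      min_coverage = 5,
                      min_mapping_quality = 10,
                      min_base_quality = 10,
                      use_adjusted_quality = FALSE,
                      strand_filter = TRUE,
                      emission_threshold = 0.5,
                      phred_cap = 255) {
  nobs <- filter_observations(
    normal_observations, min_mapping_quality, min_base_quality, use_adjusted_quality
  )
  tobs <- filter_observations(
    tumor_observations, min_mapping_quality, min_base_quality, use_adjusted_quality
  )
  classes <- select_variant_subclass(tobs, reference_base)
  if (length(classes) == 0L) return(NULL)

  scored <- purrr::map_dfr(classes, function(cl) {
    np <- summarize_pileup(nobs, reference_base, cl)
    tp <- summarize_pileup(tobs, reference_base, cl)
    counts <- tibble::tibble(
      subclass = cl,
      n_normal = np$n_trials, k_normal = np$k_successes,
      n_tumor = tp$n_trials, k_tumor = tp$k_successes
    )
    somatic_probability(counts, priors, min_coverage)
  })
  if (all(is.na(scored$p_somatic))) return(NULL) # coverage gate
  best <- scored[which.max(scored$p_somatic), ]
  if (is.na(best$p_somatic) || best$p_somatic <= emission_threshold) return(NULL)

  filters_failed <- character(0)
  if (strand_filter && best$subclass %in% BASES) {
    supp <- tobs[tobs$base == best$subclass, , drop = FALSE]
    if (!strand_bias_filter(supp)) filters_failed <- "strand_bias"
  }
  event_kind <- switch(best$subclass,
    ins = "insertion", del = "deletion", "substitution"
  )
  alt <- switch(best$subclass, ins = "<INS>", del = "<DEL>", best$subclass)
  tibble::tibble(
    contig = contig,
    position = as.integer(position),
    reference_allele = reference_base,
    alternate_allele = alt,
    event_kind = event_kind,
    n_normal = best$n_normal, k_normal = best$k_normal,
    n_tumor = best$n_tumor, k_tumor = best$k_tumor,
    posterior_probability = best$p_somatic,
    phred_quality = phred_quality(best$p_somatic, phred_cap),
    filters_failed = paste(filters_failed, collapse = ";")
  )
}
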