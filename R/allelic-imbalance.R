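# Allelic imbalance: a Bayes-factor test, at heterozygous loci inside
# annotated transcripts, of whether the variant-allele proportion in a test
# sample (e.g. tumor RNA) is tied to the proportion in a reference sample
# (e.g. normal RNA, or DNA) or independent of it. Experimental: priors for
# allele-specific shifts are not well calibrated against known-truth systems.

#' Bayes factor for allele-proportion tying at a heterozygous locus
#'
#' Compares two models of the test-sample counts, marginalised over the three
#' germline genotype classes with their priors:
#' \deqn{K = \frac{\sum_i \pi_i P(D_{test} \mid M_{tied}, i, D_{ref})}
#'                {\sum_i \pi_i P(D_{test} \mid M_{indep}, i, D_{ref})}}
#' Under both models the reference- and variant-homozygous classes use their
#' own betas (those terms cancel as the heterozygous posterior approaches 1).
#' For the heterozygous class, the *tied* model updates the allelic-balance
#' beta with the reference-sample counts
#' (`alpha_ai + k_ref`, `beta_ai + n_ref - k_ref`), while the *independent*
#' model keeps the flat (`alpha_ai`, `beta_ai`). `K > 1` therefore favours
#' tied proportions (no somatic imbalance); `K < 1` favours independence,
#' i.e. allelic imbalance. The direction is stated in the output of
#' [transcript_scan()].
#'
#' @param data A data frame with columns `n_reference`, `k_reference`,
#'   `n_test`, `k_test` (trials and variant-allele successes per sample).
#' @param priors A [pair_priors()] object.
#' @param min_coverage Coverage gate applied to both samples.
#' @return The input tibble with a `bayes_factor` column appended (`NA` for
#'   gated rows).
#' @examples
#' ai_bayes_factor(
#'   tibble::tibble(n_reference = 60, k_reference = 30, n_test = 58, k_test = 29)
#' )
#' @export
ai_bayes_factor <- function(data, priors = pair_priors(), min_coverage = 5) {
  stopifnot(
    is.data.frame(data),
    all(c("n_reference", "k_reference", "n_test", "k_test") %in% names(data))
  )
  stopifnot(inherits(priors, "pair_priors"))
  out <- tibble::as_tibble(data)
  if (nrow(out) == 0L) return(dplyr::mutate(out, bayes_factor = numeric(0)))
  covered <- out$n_reference >= min_coverage & out$n_test >= min_coverage
  bf <- rep(NA_real_, nrow(out))
  if (any(covered)) {
    n_r <- out$n_reference[covered]
    k_r <- out$k_reference[covered]
    n_t <- out$n_test[covered]
    k_t <- out$k_test[covered]

    lpi <- log(c(priors$pi_ref, priors$pi_het, priors$pi_var))
    l_ref <- beta_binomial_pmf(n_t, k_t, priors$alpha_ref, priors$beta_ref, log = TRUE)
    l_var <- beta_binomial_pmf(n_t, k_t, priors$alpha_var, priors$beta_var, log = TRUE)
    l_het_tied <- beta_binomial_pmf(
      n_t, k_t,
      priors$alpha_ai + k_r, priors$beta_ai + (n_r - k_r),
      log = TRUE
    )
    l_het_indep <- beta_binomial_pmf(n_t, k_t, priors$alpha_ai, priors$beta_ai, log = TRUE)

    num <- row_log_sum_exp(cbind(lpi[1] + l_ref, lpi[2] + l_het_tied, lpi[3] + l_var))
    den <- row_log_sum_exp(cbind(lpi[1] + l_ref, lpi[2] + l_het_indep, lpi[3] + l_var))
    bf[covered] <- exp(num - den)
  }
  dplyr::mutate(out, bayes_factor = bf)
}

#' Update prior odds by a Bayes factor
#'
#' @param prior_odds Positive prior odds of no imbalance.
#' @param bayes_factor Positive Bayes factor from [ai_bayes_factor()].
#' @return Posterior odds (their product).
#' @examples
#' posterior_odds(1, 2.5)
#' @export
posterior_odds <- function(prior_odds, bayes_factor) {
  if (any(prior_odds <= 0, na.rm = TRUE) || any(bayes_factor <= 0, na.rm = TRUE)) {
    rlang::abort("prior odds and Bayes factor must be strictly positive")
  }
  prior_odds * bayes_factor
}

#' Scan annotated transcripts for allelic imbalance
#'
#' Evaluates [ai_bayes_factor()] at every sufficiently covered locus that
#' falls inside an annotated transcript interval, and aggregates each
#' transcript by multiplying its loci's Bayes factors (treating loci as
#' independent) before applying the prior odds.
#'
#' @param loci A data frame with columns `contig`, `position` (1-based) and
#'   the count columns of [ai_bayes_factor()].
#' @param annotations A data frame with columns `contig`, `start`, `end`
#'   (0-based half-open) and `transcript_id`, e.g. from [read_annotations()].
#' @param priors A [pair_priors()] object.
#' @param prior_odds Prior odds of tied proportions, applied per transcript.
#' @param min_coverage Coverage gate per locus.
#' @return A list of class `ai_scan` with elements `per_locus` (one row per
#'   informative locus, with `bayes_factor`; `bayes_factor > 1` favours tied
#'   allele proportions, `< 1` favours imbalance), `per_transcript`
#'   (`transcript_id`, `n_loci`, `bayes_factor`, `posterior_odds`), and
#'   `n_uncovered_transcripts` (annotated transcripts with no informative
#'   locus, omitted from the tables).
#' @export
transcript_scan <- function(loci, annotations, priors = pair_priors(),
                            prior_odds = 1, min_coverage = 5) {
  stopifnot(
    is.data.frame(loci),
    all(c("contig", "position") %in% names(loci)),
    is.data.frame(annotations),
    all(c("contig", "start", "end", "transcript_id") %in% names(annotations))
  )
  if (any(annotations$end <= annotations$start)) {
    rlang::abort("annotation intervals must be non-degenerate (end > start)")
  }
  # assign loci to transcripts (0-based half-open intervals, 1-based loci)
  hits <- dplyr::inner_join(
    loci, annotations,
    by = "contig", relationship = "many-to-many"
  )
  hits <- dplyr::filter(hits, .data$position > .data$start, .data$position <= .data$end)
  per_locus <- ai_bayes_factor(
    dplyr::select(hits, -"start", -"end"),
    priors, min_coverage
  )
  per_locus <- dplyr::filter(per_locus, !is.na(.data$bayes_factor))
  per_transcript <- per_locus |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      bayes_factor = exp(sum(log(.data$bayes_factor))),
      .groups = "drop"
    ) |>
    dplyr::mutate(posterior_odds = posterior_odds(prior_odds, .data$bayes_factor))
  n_uncovered <- length(setdiff(
    unique(annotations$transcript_id), per_transcript$transcript_id
  ))
  structure(
    list(
      per_locus = per_locus,
      per_transcript = per_transcript,
      n_uncovered_transcripts = n_uncovered
    ),
    class = "ai_scan"
  )
}

#' @export
print.ai_scan <- function(x, ...) {
  cat("<ai_scan> Bayes factor direction: >1 tied allele proportions, <1 imbalance\n")
  cat(sprintf(
    "  %d informative loci in %d transcripts (%d transcripts without coverage)\n",
    nrow(x$per_locus), nrow(x$per_transcript), x$n_uncovered_transcripts
  ))
  print(x$per_transcript)
  invisible(x)
}
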