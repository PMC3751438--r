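#' Genotype priors and beta hyperparameters
#'
#' Builds the set of prior probabilities and beta-distribution hyperparameters
#' shared by all detectors. The defaults encode the standard operating point of
#' the model: germline variation is rare (`pi_het`, `pi_var`), somatic events
#' and loss of heterozygosity are rarer still (`pi_somatic`, `pi_loh`), the
#' reference-homozygous class expects variant evidence only at the sequencing
#' error rate (`alpha_ref = 1`, `beta_ref = 700` skews the beta density hard
#' against zero), the variant-homozygous class is its mirror image, and the
#' heterozygous, somatic and allelic-imbalance classes are left uninformative
#' (`alpha = beta = 1`) so that no allele fraction is presumed — the property
#' that makes the model robust to aneuploidy and stromal contamination.
#'
#' Every value can be overridden, e.g. to encode a platform-specific error
#' profile in `beta_ref`.
#'
#' @param pi_ref,pi_het,pi_var Prior probabilities of the three diploid
#'   germline genotype classes (reference-homozygous, heterozygous,
#'   variant-homozygous). Must sum to 1.
#' @param pi_somatic Prior probability of a somatic variant at a locus.
#' @param pi_loh Prior probability of somatic loss of heterozygosity at a
#'   germline-heterozygous locus.
#' @param alpha_ref,beta_ref Beta hyperparameters for the variant-evidence
#'   proportion under a reference-homozygous genotype.
#' @param alpha_var,beta_var Beta hyperparameters under a variant-homozygous
#'   genotype.
#' @param alpha_nonhom,beta_nonhom Beta hyperparameters under a heterozygous
#'   (non-homozygous) genotype.
#' @param alpha_somatic,beta_somatic Beta hyperparameters for the somatic
#'   variant class in the tumor.
#' @param alpha_ai,beta_ai Beta hyperparameters for the heterozygous class in
#'   the allelic-imbalance Bayes factor.
#'
#' @return An object of class `pair_priors`: a named list of the above values.
#' @examples
#' pair_priors()
#' pair_priors(beta_ref = 1000) # stricter error expectation
#' @export
pair_priors <- function(pi_ref = 0.9985,
                        pi_het = 0.001,
                        pi_var = 0.0005,
                        pi_somatic = 0.0001,
                        pi_loh = 0.0001,
                        alpha_ref = 1, beta_ref = 700,
                        alpha_var = 700, beta_var = 1,
                        alpha_nonhom = 1, beta_nonhom = 1,
                        alpha_somatic = 1, beta_somatic = 1,
                        alpha_ai = 1, beta_ai = 1) {
  p <- list(
    pi_ref = pi_ref, pi_het = pi_het, pi_var = pi_var,
    pi_somatic = pi_somatic, pi_loh = pi_loh,
    alpha_ref = alpha_ref, beta_ref = beta_ref,
    alpha_var = alpha_var, beta_var = beta_var,
    alpha_nonhom = alpha_nonhom, beta_nonhom = beta_nonhom,
    alpha_somatic = alpha_somatic, beta_somatic = beta_somatic,
    alpha_ai = alpha_ai, beta_ai = beta_ai
  )
  probs <- c(pi_ref, pi_het, pi_var, pi_somatic, pi_loh)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    rlang::abort("all prior probabilities must lie in [0, 1]")
  }
  if (abs(pi_ref + pi_het + pi_var - 1) > 1e-8) {
    rlang::abort("pi_ref + pi_het + pi_var must equal 1")
  }
  hyper <- unlist(p[grepl("^(alpha|beta)_", names(p))])
  if (any(!is.finite(hyper)) || any(hyper <= 0)) {
    rlang::abort("all alpha and beta hyperparameters must be strictly positive")
  }
  structure(p, class = "pair_priors")
}

#' @export
print.pair_priors <- function(x, ...) {
  cat("<pair_priors>\n")
  cat(sprintf(
    "  genotype priors: ref %.4g, het %.4g, var %.4g\n",
    x$pi_ref, x$pi_het, x$pi_var
  ))
  cat(sprintf("  event priors:    somatic %.4g, loh %.4g\n", x$pi_somatic, x$pi_loh))
  cat(sprintf(
    "  beta hyperparameters: ref (%g, %g), var (%g, %g), nonhom (%g, %g), somatic (%g, %g), ai (%g, %g)\n",
    x$alpha_ref, x$beta_ref, x$alpha_var, x$beta_var,
    x$alpha_nonhom, x$beta_nonhom, x$alpha_somatic, x$beta_somatic,
    x$alpha_ai, x$beta_ai
  ))
  invisible(x)
}

#' Summarised Bernoulli trials for one evidence class at one locus
#'
#' A pileup summary records, for one evidence class at one locus (or region),
#' the number of filtered read observations (`n_trials`) and how many of them
#' support the tested variant subclass (`k_successes`).
#'
#' @param n_trials Non-negative integer vector of trial counts.
#' @param k_successes Non-negative integer vector of success counts,
#'   element-wise at most `n_trials`.
#' @return A tibble with columns `n_trials` and `k_successes`.
#' @examples
#' pileup_summary(30, 2)
#' @export
pileup_summary <- function(n_trials, k_successes) {
  n <- as.integer(n_trials)
  k <- as.integer(k_successes)
  if (length(n) != length(k)) rlang::abort("n_trials and k_successes must have equal length")
  if (any(is.na(n)) || any(is.na(k)) || any(n < 0) || any(k < 0) || any(k > n)) {
    rlang::abort("pileup summaries require 0 <= k_successes <= n_trials")
  }
  tibble::tibble(n_trials = n, k_successes = k)
}
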