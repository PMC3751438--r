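# Independent scalar oracles, deliberately built on different primitives than
# the package (trapezoid integration of the beta-mixed binomial rather than
# lchoose/lbeta algebra). Scalar only; no log-space tricks.

# P(K = k | n, alpha, beta) by integrating dbinom(k, n, p) against the beta
# density on a fine grid.
bb_oracle <- function(n, k, alpha, beta, grid = 1e6) {
  p <- seq(1e-12, 1 - 1e-12, length.out = grid)
  f <- stats::dbinom(k, n, p) * stats::dbeta(p, alpha, beta)
  sum((f[-1] + f[-grid]) / 2 * diff(p))
}

oracle_hyper <- function(priors) {
  list(
    ref = c(priors$alpha_ref, priors$beta_ref),
    het = c(priors$alpha_nonhom, priors$beta_nonhom),
    var = c(priors$alpha_var, priors$beta_var)
  )
}

# Three-class germline posterior evaluated term by term.
germ_oracle <- function(n, k, priors = pair_priors()) {
  h <- oracle_hyper(priors)
  pis <- c(ref = priors$pi_ref, het = priors$pi_het, var = priors$pi_var)
  lik <- vapply(names(h), function(g) bb_oracle(n, k, h[[g]][1], h[[g]][2]), numeric(1))
  w <- pis * lik
  w / sum(w)
}

# Full somatic formula: P(ref_n | D_n) x reduced-class tumor posterior.
som_oracle <- function(n_n, k_n, n_t, k_t, priors = pair_priors()) {
  p_ref_n <- germ_oracle(n_n, k_n, priors)[["ref"]]
  l_som <- bb_oracle(n_t, k_t, priors$alpha_somatic, priors$beta_somatic)
  l_ref <- bb_oracle(n_t, k_t, priors$alpha_ref + k_n, priors$beta_ref + n_n - k_n)
  num <- priors$pi_somatic * l_som
  p_ref_n * num / (num + (1 - priors$pi_somatic) * l_ref)
}

# LOH formula with the heterozygous-tumor likelihood either flat or updated.
loh_oracle <- function(n_n, k_n, n_t, k_t, priors = pair_priors(), update_het = FALSE) {
  p_het_n <- germ_oracle(n_n, k_n, priors)[["het"]]
  l_hom <- bb_oracle(n_t, k_t, priors$alpha_ref, priors$beta_ref) +
    bb_oracle(n_t, k_t, priors$alpha_var, priors$beta_var)
  l_het <- if (update_het) {
    bb_oracle(n_t, k_t, priors$alpha_nonhom + k_n, priors$beta_nonhom + n_n - k_n)
  } else {
    bb_oracle(n_t, k_t, priors$alpha_nonhom, priors$beta_nonhom)
  }
  num <- priors$pi_loh * l_hom
  p_het_n * num / (num + (1 - priors$pi_loh) * l_het)
}

# Allelic-imbalance Bayes factor, term by term.
ai_oracle <- function(n_r, k_r, n_t, k_t, priors = pair_priors()) {
  l_ref <- bb_oracle(n_t, k_t, priors$alpha_ref, priors$beta_ref)
  l_var <- bb_oracle(n_t, k_t, priors$alpha_var, priors$beta_var)
  tied <- bb_oracle(n_t, k_t, priors$alpha_ai + k_r, priors$beta_ai + n_r - k_r)
  indep <- bb_oracle(n_t, k_t, priors$alpha_ai, priors$beta_ai)
  num <- priors$pi_ref * l_ref + priors$pi_het * tied + priors$pi_var * l_var
  den <- priors$pi_ref * l_ref + priors$pi_het * indep + priors$pi_var * l_var
  num / den
}

# Convenience wrappers for one-row count tibbles.
counts_row <- function(n_n, k_n, n_t, k_t) {
  tibble::tibble(n_normal = n_n, k_normal = k_n, n_tumor = n_t, k_tumor = k_t)
}

ai_row <- function(n_r, k_r, n_t, k_t) {
  tibble::tibble(n_reference = n_r, k_reference = k_r, n_test = n_t, k_test = k_t)
}
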