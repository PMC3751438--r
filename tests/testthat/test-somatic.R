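test_that("somatic probability matches the scalar oracle", {
  cases <- list(
    list(60, 0, 60, 30), # clear somatic
    list(60, 28, 60, 30), # germline het, not somatic
    list(60, 0, 60, 0), # no evidence
    list(40, 1, 80, 6),
    list(200, 0, 30, 4)
  )
  for (cs in cases) {
    got <- somatic_probability(counts_row(cs[[1]], cs[[2]], cs[[3]], cs[[4]]))$p_somatic
    want <- som_oracle(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_equal(got, want, tolerance = 1e-6,
      label = sprintf("somatic(%d,%d,%d,%d)", cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    )
  }
})

test_that("somatic probability separates somatic from germline and noise", {
  expect_gt(somatic_probability(counts_row(60, 0, 60, 30))$p_somatic, 0.99)
  expect_lt(somatic_probability(counts_row(60, 28, 60, 30))$p_somatic, 0.01)
  p0 <- somatic_probability(counts_row(60, 0, 60, 0))$p_somatic
  expect_lt(p0, pair_priors()$pi_somatic * 10)
})

test_that("the coverage gate skips shallow sites without error", {
  res <- somatic_probability(counts_row(c(4, 60), c(0, 0), c(60, 4), c(10, 2)))
  expect_true(all(is.na(res$p_somatic)))
  res2 <- somatic_probability(counts_row(5, 0, 5, 5))
  expect_false(is.na(res2$p_somatic))
})

test_that("more tumor variant evidence never lowers the somatic score", {
  p <- somatic_probability(counts_row(60, 0, 60, 0:60))$p_somatic
  expect_true(all(diff(p) >= -1e-12))
})

test_that("evidence-free somatic probability vanishes with depth", {
  n <- c(10, 50, 200, 1000, 5000)
  p <- somatic_probability(counts_row(n, 0, n, 0))$p_somatic
  expect_true(all(diff(p) < 0))
  expect_lt(p[length(p)], 1e-7)
})

test_that("extra normal coverage raises confidence in low-frequency variants", {
  # a weak tumor signal (3/60) becomes credible as the normal error model
  # sharpens: the conjugate-update effect on the reference beta
  p10 <- somatic_probability(counts_row(10, 0, 60, 3))$p_somatic
  p200 <- somatic_probability(counts_row(200, 0, 60, 3))$p_somatic
  expect_gt(p200, p10)
})

test_that("deep normal coverage suppresses under-sampled germline hets", {
  # a het at ~50% in the normal: more normal reads kill the false somatic call
  n <- c(10, 40, 160, 640)
  p_ref <- germline_posterior(pileup_summary(n, round(n / 2)))$p_ref
  expect_true(all(diff(p_ref) < 0))
  expect_lt(p_ref[4], 1e-10)
})

test_that("phred quality transforms and saturates correctly", {
  expect_equal(phred_quality(0.9), 10)
  expect_equal(phred_quality(0.99), 20)
  expect_equal(phred_quality(1), 255)
  expect_equal(phred_quality(1, cap = 99), 99)
  expect_error(phred_quality(1.2), "\\[0, 1\\]")
})

toy_locus_obs <- function(bases, strand = NULL) {
  n <- length(bases)
  if (is.null(strand)) strand <- rep(c("+", "-"), length.out = n)
  read_observations(bases, 30, 60, strand)
}

test_that("call_site emits the expected call on a clear somatic locus", {
  normal <- toy_locus_obs(rep("A", 60))
  tumor <- toy_locus_obs(c(rep("A", 30), rep("T", 30)))
  call <- call_site("chr1", 101, "A", normal, tumor)
  expect_equal(call$alternate_allele, "T")
  expect_equal(call$event_kind, "substitution")
  expect_gt(call$phred_quality, 20)
  expect_equal(call$filters_failed, "")
  expect_equal(call$k_tumor, 30L)
})

test_that("call_site is silent on all-reference and under-covered loci", {
  allref <- toy_locus_obs(rep("A", 50))
  expect_null(call_site("chr1", 1, "A", allref, allref))
  shallow_tumor <- toy_locus_obs(c("A", "T", "T", "T"))
  expect_null(call_site("chr1", 1, "A", toy_locus_obs(rep("A", 60)), shallow_tumor))
})

test_that("call_site records single-stranded support instead of dropping it", {
  normal <- toy_locus_obs(rep("A", 60))
  tumor_bases <- c(rep("A", 30), rep("T", 30))
  one_sided <- toy_locus_obs(tumor_bases,
    strand = c(rep(c("+", "-"), 15), rep("+", 30))
  )
  call <- call_site("chr1", 7, "A", normal, one_sided)
  expect_equal(call$filters_failed, "strand_bias")
  expect_gt(call$posterior_probability, 0.99)
  off <- call_site("chr1", 7, "A", normal, one_sided, strand_filter = FALSE)
  expect_equal(off$filters_failed, "")
})

test_that("quality filtering happens before counting", {
  normal <- toy_locus_obs(rep("A", 60))
  # tumor variant reads all below base quality 10: invisible to the caller
  tumor <- read_observations(
    c(rep("A", 60), rep("T", 20)),
    c(rep(30, 60), rep(5, 20)), 60,
    rep(c("+", "-"), 40)
  )
  expect_null(call_site("chr1", 3, "A", normal, tumor))
})
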