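small_cfg <- function(...) {
  sim_config(
    n_sites = 1000, coverage_normal = 60, coverage_tumor = 60,
    fraction_het = 0.3, fraction_hom_var = 0.05, fraction_somatic = 0.1,
    seed = 19, ...
  )
}

test_that("the generator is bit-reproducible and honors its composition", {
  cfg <- small_cfg()
  a <- generate_pair(cfg)
  b <- generate_pair(cfg)
  expect_identical(a, b)
  expect_equal(sum(a$somatic), 100)
  expect_equal(sum(a$genotype == "het"), 300)
  expect_equal(sum(a$genotype == "hom_var"), 50)
  expect_true(all(a$genotype[a$somatic] == "ref")) # somatic implies germline ref
  counts <- as.matrix(a[paste0("normal_", c("A", "C", "G", "T"))])
  expect_equal(as.integer(rowSums(counts)), a$n_normal)
})

test_that("allele fractions follow genotype and purity", {
  alt_frac <- function(pair, rows, sample) {
    m <- as.matrix(pair[paste0(sample, "_", c("A", "C", "G", "T"))])
    k <- m[cbind(rows, match(pair$alt[rows], c("A", "C", "G", "T")))]
    sum(k) / sum(pair[[paste0("n_", substr(sample, 1, 6))]][rows])
  }
  pure <- generate_pair(small_cfg(tumor_purity = 1))
  som <- which(pure$somatic)
  f_pure <- alt_frac(pure, som, "tumor")
  expect_equal(f_pure, 0.5, tolerance = 0.05)
  expect_lt(alt_frac(pure, som, "normal"), 0.01)
  hets <- which(pure$genotype == "het")
  expect_equal(alt_frac(pure, hets, "tumor"), 0.5, tolerance = 0.03)
  expect_equal(alt_frac(pure, hets, "normal"), 0.5, tolerance = 0.03)
  diluted <- generate_pair(small_cfg(tumor_purity = 0.4))
  f_dil <- alt_frac(diluted, which(diluted$somatic), "tumor")
  expect_lt(abs(f_dil - 0.2), 3 * sqrt(0.2 * 0.8 / (100 * 60)) + 0.005)
})

test_that("zero purity makes the tumor statistically match the normal", {
  pair <- generate_pair(small_cfg(tumor_purity = 0))
  som <- pair[pair$somatic, ]
  k_t <- sum(as.matrix(som[paste0("tumor_", c("A", "C", "G", "T"))])[
    cbind(seq_len(nrow(som)), match(som$alt, c("A", "C", "G", "T")))
  ])
  # only error reads can carry the somatic allele
  expect_lt(k_t / sum(som$n_tumor), 0.005)
})

test_that("admixture preserves depth and dilutes the somatic allele", {
  cfg <- small_cfg()
  pair <- generate_pair(cfg)
  expect_identical(admix(pair, 1, seed = 5), pair)
  mixed <- admix(pair, 0.5, seed = 5)
  expect_equal(mixed$n_tumor, pair$n_tumor)
  som <- which(pair$somatic)
  m <- as.matrix(mixed[som, paste0("tumor_", c("A", "C", "G", "T"))])
  k <- m[cbind(seq_along(som), match(pair$alt[som], c("A", "C", "G", "T")))]
  f <- sum(k) / sum(mixed$n_tumor[som])
  sd3 <- 3 * sqrt(0.25 * 0.75 / sum(mixed$n_tumor[som]))
  expect_lt(abs(f - 0.25), sd3 + 0.01)
  expect_error(admix(pair, 1.5), "\\[0, 1\\]")
})

test_that("down-sampling thins to the target coverage reproducibly", {
  cfg <- sim_config(
    n_sites = 10000, coverage_normal = 128, coverage_tumor = 128, seed = 23
  )
  pair <- generate_pair(cfg)
  thin <- downsample(pair, 8, seed = 2)
  expect_equal(mean(thin$n_normal), 8, tolerance = 0.02)
  expect_equal(mean(thin$n_tumor), 8, tolerance = 0.02)
  expect_identical(downsample(pair, 8, seed = 2), thin)
  same <- downsample(pair, mean(pair$n_normal), sample = "normal", seed = 2)
  expect_identical(same$normal_A, pair$normal_A)
  expect_error(downsample(pair, 0), "positive")
  expect_error(downsample(pair, 200), "exceeds")
})

test_that("evaluation counts sensitivity and FDR as advertised", {
  truth <- tibble::tibble(site = 1:20, somatic = rep(c(TRUE, FALSE), c(10, 10)))
  perfect <- tibble::tibble(
    site = 1:20, called = truth$somatic, phred = ifelse(truth$somatic, 90, 0)
  )
  expect_equal(
    evaluate_calls(perfect, truth)[, c("sensitivity", "fdr")],
    tibble::tibble(sensitivity = 1, fdr = 0)
  )
  none <- dplyr::mutate(perfect, called = FALSE)
  ev0 <- evaluate_calls(none, truth)
  expect_equal(ev0$sensitivity, 0)
  expect_equal(ev0$fdr, 0)
  expect_false(ev0$fdr_defined)
  mixed <- tibble::tibble(
    site = 1:20,
    called = c(rep(TRUE, 8), FALSE, FALSE, TRUE, TRUE, rep(FALSE, 8)),
    phred = 90
  )
  ev <- evaluate_calls(mixed, truth)
  expect_equal(ev$sensitivity, 0.8)
  expect_equal(ev$fdr, 0.2)
  expect_error(
    evaluate_calls(mixed, dplyr::mutate(truth, somatic = FALSE)),
    "somatic site"
  )
  # quality threshold excludes low-quality calls
  low_q <- dplyr::mutate(mixed, phred = ifelse(site <= 4, 10, 90))
  expect_equal(evaluate_calls(low_q, truth, quality_threshold = 20)$sensitivity, 0.4)
})

test_that("sensitivity rises with coverage along both axes", {
  grid <- coverage_grid(
    sim_config(n_sites = 2500, seed = 29),
    coverages = c(8, 32, 128)
  )
  # nested thinning couples the coverage levels, so only a handful of
  # borderline sites (an error read appearing in the deeper normal pileup)
  # can flip against the trend; allow that finite-sample noise (1% of sites)
  noise <- 0.01
  by_normal <- split(grid, grid$coverage_normal)
  for (g in by_normal) {
    g <- g[order(g$coverage_tumor), ]
    expect_true(all(diff(g$sensitivity) >= -noise))
  }
  by_tumor <- split(grid, grid$coverage_tumor)
  for (g in by_tumor) {
    g <- g[order(g$coverage_normal), ]
    expect_true(all(diff(g$sensitivity) >= -noise))
  }
})

test_that("sensitivity rises with tumor purity at constant throughput", {
  sweep <- purity_sweep(
    sim_config(n_sites = 2500, seed = 37),
    purities = c(0.1, 0.3, 0.6, 1)
  )
  expect_true(all(diff(sweep$sensitivity) >= 0))
  expect_gt(sweep$sensitivity[4], 0.95)
})

test_that("autoplot methods return ggplot objects", {
  grid <- coverage_grid(
    sim_config(n_sites = 300, seed = 3),
    coverages = c(8, 32)
  )
  expect_s3_class(ggplot2::autoplot(grid), "ggplot")
  expect_s3_class(plot_coverage_grid(grid, "fdr"), "ggplot")
  sweep <- purity_sweep(sim_config(n_sites = 300, seed = 3), purities = c(0.5, 1))
  expect_s3_class(ggplot2::autoplot(sweep), "ggplot")
})

test_that("BAM fixtures round-trip the generator's pileup counts exactly", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(
    n_sites = 60, coverage_normal = 30, coverage_tumor = 30,
    fraction_het = 0.3, fraction_hom_var = 0.05, fraction_somatic = 0.15,
    seed = 43
  )
  fx <- emit_bam_fixtures(cfg, dir)
  expect_true(all(file.exists(fx$reference, fx$normal_bam, fx$tumor_bam, fx$truth)))
  # pileup at the simulated sites must equal the generated counts
  param <- Rsamtools::PileupParam(
    distinguish_strands = FALSE, min_base_quality = 10, min_mapq = 10,
    max_depth = 10000
  )
  pil <- Rsamtools::pileup(fx$normal_bam, pileupParam = param)
  pil <- pil[pil$seqnames == "sim1" & pil$pos %in% fx$sites$pos, ]
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(pil)[, c("pos", "nucleotide", "count")],
    names_from = "nucleotide", values_from = "count", values_fill = 0L
  )
  merged <- dplyr::left_join(fx$sites, wide, by = "pos")
  for (b in c("A", "C", "G", "T")) {
    got <- merged[[b]]
    got[is.na(got)] <- 0L
    expect_equal(got, merged[[paste0("normal_", b)]],
      label = sprintf("pileup counts for base %s", b)
    )
  }
  truth <- utils::read.delim(fx$truth)
  expect_equal(sum(truth$somatic), sum(cfg$n_sites * 0.15))
})
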