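# Synthetic paired-sample generator and evaluation harness. Emulates a
# matched tumor/normal experiment at the pileup-count level: known germline
# genotypes, known somatic variants, Poisson depth, a uniform per-base
# miscall model, and tumor purity as read admixture. Every draw is
# reproducible from the config seed.

#' Configuration for the paired-sample simulator
#'
#' Defaults describe the reference experiment the package's evaluation
#' harness runs: 12,000 independent sites comprising 5,500 germline
#' heterozygous, 500 variant-homozygous, 1,000 somatic (heterozygous in the
#' tumor clone, reference in the germline) and 5,000 reference-homozygous
#' sites; mean depth 128x in both samples; pure tumor; uniform per-base
#' miscall rate 0.1%.
#'
#' @param n_sites Number of independent sites.
#' @param fraction_het,fraction_hom_var,fraction_somatic Site-class fractions
#'   (remainder is reference-homozygous). The composition is deterministic:
#'   class counts are `round(n_sites * fraction)`.
#' @param coverage_normal,coverage_tumor Mean sequencing depths (Poisson).
#' @param tumor_purity Fraction of tumor-sample reads of tumor-cell origin in
#'   `[0, 1]`; a somatic heterozygous variant presents at allele fraction
#'   `0.5 * tumor_purity`.
#' @param error_rate Per-base miscall probability; a miscalled base becomes
#'   one of the three other bases uniformly.
#' @param seed Integer seed; all generator draws derive from it.
#' @return A validated list of class `sim_config`.
#' @examples
#' sim_config(n_sites = 100, coverage_normal = 30, coverage_tumor = 30)
#' @export
sim_config <- function(n_sites = 12000,
                       fraction_het = 5500 / 12000,
                       fraction_hom_var = 500 / 12000,
                       fraction_somatic = 1000 / 12000,
                       coverage_normal = 128,
                       coverage_tumor = 128,
                       tumor_purity = 1,
                       error_rate = 0.001,
                       seed = 1L) {
  cfg <- list(
    n_sites = as.integer(n_sites),
    fraction_het = fraction_het,
    fraction_hom_var = fraction_hom_var,
    fraction_somatic = fraction_somatic,
    coverage_normal = coverage_normal,
    coverage_tumor = coverage_tumor,
    tumor_purity = tumor_purity,
    error_rate = error_rate,
    seed = as.integer(seed)
  )
  fr <- c(fraction_het, fraction_hom_var, fraction_somatic)
  if (cfg$n_sites < 1L) rlang::abort("n_sites must be positive")
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    rlang::abort("site-class fractions must lie in [0, 1] and sum to at most 1")
  }
  if (tumor_purity < 0 || tumor_purity > 1) rlang::abort("tumor_purity must lie in [0, 1]")
  if (error_rate < 0 || error_rate >= 1) rlang::abort("error_rate must lie in [0, 1)")
  if (coverage_normal <= 0 || coverage_tumor <= 0) rlang::abort("coverages must be positive")
  structure(cfg, class = "sim_config")
}

# Draw per-base counts for one sample at every site.
# f: per-site variant allele fraction; depth: per-site depth.
# Returns matrix with columns ref (count of reference base), alt (true
# alternate allele), oth1, oth2 (the two other bases).
draw_site_counts <- function(depth, f, error_rate) {
  n <- length(depth)
  v <- stats::rbinom(n, depth, f) # variant-origin reads
  r <- depth - v
  # ref-origin miscalls, split uniformly over the three non-reference bases
  er <- stats::rbinom(n, r, error_rate)
  er_alt <- stats::rbinom(n, er, 1 / 3)
  er_o1 <- stats::rbinom(n, er - er_alt, 1 / 2)
  er_o2 <- er - er_alt - er_o1
  # variant-origin miscalls, split over ref and the two other bases
  ev <- stats::rbinom(n, v, error_rate)
  ev_ref <- stats::rbinom(n, ev, 1 / 3)
  ev_o1 <- stats::rbinom(n, ev - ev_ref, 1 / 2)
  ev_o2 <- ev - ev_ref - ev_o1
  cbind(
    ref = r - er + ev_ref,
    alt = v - ev + er_alt,
    oth1 = er_o1 + ev_o1,
    oth2 = er_o2 + ev_o2
  )
}

# Map ref/alt/oth1/oth2 count columns onto A/C/G/T columns given per-site
# ref and alt base assignments.
counts_to_bases <- function(counts, ref, alt) {
  n <- nrow(counts)
  out <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  ref_i <- match(ref, BASES)
  alt_i <- match(alt, BASES)
  # the two "other" bases per site, in fixed base order
  oth <- t(vapply(
    seq_len(n),
    function(i) setdiff(1:4, c(ref_i[i], alt_i[i])),
    integer(2)
  ))
  idx <- seq_len(n)
  out[cbind(idx, ref_i)] <- counts[, "ref"]
  out[cbind(idx, alt_i)] <- counts[, "alt"]
  out[cbind(idx, oth[, 1])] <- counts[, "oth1"]
  out[cbind(idx, oth[, 2])] <- counts[, "oth2"]
  out
}

#' Generate a matched normal/tumor pair of site pileups with ground truth
#'
#' Draws, for every site, a germline genotype class (deterministic
#' composition per the config fractions, shuffled over sites), a reference
#' and alternate base, Poisson depths, and per-base read counts in both
#' samples under the error model. Germline sites present the same allele
#' fraction in both samples (0, 0.5 or 1); somatic sites are reference in the
#' normal and present at allele fraction `0.5 * tumor_purity` in the tumor.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per site: `site`, `ref`, `alt`,
#'   `genotype` (`"ref"`, `"het"`, `"hom_var"`), `somatic` (logical truth),
#'   per-base counts `normal_A` ... `normal_T`, `tumor_A` ... `tumor_T`, and
#'   depths `n_normal`, `n_tumor`. Bit-reproducible from `config$seed`.
#' @examples
#' generate_pair(sim_config(n_sites = 50, seed = 7))
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  n <- config$n_sites
  n_het <- round(n * config$fraction_het)
  n_hom <- round(n * config$fraction_hom_var)
  n_som <- round(n * config$fraction_somatic)
  genotype <- sample(rep(
    c("het", "hom_var", "somatic", "ref"),
    c(n_het, n_hom, n_som, n - n_het - n_hom - n_som)
  ))
  somatic <- genotype == "somatic"
  germline <- ifelse(somatic, "ref", genotype)

  ref <- sample(BASES, n, replace = TRUE)
  alt <- unname(vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1)))

  f_normal <- c(ref = 0, het = 0.5, hom_var = 1)[germline]
  f_tumor <- ifelse(somatic, 0.5 * config$tumor_purity, f_normal)

  depth_n <- stats::rpois(n, config$coverage_normal)
  depth_t <- stats::rpois(n, config$coverage_tumor)

  cn <- counts_to_bases(draw_site_counts(depth_n, f_normal, config$error_rate), ref, alt)
  ct <- counts_to_bases(draw_site_counts(depth_t, f_tumor, config$error_rate), ref, alt)
  colnames(cn) <- paste0("normal_", BASES)
  colnames(ct) <- paste0("tumor_", BASES)

  tibble::tibble(
    site = seq_len(n),
    ref = ref, alt = alt,
    genotype = germline, somatic = somatic,
    tibble::as_tibble(cn), tibble::as_tibble(ct),
    n_normal = as.integer(depth_n), n_tumor = as.integer(depth_t)
  )
}

# Multivariate-hypergeometric draw: sample `k` reads without replacement
# from per-base pools (matrix columns), vectorised over sites.
mvhyper_draw <- function(pools, k) {
  n <- nrow(pools)
  remaining_pool <- rowSums(pools)
  remaining_k <- k
  out <- matrix(0L, n, ncol(pools), dimnames = dimnames(pools))
  for (j in seq_len(ncol(pools))) {
    white <- pools[, j]
    black <- remaining_pool - white
    draw <- stats::rhyper(n, white, black, remaining_k)
    out[, j] <- draw
    remaining_pool <- black
    remaining_k <- remaining_k - draw
  }
  out
}

#' Admix tumor reads with normal reads at a given purity ratio
#'
#' Emulates normal-tissue contamination by resampling each site's tumor
#' pileup: the tumor sample's depth is preserved, with each read drawn from
#' the tumor read pool with probability `ratio` and from the normal pool
#' otherwise (without replacement within each pool). `ratio = 1` returns the
#' pure tumor; `ratio = 0` a resampled copy of the normal.
#'
#' @param pair A site tibble from [generate_pair()].
#' @param ratio Tumor purity in `[0, 1]`.
#' @param seed Integer seed for the resampling draws.
#' @return The site tibble with its `tumor_*` count columns replaced by the
#'   admixed counts (total per-site tumor depth unchanged).
#' @export
admix <- function(pair, ratio, seed = 1L) {
  if (ratio < 0 || ratio > 1) rlang::abort("ratio must lie in [0, 1]")
  withr::local_seed(as.integer(seed))
  tcols <- paste0("tumor_", BASES)
  ncols <- paste0("normal_", BASES)
  tpool <- as.matrix(pair[tcols])
  npool <- as.matrix(pair[ncols])
  depth <- rowSums(tpool)
  from_tumor <- stats::rbinom(nrow(pair), depth, ratio)
  # the normal pool must supply the remainder; cap the shortfall back to tumor
  from_tumor <- pmax(from_tumor, depth - rowSums(npool))
  mixed <- mvhyper_draw(tpool, from_tumor) + mvhyper_draw(npool, depth - from_tumor)
  out <- tibble::as_tibble(pair)
  out[tcols] <- tibble::as_tibble(mixed)
  out$n_tumor <- as.integer(rowSums(mixed))
  out
}

#' Down-sample a pair to a lower mean coverage
#'
#' Independent binomial thinning of every read count with retention
#' probability `target / current mean depth`, emulating reduced sequencing
#' throughput.
#'
#' @param pair A site tibble from [generate_pair()].
#' @param target_coverage Desired mean depth; must not exceed the current
#'   mean.
#' @param sample Which sample to thin: `"both"`, `"normal"` or `"tumor"`.
#' @param seed Integer seed.
#' @return The thinned site tibble with depths recomputed.
#' @export
downsample <- function(pair, target_coverage, sample = c("both", "normal", "tumor"),
                       seed = 1L) {
  sample <- match.arg(sample)
  if (target_coverage <= 0) rlang::abort("target_coverage must be positive")
  withr::local_seed(as.integer(seed))
  out <- tibble::as_tibble(pair)
  thin <- function(cols, depth_col) {
    m <- as.matrix(out[cols])
    current <- mean(rowSums(m))
    if (target_coverage > current) {
      rlang::abort("target_coverage exceeds the current mean coverage")
    }
    p <- target_coverage / current
    thinned <- matrix(
      stats::rbinom(length(m), as.vector(m), p),
      nrow(m), ncol(m),
      dimnames = dimnames(m)
    )
    out[cols] <<- tibble::as_tibble(thinned)
    out[[depth_col]] <<- as.integer(rowSums(thinned))
  }
  if (sample %in% c("both", "normal")) thin(paste0("normal_", BASES), "n_normal")
  if (sample %in% c("both", "tumor")) thin(paste0("tumor_", BASES), "n_tumor")
  out
}

#' Call somatic substitutions on simulated (or BAM-derived) site counts
#'
#' Vectorised caller over per-base count tables: at each site the
#' best-supported tumor non-reference base is selected (ties break
#' `A < C < G < T`), its counts in both samples form the pileup summaries,
#' and [somatic_probability()] scores the site.
#'
#' @param sites A tibble with columns `ref`, per-base counts `normal_A` ...
#'   `tumor_T`, and depths `n_normal`, `n_tumor` (e.g. from
#'   [generate_pair()]).
#' @param priors A [pair_priors()] object.
#' @param min_coverage Coverage gate per sample.
#' @param emission_threshold Minimum posterior to flag a site as called.
#' @param phred_cap Quality cap.
#' @return The input tibble with appended columns `called_alt`, `k_normal`,
#'   `k_tumor`, `p_somatic`, `phred` and `called` (posterior above the
#'   emission threshold).
#' @export
call_pileups <- function(sites, priors = pair_priors(), min_coverage = 5,
                         emission_threshold = 0.5, phred_cap = 255) {
  tmat <- as.matrix(sites[paste0("tumor_", BASES)])
  nmat <- as.matrix(sites[paste0("normal_", BASES)])
  colnames(tmat) <- colnames(nmat) <- BASES
  ref_i <- match(sites$ref, BASES)
  pick <- tmat
  pick[cbind(seq_len(nrow(pick)), ref_i)] <- -1L
  alt_i <- max.col(pick, ties.method = "first")
  idx <- cbind(seq_len(nrow(tmat)), alt_i)
  counts <- tibble::tibble(
    n_normal = as.integer(rowSums(nmat)),
    k_normal = as.integer(nmat[idx]),
    n_tumor = as.integer(rowSums(tmat)),
    k_tumor = as.integer(tmat[idx])
  )
  scored <- somatic_probability(counts, priors, min_coverage)
  dplyr::mutate(
    tibble::as_tibble(sites),
    called_alt = BASES[alt_i],
    k_normal = counts$k_normal,
    k_tumor = counts$k_tumor,
    p_somatic = scored$p_somatic,
    phred = phred_quality(dplyr::coalesce(scored$p_somatic, 0), phred_cap),
    called = !is.na(scored$p_somatic) & scored$p_somatic > emission_threshold
  )
}

#' Sensitivity and false discovery rate against simulator truth
#'
#' A call is counted when its posterior clears the emission flag and, if
#' `quality_threshold` is given, its Phred quality exceeds that threshold.
#' Sensitivity is the fraction of true somatic sites called; FDR the fraction
#' of calls at non-somatic sites. With zero calls the FDR is undefined and
#' reported as 0 with `fdr_defined = FALSE`.
#'
#' @param calls A tibble with columns `site`, `called`, `phred` (e.g. from
#'   [call_pileups()]).
#' @param truth A tibble with columns `site` and `somatic` (e.g. from
#'   [generate_pair()]).
#' @param quality_threshold Optional Phred threshold (calls at or below it
#'   are excluded); `NULL` keeps every emitted call.
#' @return A one-row tibble: `sensitivity`, `fdr`, `tp`, `fp`, `fn`,
#'   `n_calls`, `fdr_defined`.
#' @examples
#' truth <- tibble::tibble(site = 1:3, somatic = c(TRUE, TRUE, FALSE))
#' calls <- tibble::tibble(site = 1:3, called = c(TRUE, FALSE, TRUE), phred = c(90, 0, 90))
#' evaluate_calls(calls, truth)
#' @export
evaluate_calls <- function(calls, truth, quality_threshold = NULL) {
  if (nrow(truth) == 0L || !any(truth$somatic)) {
    rlang::abort("truth set must contain at least one somatic site")
  }
  dat <- dplyr::left_join(
    truth,
    dplyr::select(calls, "site", "called", "phred"),
    by = "site"
  )
  hit <- dplyr::coalesce(dat$called, FALSE)
  if (!is.null(quality_threshold)) hit <- hit & dat$phred > quality_threshold
  tp <- sum(hit & dat$somatic)
  fp <- sum(hit & !dat$somatic)
  fn <- sum(!hit & dat$somatic)
  n_calls <- tp + fp
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    fdr = if (n_calls > 0) fp / n_calls else 0,
    tp = tp, fp = fp, fn = fn, n_calls = n_calls,
    fdr_defined = n_calls > 0
  )
}

#' Sensitivity/FDR over a grid of normal and tumor coverages
#'
#' Generates one pair at the maximum requested coverage and derives every
#' lower coverage by nested binomial thinning (each level thinned from the
#' one above), mirroring a down-sampling experiment: the coverage series for
#' a given seed share reads, so the measured trend reflects coverage, not
#' re-simulation noise.
#'
#' @param config A [sim_config()] object; its coverages are overridden by
#'   the grid.
#' @param coverages Mean depths to evaluate on both axes.
#' @param quality_threshold Phred threshold passed to [evaluate_calls()].
#' @param priors,min_coverage,emission_threshold Passed to [call_pileups()].
#' @return A tibble of class `coverage_grid`: one row per
#'   (`coverage_normal`, `coverage_tumor`) with `sensitivity` and `fdr`.
#' @export
coverage_grid <- function(config, coverages = c(8, 16, 32, 64, 128),
                          quality_threshold = 20, priors = pair_priors(),
                          min_coverage = 5, emission_threshold = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  coverages <- sort(coverages, decreasing = TRUE)
  top <- coverages[1]
  cfg <- config
  cfg$coverage_normal <- top
  cfg$coverage_tumor <- top
  pair <- generate_pair(cfg)
  truth <- dplyr::select(pair, "site", "somatic")

  # nested thinning: level i is thinned from level i-1
  normals <- tumors <- vector("list", length(coverages))
  normals[[1]] <- tumors[[1]] <- pair
  for (i in seq_along(coverages)[-1]) {
    normals[[i]] <- downsample(
      normals[[i - 1]], coverages[i],
      sample = "normal", seed = config$seed + i
    )
    tumors[[i]] <- downsample(
      tumors[[i - 1]], coverages[i],
      sample = "tumor", seed = config$seed + 100L + i
    )
  }
  grid <- tidyr::expand_grid(ni = seq_along(coverages), ti = seq_along(coverages))
  res <- purrr::pmap_dfr(grid, function(ni, ti) {
    sites <- normals[[ni]]
    sites[paste0("tumor_", BASES)] <- tumors[[ti]][paste0("tumor_", BASES)]
    sites$n_tumor <- tumors[[ti]]$n_tumor
    calls <- call_pileups(sites, priors, min_coverage, emission_threshold)
    ev <- evaluate_calls(calls, truth, quality_threshold)
    tibble::tibble(
      coverage_normal = coverages[ni],
      coverage_tumor = coverages[ti],
      sensitivity = ev$sensitivity,
      fdr = ev$fdr
    )
  })
  res <- dplyr::arrange(res, .data$coverage_normal, .data$coverage_tumor)
  class(res) <- c("coverage_grid", class(res))
  res
}

#' Sensitivity/FDR across tumor purities at constant total coverage
#'
#' Generates one pure-tumor pair, then admixes the tumor sample with normal
#' reads at each requested purity ([admix()]), holding the tumor sample's
#' total depth constant, and evaluates the caller at each level.
#'
#' @param config A [sim_config()] object (its `tumor_purity` is ignored; the
#'   generated tumor is pure and diluted by resampling).
#' @param purities Tumor purity levels in `[0, 1]`.
#' @param quality_threshold Phred threshold passed to [evaluate_calls()]
#'   (`NULL` = all emitted calls).
#' @param priors,min_coverage,emission_threshold Passed to [call_pileups()].
#' @return A tibble of class `purity_sweep`: one row per purity with
#'   `sensitivity` and `fdr`.
#' @export
purity_sweep <- function(config, purities = seq(0.1, 1, by = 0.15),
                         quality_threshold = NULL, priors = pair_priors(),
                         min_coverage = 5, emission_threshold = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$tumor_purity <- 1
  pair <- generate_pair(cfg)
  truth <- dplyr::select(pair, "site", "somatic")
  res <- purrr::map_dfr(purities, function(r) {
    mixed <- if (r >= 1) pair else admix(pair, r, seed = config$seed + round(1000 * r))
    calls <- call_pileups(mixed, priors, min_coverage, emission_threshold)
    ev <- evaluate_calls(calls, truth, quality_threshold)
    tibble::tibble(purity = r, sensitivity = ev$sensitivity, fdr = ev$fdr)
  })
  class(res) <- c("purity_sweep", class(res))
  res
}
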