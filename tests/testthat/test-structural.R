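proper_frags <- function(n, insert = 300, contig = "chr1", start = NULL) {
  if (is.null(start)) start <- seq_len(n) * 100L
  fragment_observations(
    contig = contig, start = start,
    mate_contig = contig, mate_position = start + insert - 50L,
    insert_size = insert, orientation = "FR"
  )
}

test_that("the insert model is a robust median/MAD summary", {
  expect_error(estimate_insert_model(proper_frags(10)), "at least 1000")
  m <- estimate_insert_model(proper_frags(1200, insert = 300))
  expect_equal(m$median, 300)
  expect_equal(m$spread, 1) # degenerate library hits the floor
  u <- estimate_insert_model(proper_frags(1050, insert = rep(290:310, 50)))
  expect_equal(u$median, 300)
  withr::with_seed(13, {
    sizes <- round(c(stats::rnorm(9500, 300, 30), stats::rnorm(500, 3000, 30)))
    mx <- estimate_insert_model(proper_frags(10000, insert = sizes))
    expect_true(mx$median >= 295 && mx$median <= 305)
  })
})

test_that("fragment classification partitions into exactly one label", {
  model <- structure(
    list(median = 300, spread = 30, discordance_multiplier = 5),
    class = "insert_model"
  )
  frags <- fragment_observations(
    contig = c("chr1", "chr1", "chr1", "chr1"),
    start = c(100L, 200L, 300L, 400L),
    mate_contig = c("chr2", "chr1", "chr1", "chr1"),
    mate_position = c(5000L, 450L, 3300L, 650L),
    insert_size = c(NA, 300, 3050, 300),
    orientation = c("FR", "FR", "FR", "FF")
  )
  cls <- classify_fragment(frags, model)
  expect_equal(
    cls$sv_class,
    c("translocation", "concordant", "large_deletion", "inversion")
  )
  withr::with_seed(21, {
    rnd <- fragment_observations(
      contig = "chr1", start = sample(1e5, 50),
      mate_contig = sample(c("chr1", "chr2"), 50, replace = TRUE),
      mate_position = sample(1e5, 50),
      insert_size = NA, orientation = sample(c("FR", "RF", "FF", "RR"), 50, TRUE)
    )
    rnd$insert_size[rnd$contig == rnd$mate_contig] <-
      sample(100:5000, sum(rnd$contig == rnd$mate_contig))
    lab <- classify_fragment(rnd, model)$sv_class
    expect_true(all(lab %in% c("concordant", "translocation", "inversion", "large_deletion")))
    expect_equal(length(lab), 50)
  })
})

trans_frags <- function(starts, mate_contig = "chr9", mate_pos = NULL) {
  if (is.null(mate_pos)) mate_pos <- 5000L + seq_along(starts) * 40L
  frags <- fragment_observations(
    contig = "chr1", start = as.integer(starts),
    mate_contig = mate_contig, mate_position = as.integer(mate_pos),
    orientation = "FR"
  )
  dplyr::mutate(frags, sv_class = "translocation")
}

test_that("abnormal fragments cluster by gap with mate co-clustering", {
  one <- cluster_abnormal(trans_frags(seq(1000, 1450, by = 50)), window = 1000)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_fragments, 10L)
  expect_equal(one$start, 1000L)
  expect_equal(one$end, 1450L)
  expect_equal(one$mate_contig, "chr9")

  two_groups <- cluster_abnormal(
    trans_frags(c(seq(1000, 1200, by = 50), seq(11500, 11700, by = 50))),
    window = 1000
  )
  expect_equal(nrow(two_groups), 2)

  # mates scattered one-per-contig: no co-cluster survives
  scattered <- trans_frags(
    c(1000, 1050, 1100),
    mate_contig = c("chr2", "chr3", "chr4"),
    mate_pos = c(100L, 100L, 100L)
  )
  expect_equal(nrow(cluster_abnormal(scattered, window = 1000)), 0)
})

test_that("clustering is order-invariant and monotone in the window", {
  withr::with_seed(31, {
    starts <- sort(sample(1:50000, 60))
    frags <- trans_frags(starts, mate_pos = rep(7000L, 60))
    shuffled <- frags[sample(nrow(frags)), ]
    a <- cluster_abnormal(frags, window = 500)
    b <- cluster_abnormal(shuffled, window = 500)
    expect_equal(a, b)
    # window monotonicity on a subclass without the translocation
    # mate-co-cluster rule (which can revive dropped singletons)
    inv <- fragment_observations(
      contig = "chr1", start = starts,
      mate_contig = "chr1", mate_position = starts + 300L,
      insert_size = 300, orientation = "FF"
    )
    inv <- dplyr::mutate(inv, sv_class = "inversion")
    for (w in c(100, 500, 2000)) {
      wide <- cluster_abnormal(inv, window = w * 4)
      narrow <- cluster_abnormal(inv, window = w)
      expect_lte(nrow(wide), nrow(narrow))
    }
  })
})

test_that("the SV scorer is bit-identical to the point-mutation scorer", {
  withr::with_seed(17, {
    n_n <- sample(5:200, 30, replace = TRUE)
    k_n <- vapply(n_n, function(x) sample(0:x, 1), integer(1))
    n_t <- sample(5:200, 30, replace = TRUE)
    k_t <- vapply(n_t, function(x) sample(0:x, 1), integer(1))
    counts <- counts_row(n_n, k_n, n_t, k_t)
    expect_identical(
      somatic_sv_probability(counts)$p_somatic,
      somatic_probability(counts)$p_somatic
    )
  })
})

test_that("fragment-count evidence separates somatic from shared events", {
  expect_gt(somatic_sv_probability(counts_row(40, 0, 40, 20))$p_somatic, 0.99)
  expect_lt(somatic_sv_probability(counts_row(40, 0, 40, 0))$p_somatic, 0.01)
  expect_lt(somatic_sv_probability(counts_row(40, 20, 40, 20))$p_somatic, 0.01)
})

test_that("sv_scan reports an engineered somatic translocation cluster", {
  withr::with_seed(41, {
    normal_bg <- proper_frags(1500, insert = round(stats::rnorm(1500, 300, 30)))
    tumor_bg <- proper_frags(1500, insert = round(stats::rnorm(1500, 300, 30)))
    event <- fragment_observations(
      contig = "chr1", start = 7000L + seq_len(12) * 30L,
      mate_contig = "chr7", mate_position = 900L + seq_len(12) * 25L,
      orientation = "FR"
    )
    catalog <- sv_scan(normal_bg, dplyr::bind_rows(tumor_bg, event))
    expect_equal(nrow(catalog), 1)
    expect_equal(catalog$sv_class, "translocation")
    expect_equal(catalog$k_tumor, 12L)
    expect_equal(catalog$k_normal, 0L)
    expect_gt(catalog$posterior_probability, 0.99)
    # the same event in both samples is germline: scored near zero
    shared <- sv_scan(
      dplyr::bind_rows(normal_bg, event),
      dplyr::bind_rows(tumor_bg, event)
    )
    expect_lt(shared$posterior_probability, 0.01)
  })
})
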