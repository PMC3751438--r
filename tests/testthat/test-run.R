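# End-to-end BAM walking, VCF output and annotation parsing.

fixture_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "somaticpair-runfix")
      cfg <- sim_config(
        n_sites = 80, coverage_normal = 40, coverage_tumor = 40,
        fraction_het = 0.3, fraction_hom_var = 0.05, fraction_somatic = 0.15,
        seed = 11
      )
      fx <- emit_bam_fixtures(cfg, dir, n_translocation_pairs = 10)
      rc <- run_config(
        fx$normal_bam, fx$tumor_bam, fx$reference,
        output_prefix = file.path(dir, "out")
      )
      res <- suppressMessages(run_analysis(rc))
      cache <<- list(fx = fx, rc = rc, res = res, dir = dir)
    }
    cache
  }
})

test_that("run_config validates inputs and indexes with actionable errors", {
  f <- fixture_run()
  expect_error(
    run_config("absent.bam", f$fx$tumor_bam, f$fx$reference),
    "absent.bam"
  )
  unindexed <- file.path(f$dir, "unindexed.bam")
  file.copy(f$fx$normal_bam, unindexed)
  expect_error(
    run_config(unindexed, f$fx$tumor_bam, f$fx$reference),
    "index.*unindexed.bam"
  )
})

test_that("the BAM walk recovers every simulated somatic substitution", {
  f <- fixture_run()
  calls <- tidy(f$res)
  subs <- calls[calls$event_kind == "substitution", ]
  truth <- f$fx$sites
  som <- truth[truth$somatic, ]
  expect_setequal(subs$position, som$pos)
  m <- dplyr::inner_join(subs, som, by = c("position" = "pos"))
  expect_equal(m$alternate_allele, m$alt)
  expect_equal(m$reference_allele, m$ref)
  # the BAM path must agree with calling the generator's counts directly
  direct <- call_pileups(truth)
  direct_hits <- direct[direct$called, ]
  expect_setequal(subs$position, direct_hits$pos)
  agree <- dplyr::inner_join(
    subs, direct_hits,
    by = c("position" = "pos")
  )
  expect_equal(agree$posterior_probability, agree$p_somatic, tolerance = 1e-12)
  tmp <- dplyr::left_join(
    truth, dplyr::select(subs, "position", "phred_quality"),
    by = c("pos" = "position")
  )
  ev_bam <- evaluate_calls(
    tibble::tibble(
      site = tmp$site,
      called = !is.na(tmp$phred_quality),
      phred = dplyr::coalesce(tmp$phred_quality, 0)
    ),
    truth, 20
  )
  ev_direct <- evaluate_calls(direct, truth, 20)
  expect_equal(ev_bam, ev_direct)
})

test_that("the run report accounts for visited and skipped loci", {
  f <- fixture_run()
  rep <- glance(f$res)
  expect_gt(rep$sites_visited, 0)
  expect_equal(rep$calls_substitution, sum(f$fx$sites$somatic))
  expect_equal(rep$sv_regions, 1)
})

test_that("the structural catalog holds the engineered translocation", {
  f <- fixture_run()
  cat <- f$res$sv_catalog
  expect_equal(nrow(cat), 1)
  expect_equal(cat$sv_class, "translocation")
  expect_equal(cat$mate_contig, "sim2")
  expect_gt(cat$posterior_probability, 0.99)
  expect_true(
    cat$start >= f$fx$sv_region$start - 1000 && cat$end <= f$fx$sv_region$end + 1000
  )
  events_file <- paste0(f$rc$output_prefix, "_events.tsv")
  expect_true(file.exists(events_file))
  on_disk <- utils::read.delim(events_file)
  expect_equal(nrow(on_disk), 1)
  expect_equal(on_disk$sv_class, "translocation")
})

test_that("the written VCF validates and preserves the QUAL/posterior relation", {
  f <- fixture_run()
  vcf_path <- paste0(f$rc$output_prefix, ".vcf")
  vcf <- VariantAnnotation::readVcf(vcf_path)
  expect_equal(length(vcf), nrow(tidy(f$res)))
  qual <- VariantAnnotation::qual(vcf)
  pp <- VariantAnnotation::info(vcf)$PP
  expect_true(all(abs(qual - pmin(-10 * log10(1 - pp), 255)) < 0.01))
  expect_equal(colnames(vcf), c("NORMAL", "TUMOR"))
  dp <- VariantAnnotation::geno(vcf)$DP
  expect_true(all(dp > 0))
})

test_that("region restriction confines the walk and unknown regions error", {
  f <- fixture_run()
  rc2 <- run_config(
    f$fx$normal_bam, f$fx$tumor_bam, f$fx$reference,
    regions = "sim2", detectors = c("snv", "indel")
  )
  res2 <- suppressMessages(run_analysis(rc2))
  calls2 <- tidy(res2)
  expect_true(nrow(calls2) == 0 || all(calls2$contig == "sim2"))
  expect_error(
    run_config(
      f$fx$normal_bam, f$fx$tumor_bam, f$fx$reference,
      regions = "chrMissing"
    ) |> run_analysis(),
    "chrMissing"
  )
})

test_that("write_vcf handles empty call sets and rejects unsorted input", {
  dir <- withr::local_tempdir()
  empty <- tidy(fixture_run()$res)[0, ]
  p <- write_vcf(empty, file.path(dir, "empty.vcf"))
  vcf <- VariantAnnotation::readVcf(p)
  expect_equal(length(vcf), 0)
  calls <- tidy(fixture_run()$res)
  if (nrow(calls) >= 2) {
    expect_error(write_vcf(calls[c(2, 1), ], file.path(dir, "bad.vcf")), "sorted")
  }
})

test_that("filter failures are named in FILTER but records are retained", {
  dir <- withr::local_tempdir()
  call <- tidy(fixture_run()$res)[1, ]
  call$filters_failed <- "strand_bias"
  p <- write_vcf(call, file.path(dir, "flt.vcf"))
  vcf <- VariantAnnotation::readVcf(p)
  expect_equal(length(vcf), 1)
  expect_equal(as.character(VariantAnnotation::filt(vcf)), "strand_bias")
})

test_that("BED annotations merge overlapping rows", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "ann.bed")
  writeLines(
    c("chr1\t100\t200", "chr1\t150\t300", "chr2\t0\t50"),
    bed
  )
  ann <- read_annotations(bed)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$start, c(100L, 0L))
  expect_equal(ann$end, c(300L, 50L))
})

test_that("GFF3 exons group under their transcript", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "ann.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=tx1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=tx1",
    "chr1\tsrc\texon\t501\t600\t.\t+\t.\tParent=tx2"
  ), gff)
  ann <- read_annotations(gff)
  expect_equal(sort(unique(ann$transcript_id)), c("tx1", "tx2"))
  tx1 <- ann[ann$transcript_id == "tx1", ]
  expect_equal(nrow(tx1), 2)
  expect_equal(tx1$start, c(100L, 300L)) # 0-based half-open
  expect_equal(tx1$end, c(200L, 400L))
})

test_that("degenerate annotation files are handled gracefully", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.bed")
  file.create(empty)
  expect_warning(ann <- read_annotations(empty), "empty")
  expect_equal(nrow(ann), 0)
  expect_error(read_annotations(file.path(dir, "nope.bed")), "not found")
  bad <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3", "not a gff line"), bad)
  expect_error(read_annotations(bad), "bad.gff3")
})

test_that("the BAM-backed allelic-imbalance scan finds tied germline hets", {
  f <- fixture_run()
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "tx.bed")
  len1 <- Rsamtools::scanBamHeader(f$fx$normal_bam)[[1]]$targets[["sim1"]]
  writeLines(sprintf("sim1\t0\t%d", len1), bed)
  scan <- ai_scan_bams(
    f$fx$normal_bam, f$fx$tumor_bam, f$fx$reference, bed
  )
  hets <- f$fx$sites[f$fx$sites$genotype == "het", ]
  # candidate loci are the confidently heterozygous sites of the reference
  # sample; the fixture's germline hets carry the same proportions in both
  # samples, so the tied model should win at (almost) every locus
  expect_gt(nrow(scan$per_locus), 0.8 * nrow(hets))
  expect_true(all(scan$per_locus$position %in% f$fx$sites$pos))
  expect_gt(mean(scan$per_locus$bayes_factor > 1), 0.95)
  expect_equal(nrow(scan$per_transcript), 1)
  expect_equal(
    scan$per_transcript$bayes_factor,
    prod(scan$per_locus$bayes_factor)
  )
  # run_analysis exposes the same scan behind the "ai" detector toggle
  rc <- run_config(
    f$fx$normal_bam, f$fx$tumor_bam, f$fx$reference,
    annotations = bed, detectors = c("snv", "ai")
  )
  res <- suppressMessages(run_analysis(rc))
  expect_s3_class(res$ai, "ai_scan")
  expect_equal(glance(res)$ai_loci, nrow(scan$per_locus))
  expect_error(
    run_config(f$fx$normal_bam, f$fx$tumor_bam, f$fx$reference,
      detectors = "ai"
    ),
    "annotations"
  )
})
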