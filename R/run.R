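# Paired-sample analysis over BAM files: configuration, the locus walker
# (Rsamtools pileups behind the evidence-module semantics), detector
# dispatch, and the two output files — a VCF of focal somatic variants and a
# tab-separated catalog of larger structural events.

#' Configure a paired tumor/normal analysis run
#'
#' Validates input paths (BAMs must be indexed, the reference FASTA must have
#' a `.fai`) and collects every tunable of the run: detector toggles, quality
#' and coverage filters, priors, and structural-variation settings.
#'
#' @param normal_bam,tumor_bam Paths to coordinate-sorted, indexed BAM files.
#' @param reference Path to the indexed reference FASTA.
#' @param annotations Optional BED/GFF3 interval file for the
#'   allelic-imbalance scan.
#' @param output_prefix Optional path prefix; when given, [run_analysis()]
#'   writes `<prefix>.vcf` (focal variants) and `<prefix>_events.tsv` (the
#'   large-events catalog).
#' @param detectors Character subset of
#'   `c("snv", "indel", "loh", "sv", "ai")` naming the detectors to run.
#'   `"ai"` (off by default) requires `annotations` and feeds the two BAMs
#'   into [ai_scan_bams()].
#' @param regions Optional character vector of contig names to restrict the
#'   walk to.
#' @param min_mapping_quality,min_base_quality Phred filters applied to every
#'   observation (inclusive thresholds, default 10).
#' @param min_coverage Minimum filtered depth per sample at a locus
#'   (default 5).
#' @param strand_filter Record a `strand_bias` filter failure on calls whose
#'   tumor variant evidence is single-stranded.
#' @param max_depth Pileup depth cap per locus (default 10000).
#' @param priors A [pair_priors()] object.
#' @param emission_threshold Posterior probability above which a call is
#'   emitted (default 0.5).
#' @param loh_update_het Passed to [loh_probability()] as `update_het`.
#' @param phred_cap Maximum reported Phred quality.
#' @param sv_window,sv_min_support,insert_multiplier,min_insert_fragments
#'   Structural-variation settings, see [sv_scan()] and
#'   [estimate_insert_model()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(normal_bam, tumor_bam, reference,
                       annotations = NULL, output_prefix = NULL,
                       detectors = c("snv", "indel", "loh", "sv"),
                       regions = NULL,
                       min_mapping_quality = 10, min_base_quality = 10,
                       min_coverage = 5, strand_filter = TRUE,
                       max_depth = 10000,
                       priors = pair_priors(),
                       emission_threshold = 0.5,
                       loh_update_het = FALSE,
                       phred_cap = 255,
                       sv_window = 1000, sv_min_support = 3,
                       insert_multiplier = 5, min_insert_fragments = 1000) {
  detectors <- match.arg(detectors, c("snv", "indel", "loh", "sv", "ai"), several.ok = TRUE)
  if ("ai" %in% detectors && is.null(annotations)) {
    rlang::abort("the \"ai\" detector requires an annotations file")
  }
  for (p in c(normal_bam, tumor_bam, reference, annotations)) {
    if (!file.exists(p)) rlang::abort(sprintf("input file not found: %s", p))
  }
  for (b in c(normal_bam, tumor_bam)) {
    if (!file.exists(paste0(b, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", b))) {
      rlang::abort(sprintf("missing BAM index (.bai) for %s; index the file first", b))
    }
  }
  if (!file.exists(paste0(reference, ".fai"))) {
    rlang::abort(sprintf("missing FASTA index (.fai) for %s; index the file first", reference))
  }
  stopifnot(inherits(priors, "pair_priors"))
  structure(
    list(
      normal_bam = normal_bam, tumor_bam = tumor_bam, reference = reference,
      annotations = annotations, output_prefix = output_prefix,
      detectors = detectors, regions = regions,
      min_mapping_quality = min_mapping_quality,
      min_base_quality = min_base_quality,
      min_coverage = min_coverage, strand_filter = strand_filter,
      max_depth = max_depth, priors = priors,
      emission_threshold = emission_threshold,
      loh_update_het = loh_update_het, phred_cap = phred_cap,
      sv_window = sv_window, sv_min_support = sv_min_support,
      insert_multiplier = insert_multiplier,
      min_insert_fragments = min_insert_fragments
    ),
    class = "run_config"
  )
}

# Wide per-position base/indel counts for one BAM over one contig.
# Columns: pos, A, C, G, T, del, ins, and per-strand base counts A_fwd ...
bam_pileup_counts <- function(bam, contig, contig_length, config) {
  which <- GenomicRanges::GRanges(contig, IRanges::IRanges(1, contig_length))
  pp <- Rsamtools::PileupParam(
    max_depth = config$max_depth,
    min_base_quality = config$min_base_quality,
    min_mapq = config$min_mapping_quality,
    min_nucleotide_depth = 0L,
    distinguish_strands = TRUE,
    distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = TRUE,
    include_insertions = TRUE
  )
  res <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(which = which),
    pileupParam = pp
  )
  if (nrow(res) == 0L) {
    empty <- tibble::tibble(pos = integer(0))
    for (cl in c(BASES, "del", "ins")) empty[[cl]] <- integer(0)
    for (b in BASES) empty[[paste0(b, "_fwd")]] <- empty[[paste0(b, "_rev")]] <- integer(0)
    return(empty)
  }
  long <- tibble::tibble(
    pos = res$pos,
    nucleotide = as.character(res$nucleotide),
    strand = as.character(res$strand),
    count = res$count
  )
  long$nucleotide[long$nucleotide == "-"] <- "del"
  long$nucleotide[long$nucleotide == "+"] <- "ins"
  long <- long[long$nucleotide %in% c(BASES, "del", "ins"), , drop = FALSE]
  totals <- long |>
    dplyr::count(.data$pos, .data$nucleotide, wt = .data$count) |>
    tidyr::pivot_wider(
      names_from = "nucleotide", values_from = "n", values_fill = 0L
    )
  by_strand <- long[long$nucleotide %in% BASES, , drop = FALSE] |>
    dplyr::mutate(strand = ifelse(.data$strand == "+", "fwd", "rev")) |>
    dplyr::count(.data$pos, .data$nucleotide, .data$strand,
      wt = .data$count, name = "n"
    ) |>
    tidyr::pivot_wider(
      names_from = c("nucleotide", "strand"), values_from = "n",
      names_glue = "{nucleotide}_{strand}", values_fill = 0L
    )
  out <- dplyr::left_join(totals, by_strand, by = "pos")
  for (cl in c(BASES, "del", "ins")) if (!cl %in% names(out)) out[[cl]] <- 0L
  for (b in BASES) {
    for (s in c("_fwd", "_rev")) {
      cl <- paste0(b, s)
      if (!cl %in% names(out)) out[[cl]] <- 0L
      out[[cl]][is.na(out[[cl]])] <- 0L
    }
  }
  out
}

# Mate-pair fragment observations from a BAM (one row per first-of-pair read).
bam_fragments <- function(bam, regions = NULL) {
  flags <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
    isFirstMateRead = TRUE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "pos", "strand", "mrnm", "mpos", "isize", "mapq")
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(res$mrnm)
  self_rev <- bitwAnd(res$flag[keep], 16L) > 0L
  mate_rev <- bitwAnd(res$flag[keep], 32L) > 0L
  same <- as.character(res$rname[keep]) == as.character(res$mrnm[keep])
  left_first <- res$pos[keep] <= res$mpos[keep]
  left_rev <- ifelse(left_first, self_rev, mate_rev)
  right_rev <- ifelse(left_first, mate_rev, self_rev)
  orientation <- dplyr::case_when(
    !left_rev & right_rev ~ "FR",
    left_rev & !right_rev ~ "RF",
    !left_rev & !right_rev ~ "FF",
    TRUE ~ "RR"
  )
  frags <- fragment_observations(
    contig = as.character(res$rname[keep]),
    start = res$pos[keep],
    mate_contig = as.character(res$mrnm[keep]),
    mate_position = res$mpos[keep],
    insert_size = ifelse(same, res$isize[keep], NA_real_),
    orientation = orientation,
    mapping_quality = res$mapq[keep]
  )
  if (!is.null(regions)) frags <- frags[frags$contig %in% regions, , drop = FALSE]
  frags
}

# Detector dispatch for one contig's merged site counts.
call_contig <- function(sites, config) {
  priors <- config$priors
  calls <- list()

  if ("snv" %in% config$detectors && nrow(sites) > 0L) {
    snv <- call_pileups(
      sites, priors, config$min_coverage,
      config$emission_threshold, config$phred_cap
    )
    hit <- snv[snv$called, , drop = FALSE]
    if (nrow(hit) > 0L) {
      fwd <- as.matrix(hit[paste0(BASES, "_fwd_tumor")])
      rev <- as.matrix(hit[paste0(BASES, "_rev_tumor")])
      ai <- match(hit$called_alt, BASES)
      both_strands <- fwd[cbind(seq_len(nrow(hit)), ai)] > 0L &
        rev[cbind(seq_len(nrow(hit)), ai)] > 0L
      calls$snv <- tibble::tibble(
        contig = hit$contig, position = hit$pos,
        reference_allele = hit$ref, alternate_allele = hit$called_alt,
        event_kind = "substitution",
        n_normal = hit$n_normal, k_normal = hit$k_normal,
        n_tumor = hit$n_tumor, k_tumor = hit$k_tumor,
        posterior_probability = hit$p_somatic,
        phred_quality = hit$phred,
        filters_failed = ifelse(
          config$strand_filter & !both_strands, "strand_bias", ""
        )
      )
    }
  }

  if ("indel" %in% config$detectors && nrow(sites) > 0L) {
    for (kind in c("ins", "del")) {
      k_n <- sites[[paste0(kind, "_normal")]]
      k_t <- sites[[paste0(kind, "_tumor")]]
      n_n <- sites$n_normal + (if (kind == "del") k_n else 0L)
      n_t <- sites$n_tumor + (if (kind == "del") k_t else 0L)
      cand <- which(k_t > 0L)
      if (length(cand) == 0L) next
      scored <- somatic_probability(
        tibble::tibble(
          n_normal = n_n[cand], k_normal = k_n[cand],
          n_tumor = n_t[cand], k_tumor = k_t[cand]
        ),
        priors, config$min_coverage
      )
      emit <- which(!is.na(scored$p_somatic) &
        scored$p_somatic > config$emission_threshold)
      if (length(emit) == 0L) next
      rows <- cand[emit]
      calls[[kind]] <- tibble::tibble(
        contig = sites$contig[rows], position = sites$pos[rows],
        reference_allele = sites$ref[rows],
        alternate_allele = ifelse(kind == "ins", "<INS>", "<DEL>"),
        event_kind = ifelse(kind == "ins", "insertion", "deletion"),
        n_normal = scored$n_normal[emit], k_normal = scored$k_normal[emit],
        n_tumor = scored$n_tumor[emit], k_tumor = scored$k_tumor[emit],
        posterior_probability = scored$p_somatic[emit],
        phred_quality = phred_quality(scored$p_somatic[emit], config$phred_cap),
        filters_failed = ""
      )
    }
  }

  if ("loh" %in% config$detectors && nrow(sites) > 0L) {
    nmat <- as.matrix(sites[paste0("normal_", BASES)])
    colnames(nmat) <- BASES
    ref_i <- match(sites$ref, BASES)
    pick <- nmat
    pick[cbind(seq_len(nrow(pick)), ref_i)] <- -1L
    alt_i <- max.col(pick, ties.method = "first")
    idx <- cbind(seq_len(nrow(nmat)), alt_i)
    tmat <- as.matrix(sites[paste0("tumor_", BASES)])
    scored <- loh_probability(
      tibble::tibble(
        n_normal = sites$n_normal, k_normal = as.integer(nmat[idx]),
        n_tumor = sites$n_tumor, k_tumor = as.integer(tmat[idx])
      ),
      priors, config$loh_update_het, config$min_coverage
    )
    emit <- which(!is.na(scored$p_loh) & scored$p_loh > config$emission_threshold)
    if (length(emit) > 0L) {
      calls$loh <- tibble::tibble(
        contig = sites$contig[emit], position = sites$pos[emit],
        reference_allele = sites$ref[emit],
        alternate_allele = BASES[alt_i[emit]],
        event_kind = "loh",
        n_normal = scored$n_normal[emit], k_normal = scored$k_normal[emit],
        n_tumor = scored$n_tumor[emit], k_tumor = scored$k_tumor[emit],
        posterior_probability = scored$p_loh[emit],
        phred_quality = phred_quality(scored$p_loh[emit], config$phred_cap),
        filters_failed = ""
      )
    }
  }
  dplyr::bind_rows(calls)
}

#' Run a full paired tumor/normal analysis
#'
#' Walks the paired alignments contig by contig in reference order, merges
#' the two samples' filtered pileups at every covered locus, dispatches the
#' enabled detectors, and (when an `output_prefix` is configured) writes a
#' VCF v4.2 of focal somatic variants plus a tab-separated catalog of larger
#' structural events — the two-file output contract.
#'
#' @param config A [run_config()] object.
#' @return An object of class `pair_run`: list with `calls` (focal variants,
#'   one row per call), `sv_catalog` (structural-event regions), `ai` (an
#'   `ai_scan` object when the detector is enabled), `report`
#'   (one-row tibble of run statistics) and the `config`. Use
#'   [generics::tidy()] / [generics::glance()] to extract tidy tables.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  header <- Rsamtools::scanBamHeader(config$normal_bam)[[1]]$targets
  contigs <- names(header)
  if (!is.null(config$regions)) {
    missing <- setdiff(config$regions, contigs)
    if (length(missing) > 0L) {
      rlang::abort(sprintf(
        "region restriction names contigs absent from %s: %s",
        config$normal_bam, paste(missing, collapse = ", ")
      ))
    }
    contigs <- contigs[contigs %in% config$regions]
  }
  fa <- Rsamtools::FaFile(config$reference)

  sites_visited <- 0L
  sites_skipped <- 0L
  all_calls <- list()
  for (contig in contigs) {
    np <- bam_pileup_counts(config$normal_bam, contig, header[[contig]], config)
    tp <- bam_pileup_counts(config$tumor_bam, contig, header[[contig]], config)
    sites <- dplyr::full_join(np, tp, by = "pos", suffix = c("_normal", "_tumor"))
    sites <- dplyr::mutate(
      sites,
      dplyr::across(-"pos", \(x) dplyr::coalesce(x, 0L))
    )
    if (nrow(sites) == 0L) next
    sites <- dplyr::arrange(sites, .data$pos)
    refs <- Biostrings::getSeq(
      fa, GenomicRanges::GRanges(contig, IRanges::IRanges(sites$pos, width = 1))
    )
    sites$ref <- unname(as.character(refs))
    sites <- sites[sites$ref %in% BASES, , drop = FALSE]
    sites$contig <- contig
    # rename count columns to the caller's layout
    for (b in BASES) {
      names(sites)[names(sites) == paste0(b, "_normal")] <- paste0("normal_", b)
      names(sites)[names(sites) == paste0(b, "_tumor")] <- paste0("tumor_", b)
    }
    sites$n_normal <- as.integer(rowSums(as.matrix(sites[paste0("normal_", BASES)])))
    sites$n_tumor <- as.integer(rowSums(as.matrix(sites[paste0("tumor_", BASES)])))
    for (cl in c("ins_normal", "del_normal", "ins_tumor", "del_tumor")) {
      if (!cl %in% names(sites)) sites[[cl]] <- 0L
    }
    covered <- sites$n_normal >= config$min_coverage &
      sites$n_tumor >= config$min_coverage
    sites_visited <- sites_visited + nrow(sites)
    sites_skipped <- sites_skipped + sum(!covered)
    contig_calls <- call_contig(sites[covered, , drop = FALSE], config)
    if (!is.null(contig_calls) && nrow(contig_calls) > 0L) {
      all_calls[[contig]] <- contig_calls
    }
    message(sprintf(
      "%s: %d covered loci, %d calls", contig, sum(covered),
      if (is.null(contig_calls)) 0L else nrow(contig_calls)
    ))
  }
  calls <- dplyr::bind_rows(all_calls)
  if (nrow(calls) > 0L) {
    calls <- dplyr::arrange(
      calls, match(.data$contig, contigs), .data$position, .data$event_kind
    )
  }

  ai <- NULL
  if ("ai" %in% config$detectors) {
    ai <- ai_scan_bams(
      config$normal_bam, config$tumor_bam, config$reference,
      config$annotations,
      priors = config$priors, min_coverage = config$min_coverage,
      min_mapping_quality = config$min_mapping_quality,
      min_base_quality = config$min_base_quality,
      max_depth = config$max_depth
    )
  }

  sv_catalog <- NULL
  if ("sv" %in% config$detectors) {
    nf <- bam_fragments(config$normal_bam, config$regions)
    tf <- bam_fragments(config$tumor_bam, config$regions)
    sv_catalog <- sv_scan(
      nf, tf,
      model = NULL, priors = config$priors,
      window = config$sv_window, min_support = config$sv_min_support,
      min_coverage = config$min_coverage,
      min_mapping_quality = config$min_mapping_quality,
      phred_cap = config$phred_cap,
      min_insert_fragments = config$min_insert_fragments
    )
  }

  kinds <- c("substitution", "insertion", "deletion", "loh")
  ek <- calls[["event_kind"]]
  per_kind <- vapply(kinds, function(k) sum(!is.na(ek) & ek == k), integer(1))
  report <- tibble::tibble(
    contigs = length(contigs),
    sites_visited = sites_visited,
    sites_skipped_coverage = sites_skipped,
    calls_substitution = per_kind[["substitution"]],
    calls_insertion = per_kind[["insertion"]],
    calls_deletion = per_kind[["deletion"]],
    calls_loh = per_kind[["loh"]],
    sv_regions = if (is.null(sv_catalog)) 0L else nrow(sv_catalog),
    ai_loci = if (is.null(ai)) 0L else nrow(ai$per_locus)
  )

  result <- structure(
    list(
      calls = calls, sv_catalog = sv_catalog, ai = ai,
      report = report, config = config
    ),
    class = "pair_run"
  )
  if (!is.null(config$output_prefix)) {
    write_vcf(calls, paste0(config$output_prefix, ".vcf"), reference = config$reference)
    if (!is.null(sv_catalog)) {
      utils::write.table(
        sv_catalog, paste0(config$output_prefix, "_events.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
  }
  result
}

#' @export
print.pair_run <- function(x, ...) {
  cat("<pair_run>\n")
  print(x$report)
  invisible(x)
}

#' Write focal somatic calls as VCF v4.2
#'
#' One record per call: `QUAL` is the Phred-scaled posterior, `FILTER` names
#' failed filters (`PASS` otherwise; records failing filters are retained so
#' consumers can re-filter), `INFO` carries the posterior probability (`PP`)
#' and event kind (`EK`), and the two sample columns report per-sample depth
#' (`DP`) and variant-supporting count (`VC`).
#'
#' @param calls A calls tibble as produced by [run_analysis()], sorted by
#'   contig and position.
#' @param path Output path.
#' @param sample_names Names for the two genotype columns.
#' @param reference Optional reference FASTA path, recorded in the header and
#'   used to emit `##contig` lines from its index.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_names = c("NORMAL", "TUMOR"),
                      reference = NULL) {
  if (nrow(calls) > 0L) {
    by_contig <- split(calls$position, calls$contig)
    if (any(vapply(by_contig, is.unsorted, logical(1)))) {
      rlang::abort("calls must be sorted by position within each contig")
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=somaticpair",
    "##ALT=<ID=INS,Description=\"Small insertion relative to the reference\">",
    "##ALT=<ID=DEL,Description=\"Small deletion relative to the reference\">",
    "##FILTER=<ID=strand_bias,Description=\"Variant evidence on one strand only\">",
    "##INFO=<ID=PP,Number=1,Type=Float,Description=\"Posterior probability of the somatic event\">",
    "##INFO=<ID=EK,Number=1,Type=String,Description=\"Event kind: substitution, insertion, deletion or loh\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Filtered read depth\">",
    "##FORMAT=<ID=VC,Number=1,Type=Integer,Description=\"Reads supporting the variant class\">"
  )
  if (!is.null(reference)) {
    header <- c(header, sprintf("##reference=file://%s", normalizePath(reference)))
    fai <- paste0(reference, ".fai")
    if (file.exists(fai)) {
      idx <- utils::read.table(fai, sep = "\t", stringsAsFactors = FALSE)
      header <- c(header, sprintf("##contig=<ID=%s,length=%d>", idx[[1]], idx[[2]]))
    }
  }
  header <- c(header, paste(
    "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
    "FORMAT", sample_names[1], sample_names[2],
    sep = "\t"
  ))
  records <- character(0)
  if (nrow(calls) > 0L) {
    filter <- ifelse(
      is.na(calls$filters_failed) | calls$filters_failed == "",
      "PASS", calls$filters_failed
    )
    records <- paste(
      calls$contig, calls$position, ".",
      calls$reference_allele, calls$alternate_allele,
      sprintf("%.6f", calls$phred_quality), filter,
      sprintf("PP=%.17g;EK=%s", calls$posterior_probability, calls$event_kind),
      "DP:VC",
      sprintf("%d:%d", calls$n_normal, calls$k_normal),
      sprintf("%d:%d", calls$n_tumor, calls$k_tumor),
      sep = "\t"
    )
  }
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read gene annotations as merged transcript intervals
#'
#' Auto-detects BED or GFF3 by file extension and returns sorted, 0-based
#' half-open intervals. GFF3 exon rows are grouped under their transcript
#' (`Parent`, `transcript_id` or `ID` attribute, in that order) and
#' overlapping exons of one transcript are merged; BED rows (which carry no
#' transcript structure) are merged wherever they overlap and numbered.
#'
#' @param path A `.bed`, `.gff` or `.gff3` file.
#' @return A tibble with columns `contig`, `start` (0-based), `end`,
#'   `transcript_id`, sorted by contig and start. An empty file yields an
#'   empty tibble with a warning.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("annotation file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("bed", "gff", "gff3")) {
    rlang::abort(sprintf("unsupported annotation format '.%s' (use BED or GFF3)", ext))
  }
  if (length(readLines(path, n = 1)) == 0L) {
    warning(sprintf("annotation file %s is empty", path))
    return(tibble::tibble(
      contig = character(0), start = integer(0), end = integer(0),
      transcript_id = character(0)
    ))
  }
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) {
      rlang::abort(sprintf("failed to parse %s: %s", path, conditionMessage(e)))
    }
  )
  if (ext == "bed") {
    merged <- GenomicRanges::reduce(GenomicRanges::sort(gr))
    out <- tibble::tibble(
      contig = as.character(GenomicRanges::seqnames(merged)),
      start = GenomicRanges::start(merged) - 1L,
      end = GenomicRanges::end(merged),
      transcript_id = sprintf("interval_%d", seq_along(merged))
    )
  } else {
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md) && any(md$type == "exon")) gr <- gr[md$type == "exon"]
    md <- S4Vectors::mcols(gr)
    tid <- rep(NA_character_, length(gr))
    if ("Parent" %in% names(md)) {
      parent <- as.character(S4Vectors::unstrsplit(md$Parent, ","))
      tid <- ifelse(parent == "", NA_character_, parent)
    }
    if ("transcript_id" %in% names(md)) {
      tid <- dplyr::coalesce(tid, as.character(md$transcript_id))
    }
    if ("ID" %in% names(md)) tid <- dplyr::coalesce(tid, as.character(md$ID))
    tid[is.na(tid)] <- sprintf("feature_%d", which(is.na(tid)))
    by_tx <- S4Vectors::split(gr, tid)
    merged <- GenomicRanges::reduce(by_tx)
    flat <- unlist(merged)
    out <- tibble::tibble(
      contig = as.character(GenomicRanges::seqnames(flat)),
      start = GenomicRanges::start(flat) - 1L,
      end = GenomicRanges::end(flat),
      transcript_id = names(flat)
    )
  }
  dplyr::arrange(out, .data$contig, .data$start)
}
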