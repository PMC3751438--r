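# Miniature BAM/FASTA fixtures realising a simulated pair: every per-site
# read count from generate_pair() is written out as an aligned read, so the
# BAM walker must reproduce the generator's pileups exactly. Used as the
# end-to-end test surface; all files are generated at run time.

random_sequence <- function(length) {
  paste(sample(BASES, length, replace = TRUE), collapse = "")
}

# Assemble SAM lines for single-end reads realising per-base counts at sites.
# Returns a character vector of alignment lines.
site_read_lines <- function(sites, counts, contig, contig_seq, read_length, prefix) {
  long <- purrr::map_dfr(seq_along(BASES), function(b) {
    tibble::tibble(pos = sites$pos, base = BASES[b], n = counts[, b])
  })
  long <- tidyr::uncount(long[long$n > 0L, , drop = FALSE], .data$n)
  if (nrow(long) == 0L) return(character(0))
  long <- long |>
    dplyr::arrange(.data$pos) |>
    dplyr::group_by(.data$pos) |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::ungroup()
  start <- long$pos - ((long$.ord - 1L) %% read_length)
  start <- pmax(start, 1L)
  seq <- substring(contig_seq, start, start + read_length - 1L)
  at <- long$pos - start + 1L
  substr(seq, at, at) <- long$base
  flag <- ifelse(long$.ord %% 2L == 0L, 16L, 0L)
  paste(
    paste0(prefix, "_s", seq_len(nrow(long))),
    flag, contig, start, 60L, paste0(read_length, "M"),
    "*", 0L, 0L, seq, strrep("I", read_length),
    sep = "\t"
  )
}

# Proper FR pairs at given leftmost positions with given insert sizes.
pair_lines <- function(contig, left, insert, contig_seq, read_length, prefix) {
  mate <- left + insert - read_length
  seq1 <- substring(contig_seq, left, left + read_length - 1L)
  seq2 <- substring(contig_seq, mate, mate + read_length - 1L)
  q <- strrep("I", read_length)
  id <- paste0(prefix, "_p", seq_along(left))
  c(
    paste(id, 99L, contig, left, 60L, paste0(read_length, "M"),
      "=", mate, insert, seq1, q,
      sep = "\t"
    ),
    paste(id, 147L, contig, mate, 60L, paste0(read_length, "M"),
      "=", left, -insert, seq2, q,
      sep = "\t"
    )
  )
}

# Inter-contig (translocation-like) pairs: read on contig1, mate on contig2.
trans_lines <- function(contig1, pos1, contig2, pos2, seq1, seq2, read_length, prefix) {
  q <- strrep("I", read_length)
  id <- paste0(prefix, "_t", seq_along(pos1))
  c(
    paste(id, 65L, contig1, pos1, 60L, paste0(read_length, "M"),
      contig2, pos2, 0L, substring(seq1, pos1, pos1 + read_length - 1L), q,
      sep = "\t"
    ),
    paste(id, 129L, contig2, pos2, 60L, paste0(read_length, "M"),
      contig1, pos1, 0L, substring(seq2, pos2, pos2 + read_length - 1L), q,
      sep = "\t"
    )
  )
}

#' Emit a miniature BAM/FASTA fixture pair realising a simulated experiment
#'
#' Writes a small synthetic reference (two contigs), coordinate-sorted and
#' indexed BAM files for the normal and tumor samples whose pileups exactly
#' realise the per-site counts drawn by [generate_pair()], and a tab-separated
#' truth table. Site reads are single-end, placed so that each read covers
#' exactly one simulated site; both samples additionally receive proper FR
#' mate pairs (for insert-model estimation), and the tumor can carry an
#' engineered somatic translocation cluster on contig 1 with mates
#' co-clustered on contig 2.
#'
#' @param config A [sim_config()] object (keep `n_sites` modest; each site
#'   occupies `site_spacing` bp of reference).
#' @param dir Output directory (created if missing).
#' @param read_length Read length in bp.
#' @param site_spacing Distance between simulated sites (must exceed
#'   `read_length` so sites do not share reads).
#' @param n_proper_pairs Proper FR pairs per sample (insert ~ Normal(300, 30)).
#' @param n_translocation_pairs Discordant tumor-only pairs forming one
#'   translocation cluster (0 = none).
#' @return A list with paths (`reference`, `normal_bam`, `tumor_bam`,
#'   `truth`), the `sites` tibble (with `contig`/`pos` columns appended) and,
#'   when engineered, the translocation cluster's `sv_region`.
#' @export
emit_bam_fixtures <- function(config, dir,
                              read_length = 50L,
                              site_spacing = 150L,
                              n_proper_pairs = 1200L,
                              n_translocation_pairs = 0L) {
  stopifnot(inherits(config, "sim_config"))
  if (site_spacing <= read_length) rlang::abort("site_spacing must exceed read_length")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  sites <- generate_pair(config)
  n <- nrow(sites)
  withr::local_seed(config$seed + 17L)

  len1 <- (n + 2L) * site_spacing + 14000L
  len2 <- 8000L
  seq1 <- random_sequence(len1)
  seq2 <- random_sequence(len2)
  pos <- site_spacing * seq_len(n) + read_length

  # the reference must carry each site's reference base
  for (i in seq_len(n)) substr(seq1, pos[i], pos[i]) <- sites$ref[i]

  fasta <- file.path(dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(c(sim1 = seq1, sim2 = seq2))
  Biostrings::writeXStringSet(dna, fasta)
  Rsamtools::indexFa(fasta)

  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:sim1\tLN:%d", len1),
    sprintf("@SQ\tSN:sim2\tLN:%d", len2)
  )

  # proper pairs: half on the tail of sim1 (beyond the sites), half on sim2
  pair_region1 <- (n + 1L) * site_spacing + read_length
  make_sample <- function(sample) {
    counts <- as.matrix(sites[paste0(sample, "_", BASES)])
    lines <- site_read_lines(
      tibble::tibble(pos = pos), counts, "sim1", seq1, read_length, sample
    )
    half <- n_proper_pairs %/% 2L
    ins <- pmax(round(stats::rnorm(n_proper_pairs, 300, 30)), 2L * read_length + 10L)
    left1 <- sample(pair_region1:(pair_region1 + 5000L), half, replace = TRUE)
    left2 <- sample(1:(len2 - 500L), n_proper_pairs - half, replace = TRUE)
    lines <- c(
      lines,
      pair_lines("sim1", left1, ins[seq_len(half)], seq1, read_length, paste0(sample, "_1")),
      pair_lines("sim2", left2, ins[-seq_len(half)], seq2, read_length, paste0(sample, "_2"))
    )
    lines
  }
  normal_lines <- make_sample("normal")
  tumor_lines <- make_sample("tumor")

  sv_region <- NULL
  if (n_translocation_pairs > 0L) {
    # a quiet zone far from the proper-pair region, so the candidate
    # region's fragment trials are dominated by the engineered event
    sv_pos <- len1 - 4000L
    pos1 <- sv_pos + sample(0:400, n_translocation_pairs, replace = TRUE)
    pos2 <- 3000L + sample(0:400, n_translocation_pairs, replace = TRUE)
    tumor_lines <- c(
      tumor_lines,
      trans_lines("sim1", pos1, "sim2", pos2, seq1, seq2, read_length, "tumor")
    )
    # concordant normal (and tumor) coverage over the same region, so the
    # candidate region has fragment trials in both samples
    ins <- pmax(round(stats::rnorm(20L, 300, 30)), 2L * read_length + 10L)
    covl <- sv_pos + sample(0:400, 20L, replace = TRUE)
    normal_lines <- c(normal_lines, pair_lines("sim1", covl, ins, seq1, read_length, "normal_sv"))
    tumor_lines <- c(tumor_lines, pair_lines("sim1", covl, ins, seq1, read_length, "tumor_svc"))
    sv_region <- tibble::tibble(
      contig = "sim1", start = min(pos1), end = max(pos1),
      mate_contig = "sim2", n_pairs = n_translocation_pairs
    )
  }

  write_bam <- function(lines, stem) {
    sam <- file.path(dir, paste0(stem, ".sam"))
    writeLines(c(header, lines), sam)
    bam <- Rsamtools::asBam(
      sam, file.path(dir, stem),
      overwrite = TRUE, indexDestination = TRUE
    )
    unlink(sam)
    bam
  }
  normal_bam <- write_bam(normal_lines, "normal")
  tumor_bam <- write_bam(tumor_lines, "tumor")

  sites_out <- dplyr::mutate(sites, contig = "sim1", pos = pos, .after = "site")
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(
    dplyr::select(
      sites_out, "site", "contig", "pos", "ref", "alt", "genotype", "somatic"
    ),
    truth_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  list(
    reference = fasta,
    normal_bam = normal_bam,
    tumor_bam = tumor_bam,
    truth = truth_path,
    sites = sites_out,
    sv_region = sv_region
  )
}
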