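# BAM-backed allelic-imbalance scan: pileups from two alignment files
# (e.g. normal RNA as reference, tumor RNA as test — or DNA vs RNA) at
# heterozygous loci inside annotated transcripts.

#' Scan two alignment files for allelic imbalance within annotated transcripts
#'
#' Builds paired pileup counts over every contig named in the annotations,
#' identifies candidate heterozygous loci from the reference sample (top
#' non-reference base, germline heterozygous posterior above
#' `het_posterior`), and runs [transcript_scan()] on them.
#'
#' @param reference_bam,test_bam Indexed BAM files for the reference and test
#'   datasets (the tied model updates toward the reference sample's allele
#'   proportions).
#' @param reference Indexed reference FASTA.
#' @param annotations Annotation tibble from [read_annotations()], or a path
#'   to a BED/GFF3 file.
#' @param priors A [pair_priors()] object.
#' @param min_coverage Coverage gate per sample at a locus.
#' @param het_posterior Minimum reference-sample heterozygous posterior for a
#'   locus to enter the scan.
#' @param prior_odds Prior odds of tied proportions, see [transcript_scan()].
#' @param min_mapping_quality,min_base_quality,max_depth Pileup filters.
#' @return An `ai_scan` object (see [transcript_scan()]).
#' @export
ai_scan_bams <- function(reference_bam, test_bam, reference, annotations,
                         priors = pair_priors(), min_coverage = 5,
                         het_posterior = 0.9, prior_odds = 1,
                         min_mapping_quality = 10, min_base_quality = 10,
                         max_depth = 10000) {
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  cfg <- list(
    min_mapping_quality = min_mapping_quality,
    min_base_quality = min_base_quality,
    max_depth = max_depth
  )
  header <- Rsamtools::scanBamHeader(reference_bam)[[1]]$targets
  contigs <- intersect(names(header), unique(annotations$contig))
  fa <- Rsamtools::FaFile(reference)
  loci <- purrr::map_dfr(contigs, function(contig) {
    rp <- bam_pileup_counts(reference_bam, contig, header[[contig]], cfg)
    tp <- bam_pileup_counts(test_bam, contig, header[[contig]], cfg)
    sites <- dplyr::inner_join(rp, tp, by = "pos", suffix = c("_ref", "_test"))
    if (nrow(sites) == 0L) return(NULL)
    refs <- Biostrings::getSeq(
      fa, GenomicRanges::GRanges(contig, IRanges::IRanges(sites$pos, width = 1))
    )
    sites$refbase <- unname(as.character(refs))
    sites <- sites[sites$refbase %in% BASES, , drop = FALSE]
    if (nrow(sites) == 0L) return(NULL)
    rmat <- as.matrix(sites[paste0(BASES, "_ref")])
    tmat <- as.matrix(sites[paste0(BASES, "_test")])
    ref_i <- match(sites$refbase, BASES)
    pick <- rmat
    pick[cbind(seq_len(nrow(pick)), ref_i)] <- -1L
    alt_i <- max.col(pick, ties.method = "first")
    idx <- cbind(seq_len(nrow(rmat)), alt_i)
    tibble::tibble(
      contig = contig, position = sites$pos,
      n_reference = as.integer(rowSums(rmat)),
      k_reference = as.integer(rmat[idx]),
      n_test = as.integer(rowSums(tmat)),
      k_test = as.integer(tmat[idx])
    )
  })
  if (nrow(loci) == 0L) {
    loci <- tibble::tibble(
      contig = character(0), position = integer(0),
      n_reference = integer(0), k_reference = integer(0),
      n_test = integer(0), k_test = integer(0)
    )
  }
  if (nrow(loci) > 0L) {
    het <- germline_posterior(
      pileup_summary(loci$n_reference, loci$k_reference), priors
    )$p_het
    loci <- loci[het >= het_posterior, , drop = FALSE]
  }
  transcript_scan(loci, annotations, priors, prior_odds, min_coverage)
}
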