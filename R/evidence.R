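# Converting aligned-read observations over a locus into filtered Bernoulli
# trials for one evidence class at a time. Observations live in plain tibbles
# so pileups can be built, filtered and summarised with ordinary dplyr verbs.

BASES <- c("A", "C", "G", "T")

#' Build a tibble of per-read observations at a locus
#'
#' One row per aligned read covering the locus. `base` is the aligned
#' nucleotide (`"-"` inside a deletion, `"N"` for an uncalled base);
#' `indel` marks an insertion/deletion edit anchored at this locus
#' (left-aligned, at the reference base immediately preceding the event),
#' encoded as `"ins:SEQ"` or `"del:LEN"`, `NA` for reads spanning the anchor
#' without the edit. `adjusted_quality` carries a per-base alignment-adjusted
#' quality (BAQ-style) when the aligner provides one; it is consumed, never
#' recomputed.
#'
#' @param base Character vector of aligned bases (`A/C/G/T/N/-`).
#' @param base_quality,mapping_quality Phred-scaled non-negative integers.
#' @param strand `"+"` or `"-"`.
#' @param indel Optional indel edit codes (`"ins:ACGT"`, `"del:3"`), `NA`
#'   when absent.
#' @param adjusted_quality Optional Phred-scaled adjusted base qualities,
#'   `NA` when absent.
#' @return A tibble with one row per observation.
#' @examples
#' read_observations(c("A", "T"), c(30, 31), c(60, 60), c("+", "-"))
#' @export
read_observations <- function(base, base_quality, mapping_quality,
                              strand = "+", indel = NA_character_,
                              adjusted_quality = NA_real_) {
  obs <- tibble::tibble(
    base = as.character(base),
    base_quality = as.numeric(base_quality),
    mapping_quality = as.numeric(mapping_quality),
    strand = as.character(strand),
    indel = as.character(indel),
    adjusted_quality = as.numeric(adjusted_quality)
  )
  if (any(obs$base_quality < 0, na.rm = TRUE) || any(obs$mapping_quality < 0, na.rm = TRUE)) {
    rlang::abort("quality scores must be non-negative")
  }
  if (!all(obs$strand %in% c("+", "-"))) rlang::abort('strand must be "+" or "-"')
  obs
}

#' Quality-filter read observations
#'
#' Drops observations whose mapping quality or (possibly adjusted) base
#' quality falls below the thresholds, and observations with an uncalled
#' base (`N`). Thresholds are inclusive: a read at exactly the threshold is
#' kept. When `use_adjusted_quality` is `TRUE` and an adjusted (BAQ-style)
#' quality is present for a read, it substitutes for the raw base quality.
#'
#' @param observations A tibble from [read_observations()].
#' @param min_mapping_quality,min_base_quality Phred thresholds; both default
#'   to 10 (i.e. <90% confidence calls are discarded).
#' @param use_adjusted_quality Use `adjusted_quality` in place of
#'   `base_quality` where available.
#' @return The filtered tibble. Idempotent.
#' @examples
#' obs <- read_observations(c("A", "T"), c(30, 9), c(60, 60))
#' filter_observations(obs)
#' @export
filter_observations <- function(observations,
                                min_mapping_quality = 10,
                                min_base_quality = 10,
                                use_adjusted_quality = FALSE) {
  bq <- observations$base_quality
  if (use_adjusted_quality && "adjusted_quality" %in% names(observations)) {
    aq <- observations$adjusted_quality
    bq <- ifelse(!is.na(aq), aq, bq)
  }
  keep <- observations$mapping_quality >= min_mapping_quality &
    bq >= min_base_quality &
    observations$base != "N"
  observations[keep, , drop = FALSE]
}

#' Evidence classes
#'
#' An evidence class names the single genotype change being proposed at a
#' locus, so that every observation can be labelled a Bernoulli success
#' (supports that change) or failure (anything else). Substitution classes
#' are encoded by their alternate base (`"A"`, `"C"`, `"G"`, `"T"`);
#' insertions and deletions by `"ins"` and `"del"`.
#'
#' @param alt Alternate base for a substitution class.
#' @return A character evidence-class code.
#' @examples
#' ev_substitution("T")
#' ev_insertion()
#' @name evidence_class
NULL

#' @rdname evidence_class
#' @export
ev_substitution <- function(alt) {
  alt <- as.character(alt)
  if (!all(alt %in% BASES)) rlang::abort("substitution alt must be one of A, C, G, T")
  alt
}

#' @rdname evidence_class
#' @export
ev_insertion <- function() "ins"

#' @rdname evidence_class
#' @export
ev_deletion <- function() "del"

#' Summarise a filtered pileup into Bernoulli trial counts
#'
#' Counts, for one evidence class, the informative observations (`n_trials`)
#' and the successes (`k_successes`). For a substitution class the trials are
#' the observations with a called base (reads inside a deletion contribute no
#' substitution trial) and a success is a base equal to the tested alternate;
#' bases matching neither reference nor alternate count as failures. For
#' insertion/deletion classes every read spanning the anchor is a trial and a
#' success is a read carrying a matching edit at the anchor.
#'
#' @param observations A filtered observation tibble.
#' @param reference_base Reference base at the locus.
#' @param evidence_class A class code from [ev_substitution()],
#'   [ev_insertion()] or [ev_deletion()].
#' @return A one-row tibble with `n_trials` and `k_successes`.
#' @examples
#' obs <- read_observations(rep(c("A", "T"), c(20, 8)), 30, 60)
#' summarize_pileup(obs, "A", ev_substitution("T"))
#' @export
summarize_pileup <- function(observations, reference_base, evidence_class) {
  if (evidence_class %in% BASES) {
    informative <- observations$base %in% BASES
    success <- informative & observations$base == evidence_class
  } else if (evidence_class %in% c("ins", "del")) {
    informative <- rep(TRUE, nrow(observations))
    tag <- paste0(evidence_class, ":")
    success <- !is.na(observations$indel) & startsWith(observations$indel, tag)
  } else {
    rlang::abort("unknown evidence class")
  }
  pileup_summary(sum(informative), sum(success))
}

#' Enumerate candidate variant subclasses in a pileup
#'
#' Lists the evidence subclasses supported by at least one observation,
#' ordered by descending support so that the detectors test the
#' best-supported change first. Ties break on a fixed order:
#' `A < C < G < T`, then insertion, then deletion.
#'
#' @inheritParams summarize_pileup
#' @return Character vector of evidence-class codes (possibly empty).
#' @examples
#' obs <- read_observations(c(rep("G", 5), rep("T", 2), rep("A", 10)), 30, 60)
#' select_variant_subclass(obs, "A")
#' @export
select_variant_subclass <- function(observations, reference_base) {
  counts <- vapply(
    setdiff(BASES, reference_base),
    function(b) sum(observations$base == b),
    integer(1)
  )
  indel <- observations$indel
  counts <- c(
    counts,
    ins = sum(!is.na(indel) & startsWith(indel, "ins:")),
    del = sum(!is.na(indel) & startsWith(indel, "del:"))
  )
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) return(character(0))
  # stable order: candidates are already in A<C<G<T<ins<del order, and
  # sort(decreasing) with method "radix" is stable on ties
  names(sort(counts, decreasing = TRUE, method = "radix"))
}

#' Strand-bias filter
#'
#' Variant evidence present on only one strand usually indicates a mapping
#' artifact. The filter passes when the success-class observations include at
#' least one forward-strand and one reverse-strand read.
#'
#' @param variant_observations Observations supporting the candidate variant
#'   (success class only).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @examples
#' strand_bias_filter(read_observations("T", 30, 60, strand = c("+")))
#' @export
strand_bias_filter <- function(variant_observations) {
  any(variant_observations$strand == "+") && any(variant_observations$strand == "-")
}
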