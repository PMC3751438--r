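# broom-style accessors for run objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the focal calls of a paired run
#'
#' @param x A `pair_run` object from [run_analysis()].
#' @param ... Ignored.
#' @return The calls tibble (one row per focal somatic call).
#' @exportS3Method generics::tidy
tidy.pair_run <- function(x, ...) tibble::as_tibble(x$calls)

#' One-row run summary
#'
#' @param x A `pair_run` object from [run_analysis()].
#' @param ... Ignored.
#' @return The run-report tibble: loci visited, loci skipped for coverage,
#'   calls per event class, structural-event regions.
#' @exportS3Method generics::glance
glance.pair_run <- function(x, ...) x$report

#' Tidy per-transcript allelic-imbalance results
#'
#' @param x An `ai_scan` object from [transcript_scan()].
#' @param ... Ignored.
#' @return The per-transcript tibble.
#' @exportS3Method generics::tidy
tidy.ai_scan <- function(x, ...) x$per_transcript

#' One-row allelic-imbalance scan summary
#'
#' @param x An `ai_scan` object from [transcript_scan()].
#' @param ... Ignored.
#' @return A one-row tibble of scan counts.
#' @exportS3Method generics::glance
glance.ai_scan <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x$per_locus),
    n_transcripts = nrow(x$per_transcript),
    n_uncovered_transcripts = x$n_uncovered_transcripts
  )
}
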