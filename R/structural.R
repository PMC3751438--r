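# Somatic structural variation from mate-pair discordance. A fragment whose
# mate maps to another contig, at an unexpected distance, or in an unexpected
# orientation is a unit of variant evidence; clustered abnormal fragments are
# scored with the same two-sample formula as point mutations, over fragment
# counts instead of base counts.

#' Build a tibble of mate-pair fragment observations
#'
#' One row per fragment (read with a mapped mate). `insert_size` is the
#' signed template length and is only meaningful for same-contig pairs;
#' `orientation` is the relative strand layout (`FR` is the expected
#' configuration for standard paired-end libraries).
#'
#' @param contig,start Alignment contig and position of the read.
#' @param mate_contig,mate_position Alignment of the mate.
#' @param insert_size Signed insert size in bp (`NA` for inter-contig pairs).
#' @param orientation One of `"FR"`, `"RF"`, `"FF"`, `"RR"`.
#' @param mapping_quality Phred-scaled mapping quality.
#' @return A tibble with one row per fragment.
#' @export
fragment_observations <- function(contig, start, mate_contig, mate_position,
                                  insert_size = NA_real_, orientation = "FR",
                                  mapping_quality = 60) {
  frag <- tibble::tibble(
    contig = as.character(contig),
    start = as.integer(start),
    mate_contig = as.character(mate_contig),
    mate_position = as.integer(mate_position),
    insert_size = as.numeric(insert_size),
    orientation = as.character(orientation),
    mapping_quality = as.numeric(mapping_quality)
  )
  if (!all(frag$orientation %in% c("FR", "RF", "FF", "RR"))) {
    rlang::abort('orientation must be one of "FR", "RF", "FF", "RR"')
  }
  if (any(!is.na(frag$insert_size) & frag$contig != frag$mate_contig)) {
    rlang::abort("insert_size is only defined for same-contig pairs")
  }
  frag
}

#' Estimate the library insert-size model
#'
#' Robust location/scale summary of the insert sizes of proper (same-contig,
#' FR-oriented) fragments: the median and the MAD (scaled to be consistent
#' with the normal standard deviation, floored at 1 bp so degenerate
#' libraries still yield a usable model). A fragment is later called
#' discordant-by-distance when its insert exceeds
#' `median + discordance_multiplier * spread`.
#'
#' @param fragments A [fragment_observations()] tibble of proper fragments
#'   (rows with other orientations or contigs are ignored).
#' @param min_fragments Minimum number of proper fragments required
#'   (default 1000).
#' @param discordance_multiplier Multiplier on the spread (default 5).
#' @return An object of class `insert_model`: list with `median`, `spread`,
#'   `discordance_multiplier`.
#' @export
estimate_insert_model <- function(fragments, min_fragments = 1000,
                                  discordance_multiplier = 5) {
  proper <- fragments[
    fragments$orientation == "FR" & fragments$contig == fragments$mate_contig,
    ,
    drop = FALSE
  ]
  sizes <- abs(proper$insert_size)
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) < min_fragments) {
    rlang::abort(sprintf(
      "insert-model estimation needs at least %d proper fragments, got %d",
      min_fragments, length(sizes)
    ))
  }
  structure(
    list(
      median = stats::median(sizes),
      spread = max(stats::mad(sizes), 1),
      discordance_multiplier = discordance_multiplier
    ),
    class = "insert_model"
  )
}

#' @export
print.insert_model <- function(x, ...) {
  cat(sprintf(
    "<insert_model> median %g bp, spread %g bp (discordant beyond %g bp)\n",
    x$median, x$spread, x$median + x$discordance_multiplier * x$spread
  ))
  invisible(x)
}

#' Classify fragments as concordant or abnormal
#'
#' Partitions every fragment into exactly one label:
#' `translocation` (mate on a different contig), `inversion` (FF or RR
#' orientation), `large_deletion` (proper orientation but insert size beyond
#' `median + multiplier * spread`), else `concordant`.
#'
#' @param fragments A [fragment_observations()] tibble.
#' @param model An [estimate_insert_model()] object.
#' @return The input tibble with an `sv_class` column appended.
#' @export
classify_fragment <- function(fragments, model) {
  stopifnot(inherits(model, "insert_model"))
  cutoff <- model$median + model$discordance_multiplier * model$spread
  cls <- dplyr::case_when(
    fragments$contig != fragments$mate_contig ~ "translocation",
    fragments$orientation %in% c("FF", "RR") ~ "inversion",
    abs(fragments$insert_size) > cutoff ~ "large_deletion",
    TRUE ~ "concordant"
  )
  dplyr::mutate(tibble::as_tibble(fragments), sv_class = cls)
}

# Single-linkage clustering of sorted positions with gap <= window.
# Returns an integer cluster id per position (in input order).
gap_cluster <- function(pos, window) {
  ord <- order(pos)
  sorted <- pos[ord]
  breaks <- c(FALSE, diff(sorted) > window)
  ids <- cumsum(breaks) + 1L
  out <- integer(length(pos))
  out[ord] <- ids
  out
}

#' Cluster abnormal fragments of one subclass into candidate regions
#'
#' Single-linkage clustering along the reference: fragments of the same
#' subclass on the same contig whose positions are within `window` of the
#' next fragment merge into one candidate region. Translocation clusters
#' additionally require the mate positions to co-cluster within `window` on a
#' single mate contig; mate sub-clusters holding a single fragment are
#' dropped (a lone pair defines no co-cluster).
#'
#' @param fragments A classified tibble (see [classify_fragment()]) holding
#'   fragments of a *single* abnormal subclass.
#' @param window Maximum gap in bp between neighbouring fragments of one
#'   cluster (default 1000).
#' @return A tibble with one row per candidate region: `contig`, `start`,
#'   `end`, `sv_class`, `n_fragments`, and for translocations `mate_contig`,
#'   `mate_start`, `mate_end` (`NA` otherwise).
#' @export
cluster_abnormal <- function(fragments, window = 1000) {
  stopifnot("sv_class" %in% names(fragments))
  cls <- unique(fragments$sv_class)
  if (length(cls) > 1L) rlang::abort("cluster_abnormal expects a single subclass")
  if (nrow(fragments) == 0L) {
    return(tibble::tibble(
      contig = character(0), start = integer(0), end = integer(0),
      sv_class = character(0), n_fragments = integer(0),
      mate_contig = character(0), mate_start = integer(0), mate_end = integer(0)
    ))
  }
  frag <- dplyr::arrange(tibble::as_tibble(fragments), .data$contig, .data$start)
  frag <- frag |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(.cluster = gap_cluster(.data$start, window)) |>
    dplyr::ungroup()
  if (cls == "translocation") {
    # mates must land on one contig and co-cluster within the window
    frag <- frag |>
      dplyr::group_by(.data$contig, .data$.cluster, .data$mate_contig) |>
      dplyr::mutate(.mate_cluster = gap_cluster(.data$mate_position, window)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$contig, .data$.cluster, .data$mate_contig, .data$.mate_cluster)
  } else {
    frag <- dplyr::group_by(frag, .data$contig, .data$.cluster)
  }
  out <- frag |>
    dplyr::summarise(
      end = max(.data$start),
      start = min(.data$start),
      n_fragments = dplyr::n(),
      mate_contig = if (cls == "translocation") .data$mate_contig[1] else NA_character_,
      mate_start = if (cls == "translocation") min(.data$mate_position) else NA_integer_,
      mate_end = if (cls == "translocation") max(.data$mate_position) else NA_integer_,
      .groups = "drop"
    ) |>
    dplyr::mutate(sv_class = cls) |>
    # a lone inter-contig pair defines no mate co-cluster
    dplyr::filter(cls != "translocation" | .data$n_fragments >= 2L) |>
    dplyr::select(
      "contig", "start", "end", "sv_class", "n_fragments",
      "mate_contig", "mate_start", "mate_end"
    ) |>
    dplyr::arrange(.data$contig, .data$start)
  out
}

#' Probability of a somatic structural event from fragment counts
#'
#' Identical computation to [somatic_probability()] — the same code path —
#' applied to fragment-level trials: `n` counts all fragments overlapping a
#' candidate region in a sample, `k` the abnormal fragments of the tested
#' subclass.
#'
#' @inheritParams somatic_probability
#' @return The input tibble with a `p_somatic` column appended.
#' @export
somatic_sv_probability <- function(data, priors = pair_priors(), min_coverage = 5) {
  somatic_probability(data, priors, min_coverage)
}

#' Scan paired samples for somatic structural variation
#'
#' Classifies both samples' fragments against the insert model (estimated
#' from the normal sample's proper pairs when not supplied), clusters the
#' tumor's abnormal fragments per subclass into candidate regions, counts
#' supporting and overlapping fragments per sample in each region, and scores
#' each region with [somatic_sv_probability()].
#'
#' @param normal_fragments,tumor_fragments [fragment_observations()] tibbles.
#' @param model An [estimate_insert_model()] object, or `NULL` to estimate
#'   from the normal fragments.
#' @param priors A [pair_priors()] object.
#' @param window Clustering window in bp.
#' @param min_support Minimum abnormal tumor fragments for a candidate region
#'   to be scored (default 3).
#' @param min_coverage Coverage gate on fragment counts per sample.
#' @param min_mapping_quality Fragments below this mapping quality are
#'   ignored.
#' @param phred_cap Quality cap for [phred_quality()].
#' @param min_insert_fragments Passed to [estimate_insert_model()].
#' @return A tibble catalog of candidate somatic structural events: region,
#'   subclass, per-sample counts, posterior probability and Phred quality.
#' @export
sv_scan <- function(normal_fragments, tumor_fragments, model = NULL,
                    priors = pair_priors(), window = 1000, min_support = 3,
                    min_coverage = 5, min_mapping_quality = 10,
                    phred_cap = 255, min_insert_fragments = 1000) {
  normal_fragments <- normal_fragments[
    normal_fragments$mapping_quality >= min_mapping_quality, ,
    drop = FALSE
  ]
  tumor_fragments <- tumor_fragments[
    tumor_fragments$mapping_quality >= min_mapping_quality, ,
    drop = FALSE
  ]
  if (is.null(model)) {
    model <- estimate_insert_model(normal_fragments, min_insert_fragments)
  }
  ncls <- classify_fragment(normal_fragments, model)
  tcls <- classify_fragment(tumor_fragments, model)

  subclasses <- setdiff(unique(tcls$sv_class), "concordant")
  catalogs <- purrr::map(subclasses, function(cl) {
    clusters <- cluster_abnormal(tcls[tcls$sv_class == cl, , drop = FALSE], window)
    clusters <- clusters[clusters$n_fragments >= min_support, , drop = FALSE]
    if (nrow(clusters) == 0L) return(NULL)
    counts <- purrr::pmap_dfr(
      clusters,
      function(contig, start, end, sv_class, n_fragments, ...) {
        in_region <- function(x) {
          x$contig == contig & x$start >= start - window & x$start <= end + window
        }
        t_in <- tcls[in_region(tcls), , drop = FALSE]
        n_in <- ncls[in_region(ncls), , drop = FALSE]
        tibble::tibble(
          n_normal = nrow(n_in),
          k_normal = sum(n_in$sv_class == sv_class),
          n_tumor = nrow(t_in),
          k_tumor = sum(t_in$sv_class == sv_class)
        )
      }
    )
    dplyr::bind_cols(clusters, counts)
  })
  catalog <- dplyr::bind_rows(catalogs)
  if (is.null(catalog) || nrow(catalog) == 0L) {
    return(tibble::tibble(
      contig = character(0), start = integer(0), end = integer(0),
      sv_class = character(0), n_fragments = integer(0),
      mate_contig = character(0), mate_start = integer(0), mate_end = integer(0),
      n_normal = integer(0), k_normal = integer(0),
      n_tumor = integer(0), k_tumor = integer(0),
      posterior_probability = numeric(0), phred_quality = numeric(0)
    ))
  }
  scored <- somatic_sv_probability(catalog, priors, min_coverage)
  scored |>
    dplyr::rename(posterior_probability = "p_somatic") |>
    dplyr::mutate(phred_quality = phred_quality(.data$posterior_probability, phred_cap)) |>
    dplyr::arrange(.data$contig, .data$start)
}
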