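#' Align reads to reference features
#'
#' End-to-end ungapped placement of each read on every feature, both
#' strands, substitutions only. All placements at the minimum observed
#' mismatch count for the read (best stratum) are reported. Multi-mapping
#' reads are resolved by `policy`: `"fractional"` spreads weight 1/k over
#' the k best-stratum placements; `"unique_only"` drops reads with k > 1
#' and counts them separately.
#'
#' Coordinates are 0-based on the plus strand; `start` is the read's
#' leftmost base. A sense read's biological 5' end is at `start`; an
#' antisense read's 5' end is at `start + length - 1`.
#'
#' @param reads tibble of reads.
#' @param features tibble with `name` and `seq` (alignment targets only).
#' @param max_mismatch maximum substitutions (default 1).
#' @param policy `"fractional"` (default) or `"unique_only"`.
#' @return tibble with `read_id`, `feature`, `start`, `orientation`,
#'   `mismatches`, `length`, `weight`; attribute `align_stats` carries
#'   `input`, `aligned`, `unaligned` and `multimap_dropped` counts.
#' @export
align_reads <- function(reads, features, max_mismatch = 1,
                        policy = c("fractional", "unique_only")) {
  policy <- match.arg(policy)
  if (nrow(features) == 0) abort("`features` must be non-empty")
  if (nrow(reads) == 0) {
    out <- tibble::tibble(read_id = character(), feature = character(),
                          start = integer(), orientation = character(),
                          mismatches = integer(), length = integer(),
                          weight = numeric())
    attr(out, "align_stats") <- c(input = 0L, aligned = 0L, unaligned = 0L,
                                  multimap_dropped = 0L)
    return(out)
  }
  hits <- .align_scan_cpp(reads$seq, features$seq, as.integer(max_mismatch))
  out <- tibble::tibble(
    read_id = reads$read_id[hits$read],
    feature = features$name[hits$ref],
    start = hits$start,
    orientation = ifelse(hits$sense == 1, "sense", "antisense"),
    mismatches = hits$mismatches,
    length = reads$length[hits$read]
  ) %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::mutate(n_placements = dplyr::n()) %>%
    dplyr::ungroup()

  n_aligned_reads <- dplyr::n_distinct(out$read_id)
  multimap <- 0L
  if (policy == "fractional") {
    out <- out %>% dplyr::mutate(weight = 1 / .data$n_placements)
  } else {
    multimap <- dplyr::n_distinct(out$read_id[out$n_placements > 1])
    out <- out %>% dplyr::filter(.data$n_placements == 1) %>%
      dplyr::mutate(weight = 1)
  }
  out <- out %>% dplyr::select(-"n_placements")
  attr(out, "align_stats") <- c(input = nrow(reads),
                                aligned = n_aligned_reads,
                                unaligned = nrow(reads) - n_aligned_reads,
                                multimap_dropped = multimap)
  out
}

#' Align a single read against one feature
#'
#' Convenience wrapper around the alignment kernel for one read/feature
#' pair; returns every best-stratum placement.
#'
#' @param read a single-row read tibble (or list with `read_id`, `seq`).
#' @param feature single-row tibble with `name`, `seq`.
#' @param max_mismatch maximum substitutions (default 1).
#' @return alignment tibble (possibly empty).
#' @export
align_read <- function(read, feature, max_mismatch = 1) {
  align_reads(tibble::as_tibble(read[c("read_id", "seq")]) %>%
                dplyr::mutate(length = nchar(.data$seq)),
              tibble::as_tibble(feature[c("name", "seq")]),
              max_mismatch = max_mismatch)
}

#' Index alignment 5' ends per feature and orientation
#'
#' Aggregates alignment weight by the plus-strand position of each read's
#' biological 5' end: `start` for sense reads, `start + length - 1` for
#' antisense reads. This index is the input of the overlap histogram.
#'
#' @param alignments alignment tibble from [align_reads()].
#' @return tibble with `feature`, `orientation`, `pos5`, `weight`.
#' @export
five_prime_index <- function(alignments) {
  alignments %>%
    dplyr::mutate(pos5 = ifelse(.data$orientation == "sense",
                                .data$start,
                                .data$start + .data$length - 1L)) %>%
    dplyr::group_by(.data$feature, .data$orientation, .data$pos5) %>%
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
}
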