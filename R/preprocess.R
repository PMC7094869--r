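#' Clip 3' adapter sequences from reads
#'
#' Truncates each read at the leftmost position where at least `min_match`
#' bases of the adapter prefix match exactly. Reads whose clipped insert is
#' shorter than `min_insert`, and (by default) reads with no adapter
#' occurrence, are discarded.
#'
#' @param reads tibble of reads ([read_fastq()] shape).
#' @param adapter 3' adapter base string (length >= `min_match`).
#' @param min_insert minimum insert length kept after clipping (default 18).
#' @param min_match exact-match adapter prefix length required (default 8,
#'   must be >= 6).
#' @param keep_unclipped keep reads without an adapter occurrence unmodified
#'   instead of discarding them (default `FALSE`).
#' @return tibble of retained reads; attribute `clip_stats` holds a named
#'   integer vector (`input`, `clipped`, `unclipped_kept`,
#'   `discarded_no_adapter`, `discarded_short`).
#' @export
clip_adapter <- function(reads, adapter, min_insert = 18, min_match = 8,
                         keep_unclipped = FALSE) {
  if (min_match < 6) abort("`min_match` must be >= 6")
  adapter <- normalize_bases(adapter)
  if (nchar(adapter) < min_match) abort("adapter shorter than `min_match`")
  probe <- substr(adapter, 1, min_match)
  hit <- stringr::str_locate(reads$seq, stringr::fixed(probe))[, "start"]

  clipped_seq <- substr(reads$seq, 1, ifelse(is.na(hit), nchar(reads$seq), hit - 1))
  found <- !is.na(hit)
  short <- found & nchar(clipped_seq) < min_insert
  keep <- (found & !short) | (!found & keep_unclipped)

  out <- reads[keep, , drop = FALSE]
  out$seq <- clipped_seq[keep]
  out$length <- nchar(out$seq)
  if ("qual" %in% names(out)) out$qual <- substr(out$qual, 1, out$length)
  attr(out, "clip_stats") <- c(
    input = nrow(reads),
    clipped = sum(found & !short),
    unclipped_kept = sum(!found & keep_unclipped),
    discarded_no_adapter = sum(!found & !keep_unclipped),
    discarded_short = sum(short))
  out
}

#' Deplete reads matching rRNA or miRNA hairpin references
#'
#' A read is depleted iff it aligns end-to-end (either strand) to any
#' depletion reference with at most `max_mismatch` substitutions. The count
#' of reads depleted to miRNA hairpins is the between-library normaliser.
#' rRNA references take priority when a read matches both classes.
#'
#' @param reads tibble of reads.
#' @param depletion_refs tibble with `name`, `seq`, `feature_class` limited
#'   to classes `rRNA` and `miRNA_hairpin`.
#' @param max_mismatch 0 or 1 (default 1).
#' @return list with `retained` (tibble), `depleted` (tibble `class`, `n`),
#'   `hairpin_total`, `rrna_total`.
#' @export
deplete_matching <- function(reads, depletion_refs, max_mismatch = 1) {
  if (!max_mismatch %in% c(0, 1)) abort("`max_mismatch` must be 0 or 1")
  depletion_refs <- depletion_refs %>%
    dplyr::filter(.data$feature_class %in% c("rRNA", "miRNA_hairpin")) %>%
    dplyr::arrange(dplyr::desc(.data$feature_class == "rRNA"))
  if (nrow(depletion_refs) == 0) {
    warn("empty depletion reference set: all reads retained, hairpin normaliser is 0")
    return(list(retained = reads,
                depleted = tibble::tibble(class = character(), n = integer()),
                hairpin_total = 0L, rrna_total = 0L))
  }
  hit <- .deplete_scan_cpp(reads$seq, depletion_refs$seq, as.integer(max_mismatch))
  cls <- ifelse(hit > 0, depletion_refs$feature_class[pmax(hit, 1)], NA_character_)
  retained <- reads[hit == 0, , drop = FALSE]
  depl <- tibble::tibble(class = cls[hit > 0]) %>% dplyr::count(.data$class)
  list(retained = retained,
       depleted = depl,
       hairpin_total = sum(cls == "miRNA_hairpin", na.rm = TRUE),
       rrna_total = sum(cls == "rRNA", na.rm = TRUE))
}

#' Classify reads by length
#'
#' piRNAs are reads of 23-29 nt, siRNAs 20-22 nt; everything else is
#' `other`. The classification is total: every read receives exactly one
#' label.
#'
#' @param reads tibble of reads.
#' @return the input with a `read_class` column.
#' @export
classify_by_length <- function(reads) {
  reads %>% dplyr::mutate(read_class = dplyr::case_when(
    .data$length >= 23 & .data$length <= 29 ~ "piRNA",
    .data$length >= 20 & .data$length <= 22 ~ "siRNA",
    TRUE ~ "other"))
}

#' 5' nucleotide identity profile
#'
#' Per read length (18-35 nt), the fraction of reads whose first (5'-most)
#' base is A, C, G or U. Lengths with zero reads are reported with zero
#' fractions and `n_reads = 0`.
#'
#' @param reads tibble of reads.
#' @return tibble with `length`, `base` (A/C/G/U), `fraction`, `n_reads`.
#' @export
five_prime_profile <- function(reads) {
  if (nrow(reads) == 0) abort("`reads` must be non-empty")
  grid <- tidyr::expand_grid(length = 18:35, base = c("A", "C", "G", "U"))
  obs <- reads %>%
    dplyr::filter(.data$length >= 18, .data$length <= 35) %>%
    dplyr::mutate(base = as_rna_base(substr(.data$seq, 1, 1))) %>%
    dplyr::count(.data$length, .data$base, name = "k")
  totals <- obs %>% dplyr::group_by(.data$length) %>%
    dplyr::summarise(n_reads = sum(.data$k), .groups = "drop")
  grid %>%
    dplyr::left_join(obs, by = c("length", "base")) %>%
    dplyr::left_join(totals, by = "length") %>%
    dplyr::mutate(k = tidyr::replace_na(.data$k, 0L),
                  n_reads = tidyr::replace_na(.data$n_reads, 0L),
                  fraction = ifelse(.data$n_reads > 0, .data$k / .data$n_reads, 0)) %>%
    dplyr::select("length", "base", "fraction", "n_reads")
}

#' Plot a 5' nucleotide identity profile
#'
#' Stacked per-length barplot of 5' base fractions, the standard diagnostic
#' for the piRNA 1U bias.
#'
#' @param profile output of [five_prime_profile()].
#' @return a ggplot object.
#' @export
plot_five_prime_profile <- function(profile) {
  profile %>%
    dplyr::filter(.data$n_reads > 0) %>%
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$length), y = .data$fraction,
                                 fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "read length (nt)", y = "fraction of reads",
                  fill = "5' base") +
    ggplot2::theme_minimal()
}
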