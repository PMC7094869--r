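#' Weighted per-feature, per-orientation counts
#'
#' Sums alignment weight per feature and orientation, and carries the two
#' normalisers every report needs: the miRNA-hairpin read total (depleted
#' hairpin matches, the between-library normaliser) and the total library
#' reads entering depletion.
#'
#' @param alignments alignment tibble from [align_reads()].
#' @param hairpin_total integer, reads depleted to miRNA hairpins.
#' @param library_total integer, all reads in the library after clipping.
#' @return tibble with `feature`, `sense_weight`, `antisense_weight` plus
#'   per-million hairpin-normalised columns; attributes `hairpin_total`,
#'   `library_total`.
#' @export
count_by_feature <- function(alignments, hairpin_total = NA_integer_,
                             library_total = NA_integer_) {
  out <- alignments %>%
    dplyr::group_by(.data$feature) %>%
    dplyr::summarise(
      sense_weight = sum(.data$weight[.data$orientation == "sense"]),
      antisense_weight = sum(.data$weight[.data$orientation == "antisense"]),
      .groups = "drop")
  if (!is.na(hairpin_total) && hairpin_total > 0) {
    out <- out %>% dplyr::mutate(
      norm_hairpin_sense = normalize_hairpin(.data$sense_weight, hairpin_total),
      norm_hairpin_antisense = normalize_hairpin(.data$antisense_weight, hairpin_total))
  }
  attr(out, "hairpin_total") <- hairpin_total
  attr(out, "library_total") <- library_total
  out
}

#' Normalise a count to miRNA-hairpin reads per million
#'
#' @param count weighted read count (>= 0).
#' @param hairpin_total miRNA-hairpin read total (> 0).
#' @return `count / hairpin_total * 1e6`.
#' @export
normalize_hairpin <- function(count, hairpin_total) {
  if (any(is.na(hairpin_total)) || any(hairpin_total <= 0)) {
    abort("`hairpin_total` must be > 0: library is unnormalizable")
  }
  count / hairpin_total * 1e6
}

#' Per-class fraction of total library reads
#'
#' Sums aligned weight per feature class and divides by the total library
#' reads. Depleted read counts (miRNA hairpin, rRNA) may be supplied so the
#' depleted classes appear in the summary alongside the aligned ones.
#'
#' @param counts output of [count_by_feature()].
#' @param annotation tibble `name`, `class` (or [load_annotation()] output).
#' @param library_total total reads in the library; defaults to the
#'   attribute carried by `counts`.
#' @param depleted optional named vector of depleted read counts, e.g.
#'   `c(miRNA_hairpin = 1000, rRNA = 50)`.
#' @return tibble with `class`, `weight`, `fraction`.
#' @export
class_summary <- function(counts, annotation, library_total = NULL,
                          depleted = NULL) {
  if (is.null(library_total)) library_total <- attr(counts, "library_total")
  if (is.null(library_total) || is.na(library_total)) {
    abort("`library_total` is required")
  }
  missing <- setdiff(counts$feature, annotation$name)
  if (length(missing)) {
    abort(sprintf("unannotated feature(s): %s", paste(missing, collapse = ", ")))
  }
  out <- counts %>%
    dplyr::left_join(annotation, by = c(feature = "name")) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(weight = sum(.data$sense_weight + .data$antisense_weight),
                     .groups = "drop")
  if (!is.null(depleted) && length(depleted)) {
    out <- dplyr::bind_rows(out,
                            tibble::tibble(class = names(depleted),
                                           weight = as.numeric(depleted))) %>%
      dplyr::group_by(.data$class) %>%
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  }
  out %>% dplyr::mutate(fraction = .data$weight / library_total)
}

#' Per-nucleotide read density across a feature
#'
#' Every alignment adds its weight to each covered position of its
#' orientation's track (`mode = "coverage"`, default) or to its 5'-end
#' position only (`mode = "five_prime"`). Tracks are normalised to
#' miRNA-hairpin reads per million when `hairpin_total` is given.
#'
#' @param alignments alignment tibble.
#' @param feature feature name.
#' @param feature_length length of the feature in nt.
#' @param hairpin_total optional hairpin normaliser (> 0).
#' @param mode `"coverage"` or `"five_prime"`.
#' @return tibble with `position` (0-based), `sense`, `antisense`.
#' @export
density_profile <- function(alignments, feature, feature_length,
                            hairpin_total = NULL,
                            mode = c("coverage", "five_prime")) {
  mode <- match.arg(mode)
  aln <- alignments %>% dplyr::filter(.data$feature == .env$feature)
  sense <- numeric(feature_length)
  anti <- numeric(feature_length)
  for (i in seq_len(nrow(aln))) {
    if (mode == "coverage") {
      span <- (aln$start[i] + 1L):(aln$start[i] + aln$length[i])
    } else {
      span <- if (aln$orientation[i] == "sense") aln$start[i] + 1L
              else aln$start[i] + aln$length[i]
    }
    if (aln$orientation[i] == "sense") {
      sense[span] <- sense[span] + aln$weight[i]
    } else {
      anti[span] <- anti[span] + aln$weight[i]
    }
  }
  if (!is.null(hairpin_total)) {
    sense <- normalize_hairpin(sense, hairpin_total)
    anti <- normalize_hairpin(anti, hairpin_total)
  }
  tibble::tibble(position = seq_len(feature_length) - 1L,
                 sense = sense, antisense = anti)
}

#' Plot a per-feature read density profile
#'
#' Sense coverage is drawn upward (blue), antisense downward (red), the
#' conventional rendering of piRNA density across a transposon.
#'
#' @param profile output of [density_profile()].
#' @param feature optional feature name for the title.
#' @return a ggplot object.
#' @export
plot_density_profile <- function(profile, feature = NULL) {
  df <- profile %>%
    tidyr::pivot_longer(c("sense", "antisense"),
                        names_to = "orientation", values_to = "density") %>%
    dplyr::mutate(density = ifelse(.data$orientation == "antisense",
                                   -.data$density, .data$density))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$density,
                                   fill = .data$orientation)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(sense = "#3366cc", antisense = "#cc3333")) +
    ggplot2::labs(x = "position (nt)", y = "normalised density",
                  title = feature) +
    ggplot2::theme_minimal()
}
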