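#' Replicate-aware differential abundance between two conditions
#'
#' Takes a long table of per-feature, per-replicate normalised abundances
#' for two conditions and produces, per feature: mean abundances, the
#' pseudocounted log2 fold change of condition B over A, a p-value (Student's
#' t on log2(abundance + pseudocount) across replicates by default, or a
#' rank-sum test), the Benjamini-Hochberg q-value, and an up/down/unchanged
#' call at the fold and FDR cutoffs.
#'
#' @param data tibble with columns `feature`, `condition` (two levels; the
#'   first sorted level is the baseline A), `replicate`, `abundance`
#'   (hairpin-normalised, >= 0).
#' @param fold_cut minimum fold change called (default 1.5).
#' @param fdr_cut FDR threshold (default 0.1).
#' @param pseudocount added before log2 (default 1).
#' @param test `"t"` (equal-variance Student's t, default) or `"wilcoxon"`
#'   (Mann-Whitney rank-sum across replicates).
#' @param var_equal pool variances in the t-test (default `TRUE`).
#' @return A `pp_differential` object; `tidy()` returns the per-feature
#'   table, `glance()` a one-row summary including the global Wilcoxon
#'   signed-rank p over per-feature log2 fold changes.
#' @export
differential_abundance <- function(data, fold_cut = 1.5, fdr_cut = 0.1,
                                   pseudocount = 1.0,
                                   test = c("t", "wilcoxon"),
                                   var_equal = TRUE) {
  test <- match.arg(test)
  conds <- sort(unique(data$condition))
  if (length(conds) != 2) abort("`data` must contain exactly two conditions")
  if (any(data$abundance < 0)) abort("abundances must be >= 0")

  per_feature <- data %>%
    dplyr::mutate(logab = log2(.data$abundance + pseudocount)) %>%
    dplyr::group_by(.data$feature) %>%
    dplyr::summarise(
      mean_abundance_a = mean(.data$abundance[.data$condition == conds[1]]),
      mean_abundance_b = mean(.data$abundance[.data$condition == conds[2]]),
      p = {
        xa <- .data$logab[.data$condition == conds[1]]
        xb <- .data$logab[.data$condition == conds[2]]
        if (length(xa) < 2 || length(xb) < 2) NA_real_
        else if (test == "t") students_t(xa, xb, var_equal = var_equal)
        else stats::wilcox.test(xa, xb, exact = FALSE)$p.value
      },
      .groups = "drop") %>%
    dplyr::mutate(
      log2fc = log2_fold_change(.data$mean_abundance_a, .data$mean_abundance_b,
                                pseudocount = pseudocount),
      q = bh_adjust(.data$p))
  per_feature <- call_differential(per_feature, fold_cut = fold_cut, fdr_cut = fdr_cut)

  global_p <- if (nrow(per_feature) >= 5) {
    wilcoxon_signed_rank(per_feature$log2fc)
  } else NA_real_

  structure(list(result = per_feature,
                 conditions = conds,
                 fold_cut = fold_cut, fdr_cut = fdr_cut,
                 pseudocount = pseudocount, test = test,
                 global_wilcoxon_p = global_p),
            class = "pp_differential")
}

#' Call features up, down or unchanged
#'
#' Applies the fold and FDR cutoffs: `up` iff `2^log2fc > fold_cut` and
#' `q < fdr_cut`; `down` symmetrically; otherwise `unchanged`.
#'
#' @param records tibble with `log2fc` and `q`.
#' @param fold_cut minimum fold change (default 1.5).
#' @param fdr_cut FDR threshold (default 0.1).
#' @return `records` with a `call` column.
#' @export
call_differential <- function(records, fold_cut = 1.5, fdr_cut = 0.1) {
  records %>% dplyr::mutate(call = dplyr::case_when(
    2^.data$log2fc > fold_cut & .data$q < fdr_cut & !is.na(.data$q) ~ "up",
    2^(-.data$log2fc) > fold_cut & .data$q < fdr_cut & !is.na(.data$q) ~ "down",
    TRUE ~ "unchanged"))
}

#' Per-class differential test of library-fraction summaries
#'
#' Student's t-test per feature class on per-replicate fractions of total
#' library reads, the class-level companion to the per-feature analysis.
#'
#' @param data tibble with `class`, `condition` (two levels), `replicate`,
#'   `fraction`.
#' @param var_equal pool variances (default `TRUE`).
#' @return tibble with `class`, `mean_fraction_a`, `mean_fraction_b`,
#'   `log2fc`, `p`.
#' @export
class_differential <- function(data, var_equal = TRUE) {
  conds <- sort(unique(data$condition))
  if (length(conds) != 2) abort("`data` must contain exactly two conditions")
  data %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(
      mean_fraction_a = mean(.data$fraction[.data$condition == conds[1]]),
      mean_fraction_b = mean(.data$fraction[.data$condition == conds[2]]),
      p = students_t(.data$fraction[.data$condition == conds[1]],
                     .data$fraction[.data$condition == conds[2]],
                     var_equal = var_equal),
      .groups = "drop") %>%
    dplyr::mutate(log2fc = log2(.data$mean_fraction_b / .data$mean_fraction_a))
}

#' @export
print.pp_differential <- function(x, ...) {
  cat(sprintf("<pp_differential> %s vs %s: %d features, %d up, %d down (fold > %.2g, FDR < %.2g)\n",
              x$conditions[2], x$conditions[1], nrow(x$result),
              sum(x$result$call == "up"), sum(x$result$call == "down"),
              x$fold_cut, x$fdr_cut))
  print(x$result)
  invisible(x)
}

#' @describeIn differential_abundance per-feature differential table.
#' @param x a `pp_differential` object.
#' @param ... unused.
#' @method tidy pp_differential
#' @export
tidy.pp_differential <- function(x, ...) x$result

#' @describeIn differential_abundance one-row summary: feature and call
#'   counts, median log2 fold change, global signed-rank p.
#' @method glance pp_differential
#' @export
glance.pp_differential <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$result),
    n_up = sum(x$result$call == "up"),
    n_down = sum(x$result$call == "down"),
    median_log2fc = median(x$result$log2fc),
    global_wilcoxon_p = x$global_wilcoxon_p)
}

#' @describeIn differential_abundance MA-style plot: mean abundance vs log2
#'   fold change, coloured by call.
#' @param object a `pp_differential` object.
#' @method autoplot pp_differential
#' @export
autoplot.pp_differential <- function(object, ...) {
  df <- object$result %>%
    dplyr::mutate(mean_ab = (.data$mean_abundance_a + .data$mean_abundance_b) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_ab, y = .data$log2fc,
                                   colour = .data$call)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(up = "#cc3333", down = "#3366cc",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "mean normalised abundance", y = "log2 fold change") +
    ggplot2::theme_minimal()
}
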