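#' 5'-5' overlap histogram between sense and antisense reads
#'
#' For every (sense 5' at `s`, antisense 5' at `a`) position pair on a
#' feature, the overlap is `o = a - s + 1`; each pair adds the product of
#' the indexed weights to bin `o`. An exact ping-pong duplex has `o = 10`.
#'
#' @param index 5'-end index from [five_prime_index()], built from
#'   piRNA-class reads only.
#' @param o_max largest overlap reported (default 30; must be >= 10 so the
#'   signature bin exists).
#' @return tibble with `feature`, `overlap` (1..`o_max`), `weight`.
#' @export
overlap_histogram <- function(index, o_max = 30) {
  if (o_max < 10) abort("`o_max` must be >= 10 (the ping-pong signature bin)")
  feats <- unique(index$feature)
  purrr::map_dfr(feats, function(f) {
    sub <- index[index$feature == f, ]
    s <- sub[sub$orientation == "sense", ]
    a <- sub[sub$orientation == "antisense", ]
    w <- numeric(o_max)
    if (nrow(s) && nrow(a)) {
      for (o in seq_len(o_max)) {
        m <- match(a$pos5 - o + 1L, s$pos5)
        ok <- !is.na(m)
        if (any(ok)) w[o] <- sum(a$weight[ok] * s$weight[m[ok]])
      }
    }
    tibble::tibble(feature = f, overlap = seq_len(o_max), weight = w)
  })
}

# Which rows (one per read-placement, with pos5/base10/base1/weight)
# participate in at least one qualifying ping-pong pair? A (sense,
# antisense) pair qualifies iff their 5' ends overlap by exactly 10 AND
# (the sense read's 10th base is A OR the antisense read's 1st base is U).
# Sense-role reads shorter than 10 nt are excluded (warning counter).
pp_qualify <- function(df) {
  out <- logical(nrow(df))
  short <- df$orientation == "sense" & nchar(df$base10) == 0
  n_short <- sum(short)
  if (n_short > 0) {
    warn(sprintf("%d sense-role read(s) shorter than 10 nt excluded from pairing", n_short))
  }
  for (f in unique(df$feature)) {
    sel <- which(df$feature == f)
    sub <- df[sel, ]
    s_ok <- sub$orientation == "sense" & nchar(sub$base10) > 0
    a_ok <- sub$orientation == "antisense"
    sense_pos <- unique(sub$pos5[s_ok])
    senseA <- unique(sub$pos5[s_ok & sub$base10 == "A"])
    anti_pos <- unique(sub$pos5[a_ok])
    antiU <- unique(sub$pos5[a_ok & sub$base1 == "T"])
    q <- logical(nrow(sub))
    q[s_ok] <- (sub$base10[s_ok] == "A" & (sub$pos5[s_ok] + 9L) %in% anti_pos) |
      ((sub$pos5[s_ok] + 9L) %in% antiU)
    q[a_ok] <- (sub$base1[a_ok] == "T" & (sub$pos5[a_ok] - 9L) %in% sense_pos) |
      ((sub$pos5[a_ok] - 9L) %in% senseA)
    out[sel] <- q
  }
  out
}

#' Ping-pong ratio from qualifying and total weights
#'
#' @param qualifying_weight weighted count of piRNA reads in at least one
#'   qualifying pair.
#' @param total_piRNA_weight all piRNA weight on the feature.
#' @return `qualifying_weight / total_piRNA_weight`, 0 when the total is 0.
#' @export
pingpong_ratio <- function(qualifying_weight, total_piRNA_weight) {
  ifelse(total_piRNA_weight > 0, qualifying_weight / total_piRNA_weight, 0)
}

#' Ping-pong signature analysis of an aligned library
#'
#' Computes, per feature, the 5'-5' overlap histogram, the weighted count of
#' piRNA reads participating in at least one qualifying pair (exact 10-nt
#' 5' overlap AND sense 10A or antisense 1U -- the 10A/1U signature judged
#' on the read's own sequence), and the ping-pong ratio
#' qualifying / total piRNA weight. The ratio is invariant under uniform
#' library scaling, so no library-size normalisation is needed.
#'
#' @param alignments alignment tibble from [align_reads()].
#' @param reads the read tibble the alignments came from (for base checks).
#' @param o_max histogram range (default 30).
#' @param numerator `"reads"` (default; each qualifying read counted once)
#'   or `"pairs"` (sum of weight products over qualifying pairs).
#' @param scope denominator scope: `"feature"` (default; total piRNA weight
#'   on that feature, as ratios are reported per transposon) or
#'   `"library"` (total piRNA weight over all features).
#' @param piRNA_only restrict to reads of 23-29 nt before pairing
#'   (default `TRUE`).
#' @return A `pp_pingpong` object: list with `histogram`, `ratios`
#'   (`feature`, `qualifying_weight`, `total_weight`, `ratio`), `o_max`,
#'   `numerator`, `scope`.
#' @export
pingpong_stats <- function(alignments, reads, o_max = 30,
                           numerator = c("reads", "pairs"),
                           scope = c("feature", "library"),
                           piRNA_only = TRUE) {
  numerator <- match.arg(numerator)
  scope <- match.arg(scope)
  aln <- alignments
  if (piRNA_only) aln <- aln %>% dplyr::filter(.data$length >= 23, .data$length <= 29)
  df <- aln %>%
    dplyr::left_join(reads %>% dplyr::select("read_id", "seq"), by = "read_id") %>%
    dplyr::mutate(pos5 = ifelse(.data$orientation == "sense",
                                .data$start, .data$start + .data$length - 1L),
                  base10 = substr(.data$seq, 10, 10),
                  base1 = substr(.data$seq, 1, 1))

  idx <- five_prime_index(aln)
  hist <- overlap_histogram(idx, o_max = o_max)

  totals <- df %>%
    dplyr::group_by(.data$feature) %>%
    dplyr::summarise(total_weight = sum(.data$weight), .groups = "drop")

  if (numerator == "reads") {
    df$qualifies <- pp_qualify(df)
    qual <- df %>%
      dplyr::group_by(.data$feature, .data$read_id) %>%
      dplyr::summarise(w = sum(.data$weight), q = any(.data$qualifies),
                       .groups = "drop") %>%
      dplyr::group_by(.data$feature) %>%
      dplyr::summarise(qualifying_weight = sum(.data$w[.data$q]), .groups = "drop")
  } else {
    qual <- purrr::map_dfr(unique(df$feature), function(f) {
      sub <- df[df$feature == f, ]
      s <- sub[sub$orientation == "sense" & nchar(sub$base10) > 0, ]
      a <- sub[sub$orientation == "antisense", ]
      w <- 0
      if (nrow(s) && nrow(a)) {
        for (i in seq_len(nrow(s))) {
          hit <- a$pos5 == s$pos5[i] + 9L & (s$base10[i] == "A" | a$base1 == "T")
          w <- w + s$weight[i] * sum(a$weight[hit])
        }
      }
      tibble::tibble(feature = f, qualifying_weight = w)
    })
  }

  ratios <- totals %>%
    dplyr::left_join(qual, by = "feature") %>%
    dplyr::mutate(qualifying_weight = tidyr::replace_na(.data$qualifying_weight, 0))
  denom <- if (scope == "library") sum(ratios$total_weight) else ratios$total_weight
  ratios <- ratios %>%
    dplyr::mutate(ratio = pingpong_ratio(.data$qualifying_weight, denom)) %>%
    dplyr::select("feature", "qualifying_weight", "total_weight", "ratio")

  structure(list(histogram = hist, ratios = ratios, o_max = o_max,
                 numerator = numerator, scope = scope),
            class = "pp_pingpong")
}

#' @export
print.pp_pingpong <- function(x, ...) {
  cat(sprintf("<pp_pingpong> %d feature(s), o_max = %d, numerator = %s, scope = %s\n",
              nrow(x$ratios), x$o_max, x$numerator, x$scope))
  print(x$ratios)
  invisible(x)
}

#' @describeIn pingpong_stats per-feature ratio table.
#' @param x a `pp_pingpong` object.
#' @param ... unused.
#' @method tidy pp_pingpong
#' @export
tidy.pp_pingpong <- function(x, ...) x$ratios

#' @describeIn pingpong_stats one-row summary (features, total and
#'   qualifying weight, weighted mean ratio, bin-10 histogram share).
#' @method glance pp_pingpong
#' @export
glance.pp_pingpong <- function(x, ...) {
  h <- x$histogram %>% dplyr::group_by(.data$overlap) %>%
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  tibble::tibble(
    n_features = nrow(x$ratios),
    total_weight = sum(x$ratios$total_weight),
    qualifying_weight = sum(x$ratios$qualifying_weight),
    mean_ratio = ifelse(sum(x$ratios$total_weight) > 0,
                        sum(x$ratios$qualifying_weight) / sum(x$ratios$total_weight), 0),
    bin10_share = ifelse(sum(h$weight) > 0,
                         h$weight[h$overlap == 10] / sum(h$weight), NA_real_))
}

#' @describeIn pingpong_stats overlap histogram bar chart (bin 10
#'   highlighted), summed over features or faceted by feature.
#' @param object a `pp_pingpong` object.
#' @param by_feature facet per feature instead of pooling (default `FALSE`).
#' @method autoplot pp_pingpong
#' @export
autoplot.pp_pingpong <- function(object, by_feature = FALSE, ...) {
  h <- object$histogram
  if (!by_feature) {
    h <- h %>% dplyr::group_by(.data$overlap) %>%
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  }
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$overlap, y = .data$weight,
                                       fill = .data$overlap == 10)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#cc3333")) +
    ggplot2::labs(x = "5'-5' overlap (nt)", y = "paired weight") +
    ggplot2::theme_minimal()
  if (by_feature) p <- p + ggplot2::facet_wrap(~feature, scales = "free_y")
  p
}

#' Compare per-transposon ping-pong ratios between two conditions
#'
#' Takes per-replicate, per-feature ratio tables for two conditions,
#' averages ratios over replicates within each condition, and tests the
#' paired per-feature differences with the Wilcoxon signed-rank test.
#'
#' @param cond_a,cond_b tibbles with `feature`, `replicate`, `ratio`.
#' @return list (class `pp_ratio_comparison`) with `per_replicate` (both
#'   conditions stacked), `per_feature` (means and differences), `p`
#'   (two-sided signed-rank p; `NA` when fewer than 5 shared features) and
#'   `n_shared`.
#' @export
compare_ratios <- function(cond_a, cond_b) {
  per_rep <- dplyr::bind_rows(
    cond_a %>% dplyr::mutate(condition = "A"),
    cond_b %>% dplyr::mutate(condition = "B"))
  mean_a <- cond_a %>% dplyr::group_by(.data$feature) %>%
    dplyr::summarise(mean_a = mean(.data$ratio), .groups = "drop")
  mean_b <- cond_b %>% dplyr::group_by(.data$feature) %>%
    dplyr::summarise(mean_b = mean(.data$ratio), .groups = "drop")
  per_feature <- dplyr::inner_join(mean_a, mean_b, by = "feature") %>%
    dplyr::mutate(diff = .data$mean_b - .data$mean_a)
  n_shared <- nrow(per_feature)
  p <- if (n_shared < 5) NA_real_ else wilcoxon_signed_rank(per_feature$diff)
  structure(list(per_replicate = per_rep, per_feature = per_feature,
                 p = p, n_shared = n_shared),
            class = "pp_ratio_comparison")
}

#' @export
print.pp_ratio_comparison <- function(x, ...) {
  cat(sprintf("<pp_ratio_comparison> %d shared feature(s); Wilcoxon signed-rank p = %s\n",
              x$n_shared, format(x$p, digits = 4)))
  print(x$per_feature)
  invisible(x)
}

#' @describeIn compare_ratios per-replicate ratio box plots by condition.
#' @param object a `pp_ratio_comparison` object.
#' @param ... unused.
#' @method autoplot pp_ratio_comparison
#' @export
autoplot.pp_ratio_comparison <- function(object, ...) {
  ggplot2::ggplot(object$per_replicate,
                  ggplot2::aes(x = factor(.data$replicate), y = .data$ratio,
                               fill = .data$condition)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~condition, scales = "free_x") +
    ggplot2::labs(x = "replicate", y = "ping-pong ratio") +
    ggplot2::theme_minimal()
}
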