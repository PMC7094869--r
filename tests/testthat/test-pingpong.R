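# build a 5'-index tibble directly
mk_idx <- function(feature, orientation, pos5, weight = 1) {
  tibble::tibble(feature = feature, orientation = orientation,
                 pos5 = as.integer(pos5), weight = weight)
}

test_that("overlap bins follow the a - s + 1 definition", {
  idx <- mk_idx("te1", c("sense", "antisense"), c(0, 9))
  h <- overlap_histogram(idx)
  expect_equal(h$weight[h$overlap == 10], 1)
  expect_equal(sum(h$weight), 1)

  idx2 <- mk_idx("te1", c("sense", "antisense"), c(0, 8))
  h2 <- overlap_histogram(idx2)
  expect_equal(h2$weight[h2$overlap == 9], 1)
  expect_error(overlap_histogram(idx, o_max = 9), "o_max")
})

test_that("histogram is bilinear in the indexed weights", {
  set.seed(5)
  idx <- mk_idx("te1",
                sample(c("sense", "antisense"), 60, TRUE),
                sample(0:200, 60, TRUE), runif(60))
  h1 <- overlap_histogram(idx)
  idx2 <- dplyr::mutate(idx, weight = ifelse(orientation == "sense",
                                             2 * weight, weight))
  h2 <- overlap_histogram(idx2)
  expect_equal(h2$weight, 2 * h1$weight)
})

test_that("the qualifying-pair OR rule is applied literally", {
  base_read <- function(id, seq) tibble::tibble(read_id = id, seq = seq,
                                                length = nchar(seq))
  te <- paste(rep("C", 200), collapse = "")
  mk <- function(sense_seq, anti_seq, anti_pos5 = 9L) {
    aln <- tibble::tibble(
      read_id = c("s1", "a1"), feature = "te1",
      start = c(0L, anti_pos5 - nchar(anti_seq) + 1L),
      orientation = c("sense", "antisense"), mismatches = 0L,
      length = c(nchar(sense_seq), nchar(anti_seq)), weight = 1)
    reads <- dplyr::bind_rows(base_read("s1", sense_seq), base_read("a1", anti_seq))
    tidy(pingpong_stats(aln, reads, piRNA_only = FALSE))
  }
  s_10A <- paste0(strrep("C", 9), "A", strrep("C", 14)) # 24 nt, A at 10
  s_10C <- strrep("C", 24)
  a_1U <- paste0("T", strrep("G", 22))
  a_1G <- strrep("G", 23)

  expect_equal(mk(s_10A, a_1G)$qualifying_weight, 2)   # 10A alone suffices
  expect_equal(mk(s_10C, a_1U)$qualifying_weight, 2)   # 1U alone suffices
  expect_equal(mk(s_10C, a_1G)$qualifying_weight, 0)   # neither holds
  expect_equal(mk(s_10A, a_1G, anti_pos5 = 8L)$qualifying_weight, 0) # overlap 9
})

test_that("histogram and qualifying weights match the all-pairs double loop", {
  refs <- tiny_refs(seed = 61)
  for (seed in c(3, 4)) {
    p <- library_params(n_reads = 700, seed = seed,
                        position_model = if (seed %% 2) "sites" else "uniform")
    lib <- simulate_library(p, refs)
    res <- process_library(lib$reads, refs)
    pir <- dplyr::filter(classify_by_length(lib$reads), read_class == "piRNA")
    df <- res$alignments %>%
      dplyr::filter(length >= 23, length <= 29) %>%
      dplyr::left_join(dplyr::select(pir, read_id, seq), by = "read_id") %>%
      dplyr::mutate(pos5 = ifelse(orientation == "sense", start,
                                  start + length - 1L))
    want_h <- oracle_overlap_histogram(df)
    got_h <- res$pingpong$histogram
    merged <- merge(got_h, want_h, by = c("feature", "overlap"), all = TRUE)
    merged$weight.y[is.na(merged$weight.y)] <- 0
    expect_equal(merged$weight.x, merged$weight.y, tolerance = 1e-12)

    want_q <- oracle_qualifying_weight(df)
    got_q <- tidy(res$pingpong)
    m2 <- merge(got_q, want_q, by = "feature")
    expect_equal(m2$qualifying_weight.x, m2$qualifying_weight.y, tolerance = 1e-12)
  }
})

test_that("the ping-pong ratio is bounded arithmetic with zero guards", {
  expect_equal(pingpong_ratio(4, 20), 0.2)
  expect_equal(pingpong_ratio(0, 50), 0)
  expect_equal(pingpong_ratio(0, 0), 0)
  expect_equal(pingpong_ratio(c(1, 0), c(2, 0)), c(0.5, 0))
})

test_that("duplicating every read leaves per-feature ratios unchanged", {
  refs <- tiny_refs(seed = 71)
  p <- library_params(n_reads = 1500, seed = 5)
  lib <- simulate_library(p, refs)
  res1 <- process_library(lib$reads, refs)
  doubled <- dplyr::bind_rows(lib$reads,
                              dplyr::mutate(lib$reads, read_id = paste0(read_id, "_dup")))
  res2 <- process_library(doubled, refs)
  r1 <- tidy(res1$pingpong)
  r2 <- tidy(res2$pingpong)
  m <- merge(r1, r2, by = "feature")
  expect_equal(m$total_weight.y, 2 * m$total_weight.x)
  expect_equal(m$ratio.y, m$ratio.x, tolerance = 1e-12)
})

test_that("compare_ratios handles identity, shifts and small feature sets", {
  a <- tidyr::crossing(feature = paste0("te", 1:10), replicate = 1:2) %>%
    dplyr::mutate(ratio = 0.2 + 0.01 * as.integer(factor(feature)))
  cmp_same <- compare_ratios(a, a)
  expect_equal(cmp_same$p, 1)

  b <- dplyr::mutate(a, ratio = ratio + 0.1)
  cmp_shift <- compare_ratios(a, b)
  expect_equal(cmp_shift$n_shared, 10)
  # all ten per-feature differences positive: two-sided exact p = 2/1024
  expect_equal(cmp_shift$p, 2 / 1024)
  expect_equal(wilcoxon_signed_rank(cmp_shift$per_feature$diff, "greater"),
               1 / 1024)

  small <- dplyr::filter(a, feature %in% paste0("te", 1:4))
  expect_true(is.na(compare_ratios(small, small)$p))
})

test_that("tidy/glance/autoplot expose the ping-pong fit", {
  refs <- tiny_refs(seed = 81)
  lib <- simulate_library(library_params(n_reads = 800, seed = 2), refs)
  res <- process_library(lib$reads, refs)
  td <- tidy(res$pingpong)
  expect_true(all(td$ratio >= 0 & td$ratio <= 1))
  gl <- glance(res$pingpong)
  expect_equal(gl$n_features, nrow(td))
  expect_s3_class(autoplot(res$pingpong), "ggplot")
})
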