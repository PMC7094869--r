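adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("clip_adapter truncates at the adapter prefix and enforces min_insert", {
  insert <- paste(rep("A", 21), collapse = "")
  reads <- tibble::tibble(read_id = "r1", seq = paste0(insert, adapter),
                          length = nchar(paste0(insert, adapter)),
                          qual = strrep("I", 21 + nchar(adapter)))
  out <- clip_adapter(reads, adapter)
  expect_equal(out$seq, insert)
  expect_equal(out$length, 21L)
  expect_equal(nchar(out$qual), 21L)

  # no adapter occurrence: discarded by default, kept under the policy flag
  naked <- tibble::tibble(read_id = "r2", seq = strrep("C", 25), length = 25L,
                          qual = strrep("I", 25))
  expect_equal(nrow(clip_adapter(naked, adapter)), 0)
  expect_equal(attr(clip_adapter(naked, adapter), "clip_stats")[["discarded_no_adapter"]], 1)
  expect_equal(clip_adapter(naked, adapter, keep_unclipped = TRUE)$seq, naked$seq)

  # short insert discarded
  shorty <- tibble::tibble(read_id = "r3", seq = paste0("ACGTACGTAC", adapter),
                           length = 10L + nchar(adapter),
                           qual = strrep("I", 10 + nchar(adapter)))
  expect_equal(nrow(clip_adapter(shorty, adapter, min_insert = 18)), 0)

  expect_error(clip_adapter(reads, "ACGTAC", min_match = 8), "min_match")
  expect_error(clip_adapter(reads, adapter, min_match = 4), "min_match")
})

test_that("clipped lengths equal the generator insert lengths", {
  refs <- tiny_refs(seed = 6)
  p <- library_params(n_reads = 500, adapter = adapter, seed = 9)
  lib <- simulate_library(p, refs)
  out <- clip_adapter(lib$reads, adapter)
  expect_equal(nrow(out), 500)
  truth_len <- lib$truth$reads$length[match(out$read_id, lib$truth$reads$read_id)]
  expect_equal(out$length, truth_len)
})

test_that("depletion matches the brute-force all-offsets scan", {
  set.seed(21)
  refs <- tiny_refs(seed = 21)
  depl_refs <- dplyr::filter(refs, feature_class %in% c("rRNA", "miRNA_hairpin"))

  # planted hairpin substring, its 1- and 2-mismatch variants, random reads
  hp <- depl_refs$seq[depl_refs$feature_class == "miRNA_hairpin"][1]
  exact <- substr(hp, 5, 28)
  one_mm <- exact; substr(one_mm, 3, 3) <- if (substr(one_mm, 3, 3) == "A") "C" else "A"
  two_mm <- one_mm; substr(two_mm, 9, 9) <- if (substr(two_mm, 9, 9) == "G") "T" else "G"
  reads <- dplyr::bind_rows(
    tibble::tibble(read_id = c("exact", "one_mm", "two_mm"),
                   seq = c(exact, one_mm, two_mm),
                   length = nchar(c(exact, one_mm, two_mm)),
                   qual = strrep("I", nchar(c(exact, one_mm, two_mm)))),
    random_reads(60, prefix = "bg"))

  res <- deplete_matching(reads, depl_refs, max_mismatch = 1)
  kept <- res$retained$read_id
  expect_false("exact" %in% kept)
  expect_false("one_mm" %in% kept)
  expect_true("two_mm" %in% kept)
  expect_gte(res$hairpin_total, 2)

  oracle_kept <- reads$read_id[!vapply(reads$seq, oracle_deplete_hit,
                                       logical(1), refs = depl_refs)]
  expect_setequal(kept, oracle_kept)
  # partition invariant
  expect_equal(nrow(res$retained) + res$hairpin_total + res$rrna_total, nrow(reads))
})

test_that("an empty depletion set warns and retains everything", {
  reads <- random_reads(5)
  empty <- tibble::tibble(name = character(), seq = character(),
                          feature_class = character())
  expect_warning(res <- deplete_matching(reads, empty), "hairpin normaliser")
  expect_equal(nrow(res$retained), 5)
  expect_equal(res$hairpin_total, 0L)
})

test_that("length classification is total with the documented boundaries", {
  reads <- tibble::tibble(read_id = paste0("r", 1:6),
                          seq = strrep("A", c(19, 20, 22, 23, 29, 30)),
                          length = c(19L, 20L, 22L, 23L, 29L, 30L))
  out <- classify_by_length(reads)
  expect_equal(out$read_class, c("other", "siRNA", "siRNA", "piRNA", "piRNA", "other"))
})

test_that("five_prime_profile rows are proper distributions", {
  reads <- tibble::tibble(read_id = paste0("r", 1:10),
                          seq = strrep("T", 24), length = 24L)
  prof <- five_prime_profile(reads)
  expect_equal(prof$fraction[prof$length == 24 & prof$base == "U"], 1)
  sums <- prof %>% dplyr::filter(n_reads > 0) %>%
    dplyr::group_by(length) %>% dplyr::summarise(s = sum(fraction))
  expect_true(all(abs(sums$s - 1) < 1e-9))

  set.seed(1)
  unif <- random_reads(10000, len_range = 24)
  pu <- five_prime_profile(unif)
  fr <- pu$fraction[pu$length == 24]
  expect_true(all(abs(fr - 0.25) < 4 * sqrt(0.25 * 0.75 / 10000)))
})

test_that("the simulated 1U bias is recovered in the 5' profile", {
  refs <- tiny_refs(seed = 14, n_te = 4, te_length = 800)
  p <- library_params(n_reads = 20000, u1_bias = 0.8, sense_fraction = 0,
                      pingpong_fraction = 0, seed = 17)
  lib <- simulate_library(p, refs)
  depl <- deplete_matching(lib$reads,
                           dplyr::filter(refs, feature_class %in% c("rRNA", "miRNA_hairpin")))
  prof <- five_prime_profile(classify_by_length(depl$retained))
  ufrac <- prof %>%
    dplyr::filter(length %in% 23:29, base == "U") %>%
    dplyr::summarise(u = sum(fraction * n_reads) / sum(n_reads)) %>%
    dplyr::pull(u)
  expect_gt(ufrac, 0.77)
  expect_lt(ufrac, 0.83)
})
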