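test_that("exact sense and antisense placements follow the coordinate rules", {
  refs <- tiny_refs(seed = 31)
  te <- refs[refs$feature_class == "transposon", ][1, ]

  sense_read <- tibble::tibble(read_id = "s", seq = substr(te$seq, 41, 64),
                               length = 24L)
  aln <- align_reads(sense_read, te, max_mismatch = 1)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 40)
  expect_equal(aln$orientation, "sense")
  expect_equal(aln$mismatches, 0)

  anti_read <- tibble::tibble(
    read_id = "a", seq = oracle_revcomp(substr(te$seq, 11, 35)), length = 25L)
  aln2 <- align_reads(anti_read, te, max_mismatch = 1)
  expect_equal(aln2$start, 10)
  expect_equal(aln2$orientation, "antisense")
  idx <- five_prime_index(aln2)
  expect_equal(idx$pos5, 34)
})

test_that("hit sets equal the exhaustive offset-by-strand scan", {
  set.seed(42)
  refs <- generate_reference_set(n_te = 1, te_length = 2000, n_hairpins = 1,
                                 seed = 42, n_clusters = 0, n_genes = 0)
  te <- refs[refs$feature_class == "transposon", ]
  # planted exact, planted 1-mismatch, planted antisense, and random reads
  planted <- substr(te$seq, 101, 124)
  mut <- planted; substr(mut, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                                 substr(mut, 12, 12))[1]
  seqs <- c(planted, mut, oracle_revcomp(substr(te$seq, 501, 524)),
            replicate(30, paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")))
  reads <- tibble::tibble(read_id = paste0("r", seq_along(seqs)), seq = seqs,
                          length = nchar(seqs))
  aln <- align_reads(reads, te, max_mismatch = 1)
  for (i in seq_len(nrow(reads))) {
    got <- aln[aln$read_id == reads$read_id[i],
               c("feature", "start", "orientation", "mismatches")]
    got <- got[order(got$start, got$orientation), ]
    want <- oracle_align(reads$seq[i], te, max_mm = 1)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want$start, want$orientation), ]
      expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
    }
  }
})

test_that("multi-mapper policies split or drop weight as configured", {
  refs <- tiny_refs(seed = 8)
  te <- refs[refs$feature_class == "transposon", ][1, ]
  two <- dplyr::bind_rows(te, dplyr::mutate(te, name = "TE_copy"))
  read <- tibble::tibble(read_id = "m", seq = substr(te$seq, 21, 44), length = 24L)

  frac <- align_reads(read, two, policy = "fractional")
  expect_equal(nrow(frac), 2)
  expect_equal(frac$weight, c(0.5, 0.5))
  expect_equal(sum(frac$weight), 1)

  uniq <- align_reads(read, two, policy = "unique_only")
  expect_equal(nrow(uniq), 0)
  expect_equal(attr(uniq, "align_stats")[["multimap_dropped"]], 1)
})

test_that("weights are conserved and policies agree on uniquely-placed data", {
  refs <- tiny_refs(seed = 19)
  p <- library_params(n_reads = 1500, seed = 23)
  lib <- simulate_library(p, refs)
  targets <- dplyr::filter(refs, feature_class %in%
                             c("transposon", "piRNA_cluster", "gene"))
  pir <- dplyr::filter(classify_by_length(lib$reads), read_class == "piRNA")
  frac <- align_reads(pir, targets, policy = "fractional")
  stats <- attr(frac, "align_stats")
  expect_equal(sum(frac$weight), stats[["aligned"]])
  uniq <- align_reads(pir, targets, policy = "unique_only")
  if (stats[["multimap_dropped"]] == 0) {
    expect_equal(dplyr::arrange(frac, read_id, feature, start),
                 dplyr::arrange(uniq, read_id, feature, start))
  }
})

test_that("strand involution: reverse-complemented reads flip orientation", {
  refs <- tiny_refs(seed = 27)
  te <- refs[refs$feature_class == "transposon", ][1, ]
  set.seed(3)
  reads <- random_reads(10, len_range = 24)
  reads$seq[1] <- substr(te$seq, 61, 84) # guarantee at least one hit
  fwd <- align_reads(reads, te)
  rev <- align_reads(dplyr::mutate(reads, seq = vapply(seq, oracle_revcomp,
                                                       character(1))), te)
  fwd_key <- fwd[order(fwd$read_id, fwd$start), c("read_id", "start", "mismatches")]
  rev_key <- rev[order(rev$read_id, rev$start), c("read_id", "start", "mismatches")]
  expect_equal(as.data.frame(fwd_key), as.data.frame(rev_key), ignore_attr = TRUE)
  merged <- merge(as.data.frame(fwd), as.data.frame(rev),
                  by = c("read_id", "start"))
  expect_true(all(merged$orientation.x != merged$orientation.y))
})

test_that("the scan agrees with Biostrings pattern matching on exact hits", {
  refs <- tiny_refs(seed = 33)
  te <- refs[refs$feature_class == "transposon", ][1, ]
  reads <- tibble::tibble(read_id = c("x", "y"),
                          seq = c(substr(te$seq, 201, 226),
                                  oracle_revcomp(substr(te$seq, 301, 326))),
                          length = 26L)
  aln <- align_reads(reads, te, max_mismatch = 0)
  subject <- Biostrings::DNAString(te$seq)
  for (i in 1:2) {
    fwd <- Biostrings::matchPattern(reads$seq[i], subject)
    rev <- Biostrings::matchPattern(oracle_revcomp(reads$seq[i]), subject)
    starts0 <- sort(c(BiocGenerics::start(fwd), BiocGenerics::start(rev)) - 1L)
    expect_equal(sort(aln$start[aln$read_id == reads$read_id[i]]), starts0)
  }
})
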