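test_that("reference sets are deterministic given the seed and validated", {
  a <- generate_reference_set(n_te = 2, te_length = 500, n_hairpins = 3, seed = 7)
  b <- generate_reference_set(n_te = 2, te_length = 500, n_hairpins = 3, seed = 7)
  expect_identical(a, b)
  expect_error(generate_reference_set(n_te = 0), "n_te")
  expect_error(generate_reference_set(n_te = 1, te_length = 50), "te_length")
  expect_true(any(a$feature_class == "rRNA"))
})

test_that("reference base composition is near-uniform", {
  refs <- generate_reference_set(n_te = 1, te_length = 10000, n_hairpins = 1,
                                 seed = 3, n_clusters = 0, n_genes = 0)
  bases <- table(strsplit(refs$seq[refs$feature_class == "transposon"], "")[[1]])
  # binomial 99.99% bound on each base fraction around 1/4
  tol <- 4 * sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(bases / 10000 - 0.25) < tol))
})

test_that("start-site pools forbid accidental exact-10 offsets", {
  refs <- tiny_refs(seed = 9)
  for (s in refs$sites[refs$feature_class == "transposon"]) {
    expect_length(intersect(s$anti, s$sense + 9), 0)
    expect_length(intersect(s$anti, s$duplex_s + 9), 0)
    expect_length(intersect(s$sense + 9, s$duplex_s + 9), 0)
    expect_length(intersect(s$anti - 9, s$duplex_s), 0)
  }
})

test_that("simulate_library conserves read counts and is seed-deterministic", {
  refs <- tiny_refs(seed = 2)
  p <- library_params(n_reads = 2000, seed = 5)
  lib <- simulate_library(p, refs)
  expect_equal(nrow(lib$reads), 2000)
  expect_equal(sum(lib$truth$classes$reads), 2000)
  lib2 <- simulate_library(p, refs)
  expect_identical(lib$reads, lib2$reads)
  # truth reads are exact substrings except forced/error bases: all lengths agree
  expect_equal(lib$truth$reads$length, nchar(lib$truth$reads$seq))
})

test_that("pingpong_fraction drives emitted pair structure", {
  refs <- tiny_refs(seed = 4)
  p0 <- library_params(n_reads = 3000, pingpong_fraction = 0, seed = 8)
  lib0 <- simulate_library(p0, refs)
  expect_equal(sum(lib0$truth$features$emitted_pairs), 0)

  p1 <- library_params(n_reads = 3000, pingpong_fraction = 1, a10_bias = 1,
                       cluster_fraction = 0, seed = 8)
  lib1 <- simulate_library(p1, refs)
  n_te_reads <- lib1$truth$classes$reads[lib1$truth$classes$class == "te_piRNA"]
  expect_equal(sum(lib1$truth$features$emitted_pairs), n_te_reads %/% 2)
  # with a10 forced every designed pair qualifies, so every paired read does
  te_feats <- lib1$truth$features[grepl("^TE", lib1$truth$features$feature), ]
  expect_true(all(te_feats$qualifying_reads >= 2 * te_feats$emitted_pairs))
})

test_that("emitted ping-pong pairs sit at a 10 nt 5' offset with the signature", {
  refs <- tiny_refs(seed = 12)
  p <- library_params(n_reads = 2000, pingpong_fraction = 1, a10_bias = 1,
                      u1_bias = 1, cluster_fraction = 0, seed = 3)
  tr <- simulate_library(p, refs)$truth$reads
  pairs <- tr[!is.na(tr$pair_id), ]
  by_pair <- split(pairs, pairs$pair_id)
  for (pr in by_pair[1:20]) {
    s <- pr[pr$orientation == "sense", ]
    a <- pr[pr$orientation == "antisense", ]
    expect_equal(a$pos5 - s$pos5, 9)
    expect_equal(substr(s$seq, 10, 10), "A")
    expect_equal(substr(a$seq, 1, 1), "T")
  }
})

test_that("optional adapter is appended to every read", {
  refs <- tiny_refs(seed = 2)
  p <- library_params(n_reads = 200, adapter = "TGGAATTCTCGGGTGCCAAGG", seed = 1)
  lib <- simulate_library(p, refs)
  expect_true(all(grepl("TGGAATTCTCGGGTGCCAAGG$", lib$reads$seq)))
})

test_that("condition pairs scale the transposon stream and hold hairpins fixed", {
  p <- library_params(n_reads = 10000, seed = 2)
  des <- simulate_condition_pair(p, fold_by_class = c(transposon = 3),
                                 n_replicates = 3)
  expect_error(simulate_condition_pair(p, n_replicates = 1), "n_replicates")
  expect_error(simulate_condition_pair(p, fold_by_class = c(transposon = -1)),
               "fold")
  # expected hairpin reads identical in absolute number
  e_mi_a <- des$params_a$n_reads * des$params_a$class_mix[["miRNA_hairpin"]]
  e_mi_b <- des$params_b$n_reads * des$params_b$class_mix[["miRNA_hairpin"]]
  expect_equal(e_mi_a, e_mi_b, tolerance = 1e-4)
  # expected TE stream scaled threefold
  te_a <- des$params_a$n_reads * des$params_a$class_mix[["te_piRNA"]] *
    (1 - des$params_a$cluster_fraction)
  te_b <- des$params_b$n_reads * des$params_b$class_mix[["te_piRNA"]] *
    (1 - des$params_b$cluster_fraction)
  expect_equal(te_b / te_a, 3, tolerance = 1e-3)
  expect_equal(des$seeds_a, 2 + 1:3)
  expect_equal(des$seeds_b, 2 + 3 + 1:3)
})

test_that("library_params validates probability inputs", {
  expect_error(library_params(class_mix = c(te_piRNA = 0.5, siRNA = 0.5,
                                            miRNA_hairpin = 0.2, rRNA = 0.1)),
               "sum to 1")
  expect_error(library_params(pingpong_fraction = 1.2), "pingpong_fraction")
  expect_error(library_params(n_reads = -5), "n_reads")
})
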