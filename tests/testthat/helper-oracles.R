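# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (double loops, literal enumeration) so they share no
# code path with the implementation they check.

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# exhaustive offset x strand scan for end-to-end placements with <= max_mm
# substitutions; best-stratum filtered
oracle_align <- function(read_seq, refs, max_mm = 1) {
  hits <- list()
  rc <- oracle_revcomp(read_seq)
  L <- nchar(read_seq)
  for (j in seq_len(nrow(refs))) {
    ref <- refs$seq[j]
    for (s in 0:(nchar(ref) - L)) {
      win <- substr(ref, s + 1, s + L)
      for (orient in c("sense", "antisense")) {
        q <- if (orient == "sense") read_seq else rc
        mm <- sum(strsplit(win, "")[[1]] != strsplit(q, "")[[1]])
        if (mm <= max_mm) {
          hits[[length(hits) + 1]] <- data.frame(
            feature = refs$name[j], start = s, orientation = orient,
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  out <- do.call(rbind, hits)
  out[out$mismatches == min(out$mismatches), ]
}

oracle_deplete_hit <- function(read_seq, refs, max_mm = 1) {
  !is.null(oracle_align(read_seq, refs, max_mm = max_mm))
}

# all-pairs double loop over per-read 5' ends: overlap histogram
oracle_overlap_histogram <- function(df, o_max = 30) {
  sense <- df[df$orientation == "sense", ]
  anti <- df[df$orientation == "antisense", ]
  out <- list()
  for (f in unique(df$feature)) {
    w <- numeric(o_max)
    s <- sense[sense$feature == f, ]
    a <- anti[anti$feature == f, ]
    if (nrow(s) && nrow(a)) {
      for (i in seq_len(nrow(s))) for (k in seq_len(nrow(a))) {
        o <- a$pos5[k] - s$pos5[i] + 1
        if (o >= 1 && o <= o_max) w[o] <- w[o] + s$weight[i] * a$weight[k]
      }
    }
    out[[f]] <- data.frame(feature = f, overlap = seq_len(o_max), weight = w)
  }
  do.call(rbind, unname(out))
}

# all-pairs double loop: weight of reads in >= 1 qualifying pair, per feature
oracle_qualifying_weight <- function(df) {
  res <- list()
  for (f in unique(df$feature)) {
    sub <- df[df$feature == f, ]
    sense <- sub[sub$orientation == "sense" & nchar(sub$seq) >= 10, ]
    anti <- sub[sub$orientation == "antisense", ]
    inpair <- character()
    if (nrow(sense) && nrow(anti)) {
      for (i in seq_len(nrow(sense))) for (k in seq_len(nrow(anti))) {
        overlap <- anti$pos5[k] - sense$pos5[i] + 1
        if (overlap == 10 &&
            (substr(sense$seq[i], 10, 10) == "A" || substr(anti$seq[k], 1, 1) == "T")) {
          inpair <- union(inpair, c(sense$read_id[i], anti$read_id[k]))
        }
      }
    }
    per_read <- aggregate(weight ~ read_id, data = sub, FUN = sum)
    res[[f]] <- data.frame(
      feature = f,
      qualifying_weight = sum(per_read$weight[per_read$read_id %in% inpair]))
  }
  do.call(rbind, unname(res))
}

# literal 2^n sign enumeration for the signed-rank test (zeros dropped,
# mid-ranks); feasible for n <= 14
oracle_signed_rank_p <- function(diffs, alternative = "two.sided") {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_ge, p_le)),
         greater = p_ge,
         less = p_le)
}

# random read tibble over the DNA alphabet
random_reads <- function(n, len_range = 20:29, prefix = "r") {
  lens <- sample(len_range, n, replace = TRUE)
  tibble::tibble(
    read_id = paste0(prefix, seq_len(n)),
    seq = vapply(lens, function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                         collapse = ""), character(1)),
    length = lens,
    qual = strrep("I", lens))
}

# small reference set for fast tests
tiny_refs <- function(seed = 1, n_te = 3, te_length = 500, n_hairpins = 3,
                      ...) {
  generate_reference_set(n_te = n_te, te_length = te_length,
                         n_hairpins = n_hairpins, seed = seed,
                         n_clusters = 1, cluster_length = 600,
                         n_genes = 1, gene_length = 400,
                         n_rrna = 1, rrna_length = 400,
                         hairpin_length = 60, ...)
}
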