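#' Parameters for a simulated small RNA library
#'
#' Bundles the knobs of the read generator. The generator emits a mixture of
#' transposon/cluster-derived piRNAs (23-29 nt), endo-siRNAs (20-22 nt),
#' miRNA-hairpin fragments and rRNA fragments. A controllable fraction of
#' transposon piRNAs is emitted as exact 10-nt 5'-overlap (ping-pong) pairs
#' carrying the 10A/1U signature.
#'
#' @param n_reads number of reads to emit (exactly).
#' @param class_mix named probabilities over `te_piRNA`, `siRNA`,
#'   `miRNA_hairpin`, `rRNA`; must sum to 1.
#' @param pingpong_fraction probability that a transposon piRNA read is
#'   emitted as a member of an exact 10-nt 5'-overlap pair.
#' @param u1_bias probability that an antisense (primary) piRNA's first base
#'   is U; otherwise the first base is drawn uniformly from A/C/G.
#' @param a10_bias probability that the sense member of a ping-pong pair has
#'   A at read position 10; otherwise drawn uniformly from C/G/U.
#' @param sense_fraction probability an unpaired transposon piRNA is sense.
#' @param cluster_fraction share of the piRNA stream drawn from
#'   piRNA-cluster features instead of transposons.
#' @param length_dist list with elements `piRNA` (probabilities over
#'   23-29 nt) and `siRNA` (over 20-22 nt).
#' @param position_model `"sites"` (default) draws 5' ends from the discrete
#'   per-feature start-site pools attached to the reference set, emulating
#'   the reproducible 5' ends of real piRNAs; `"uniform"` places 5' ends
#'   uniformly over all valid offsets.
#' @param error_rate per-base uniform substitution probability (default 0).
#' @param adapter optional 3' adapter sequence appended to every read.
#' @param seed integer RNG seed.
#' @return A `library_params` list.
#' @export
library_params <- function(n_reads = 20000,
                           class_mix = c(te_piRNA = 0.35, siRNA = 0.15,
                                         miRNA_hairpin = 0.40, rRNA = 0.10),
                           pingpong_fraction = 0.4,
                           u1_bias = 0.8,
                           a10_bias = 0.7,
                           sense_fraction = 0.3,
                           cluster_fraction = 0.3,
                           length_dist = list(
                             piRNA = c(`23` = 0.08, `24` = 0.16, `25` = 0.24,
                                       `26` = 0.22, `27` = 0.16, `28` = 0.09,
                                       `29` = 0.05),
                             siRNA = c(`20` = 0.25, `21` = 0.50, `22` = 0.25)),
                           position_model = c("sites", "uniform"),
                           error_rate = 0,
                           adapter = NULL,
                           seed = 1L) {
  if (!is.numeric(n_reads) || n_reads < 0) abort("`n_reads` must be >= 0")
  if (is.null(names(class_mix)) ||
      !setequal(names(class_mix), c("te_piRNA", "siRNA", "miRNA_hairpin", "rRNA"))) {
    abort("`class_mix` must be named over te_piRNA, siRNA, miRNA_hairpin, rRNA")
  }
  stopifnot_prob(class_mix, "class_mix")
  if (abs(sum(class_mix) - 1) > 1e-9) abort("`class_mix` must sum to 1")
  for (nm in c("pingpong_fraction", "u1_bias", "a10_bias", "sense_fraction",
               "cluster_fraction", "error_rate")) {
    stopifnot_prob(get(nm), nm)
  }
  if (abs(sum(length_dist$piRNA) - 1) > 1e-9 || abs(sum(length_dist$siRNA) - 1) > 1e-9) {
    abort("`length_dist` components must each sum to 1")
  }
  structure(list(
    n_reads = as.integer(n_reads),
    class_mix = class_mix[c("te_piRNA", "siRNA", "miRNA_hairpin", "rRNA")],
    pingpong_fraction = pingpong_fraction,
    u1_bias = u1_bias,
    a10_bias = a10_bias,
    sense_fraction = sense_fraction,
    cluster_fraction = cluster_fraction,
    length_dist = length_dist,
    position_model = match.arg(position_model),
    error_rate = error_rate,
    adapter = if (is.null(adapter)) NULL else normalize_bases(adapter),
    seed = as.integer(seed)
  ), class = "library_params")
}

max_sim_read_len <- 29L

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Disjoint 5'-start-site pools for one feature of length L:
#   duplex_s : sense 5' positions of ping-pong duplex hotspots (antisense
#              partner 5' end is duplex_s + 9); deliberately few per
#              feature, so that at realistic depth every hotspot carries
#              several pairs and the qualification probability of a read at
#              a hotspot is saturated (depth-invariant)
#   sense    : background sense 5' positions, no antisense site at +9
#   anti     : background antisense 5' positions, no sense site at -9
# so background reads can never form an exact overlap-10 pair.
make_sites <- function(L, n_duplex, n_bg) {
  duplex_range <- 19:(L - max_sim_read_len)
  duplex_s <- resample(duplex_range, min(n_duplex, length(duplex_range)))
  anti_cand <- setdiff(28:(L - 1), c(duplex_s + 9, duplex_s, duplex_s - 9))
  anti <- resample(anti_cand, min(n_bg, length(anti_cand)))
  sense_cand <- setdiff(0:(L - max_sim_read_len), c(duplex_s, anti - 9, anti, duplex_s + 18))
  sense <- resample(sense_cand, min(n_bg, length(sense_cand)))
  list(duplex_s = sort(duplex_s), sense = sort(sense), anti = sort(anti))
}

#' Generate a synthetic reference set
#'
#' Produces uniform-random reference sequences for every feature class the
#' pipeline knows: transposon consensus sequences, piRNA clusters, genes,
#' miRNA hairpins and an rRNA decoy. Transposons and clusters carry discrete
#' piRNA 5'-start-site pools (list-column `sites`) used by the `"sites"`
#' placement model of [simulate_library()].
#'
#' @param n_te number of transposon features (>= 1).
#' @param te_length transposon length in nt (>= 100).
#' @param n_hairpins number of miRNA hairpin features.
#' @param seed integer RNG seed; the set is deterministic given the seed.
#' @param n_clusters,cluster_length piRNA-cluster features.
#' @param n_genes,gene_length gene features (siRNA targets).
#' @param n_rrna,rrna_length rRNA decoy features (>= 1 decoy always kept).
#' @param hairpin_length miRNA hairpin length in nt.
#' @param sites_per_kb background 5'-site density per strand per kb.
#' @param duplex_sites ping-pong duplex hotspots per transposon (a small
#'   fixed number, emulating the dominant ping-pong loci of real
#'   transposons).
#' @return tibble with `name`, `seq`, `feature_class` and `sites`.
#' @export
generate_reference_set <- function(n_te = 8, te_length = 1500, n_hairpins = 10,
                                   seed = 1L,
                                   n_clusters = 3, cluster_length = 3000,
                                   n_genes = 3, gene_length = 1500,
                                   n_rrna = 1, rrna_length = 1500,
                                   hairpin_length = 70,
                                   sites_per_kb = 30, duplex_sites = 12) {
  if (n_te < 1) abort("`n_te` must be >= 1")
  if (te_length < 100) abort("`te_length` must be >= 100")
  if (te_length < max_sim_read_len + 10) {
    abort("`te_length` must exceed the longest simulated read plus 10 nt")
  }
  if (n_rrna < 1) abort("`n_rrna` must be >= 1 (the depletion decoy)")
  set.seed(seed)

  build <- function(prefix, n, len, class) {
    if (n == 0) return(NULL)
    tibble::tibble(
      name = sprintf("%s_%02d", prefix, seq_len(n)),
      seq = vapply(seq_len(n), function(i) rand_seq(len), character(1)),
      feature_class = class
    )
  }
  refs <- dplyr::bind_rows(
    build("TE", n_te, te_length, "transposon"),
    build("CLUSTER", n_clusters, cluster_length, "piRNA_cluster"),
    build("GENE", n_genes, gene_length, "gene"),
    build("HAIRPIN", n_hairpins, hairpin_length, "miRNA_hairpin"),
    build("RRNA", n_rrna, rrna_length, "rRNA")
  )
  refs$sites <- purrr::map2(refs$seq, refs$feature_class, function(s, cls) {
    L <- nchar(s)
    if (cls == "transposon") {
      make_sites(L, n_duplex = duplex_sites,
                 n_bg = max(4, round(sites_per_kb * L / 1000)))
    } else if (cls == "piRNA_cluster") {
      list(duplex_s = integer(),
           sense = sort(resample(0:(L - max_sim_read_len),
                                 max(4, round(sites_per_kb * L / 1000)))),
           anti = integer())
    } else {
      NULL
    }
  })
  refs
}

draw_lengths <- function(n, dist) {
  if (n == 0) return(integer())
  lens <- as.integer(names(dist))
  lens[sample.int(length(lens), n, replace = TRUE, prob = as.numeric(dist))]
}

# force position `pos` of each read to `hit` with probability p_hit, else to
# a base drawn uniformly from the remaining three
force_base <- function(seqs, pos, hit, p_hit) {
  n <- length(seqs)
  if (n == 0) return(seqs)
  others <- setdiff(c("A", "C", "G", "T"), hit)
  new <- ifelse(runif(n) < p_hit, hit, sample(others, n, replace = TRUE))
  substr(seqs, pos, pos) <- new
  seqs
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(b)) < rate
    if (any(hit)) {
      b[hit] <- vapply(b[hit], function(x) resample(setdiff(c("A", "C", "G", "T"), x), 1),
                       character(1))
    }
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate one small RNA library with ground truth
#'
#' Emits exactly `n_reads` reads drawn from the class mixture in `params`,
#' placed on the reference set, together with a ground-truth record of every
#' emission. Ping-pong pairs are emitted as one sense read with 5' end `s`
#' and one antisense read whose 5' end sits at plus-strand position `s + 9`;
#' reads are exact (reverse-complemented) substrings of the reference except
#' for the forced signature bases (sense position 10 -> A with probability
#' `a10_bias`; antisense position 1 -> U with probability `u1_bias`) and
#' optional uniform sequencing errors.
#'
#' @param params a [library_params()] object.
#' @param refs reference set from [generate_reference_set()] (or any tibble
#'   with `name`, `seq`, `feature_class`, optionally `sites`).
#' @return A `pp_library` list: `reads` (FASTQ-ready tibble), `truth` (list
#'   of tibbles `reads`, `features`, `classes`), `params`.
#' @export
simulate_library <- function(params, refs) {
  stopifnot(inherits(params, "library_params"))
  te <- refs %>% dplyr::filter(.data$feature_class == "transposon")
  hp <- refs %>% dplyr::filter(.data$feature_class == "miRNA_hairpin")
  cl <- refs %>% dplyr::filter(.data$feature_class == "piRNA_cluster")
  gn <- refs %>% dplyr::filter(.data$feature_class == "gene")
  rr <- refs %>% dplyr::filter(.data$feature_class == "rRNA")
  if (nrow(te) == 0) abort("reference set has no transposon feature")
  if (nrow(hp) == 0) abort("reference set has no miRNA_hairpin feature")

  set.seed(params$seed)
  n <- params$n_reads
  mix <- params$class_mix
  counts <- drop(rmultinom(1, n, mix))
  names(counts) <- names(mix)

  n_cluster <- if (nrow(cl)) rbinom(1, counts[["te_piRNA"]], params$cluster_fraction) else 0L
  n_te_reads <- counts[["te_piRNA"]] - n_cluster
  n_paired <- rbinom(1, n_te_reads, params$pingpong_fraction)
  n_pairs <- n_paired %/% 2L
  n_te_single <- n_te_reads - 2L * n_pairs

  use_sites <- params$position_model == "sites"
  pi_dist <- params$length_dist$piRNA
  si_dist <- params$length_dist$siRNA

  rows <- list()

  ## ping-pong pairs on transposons -------------------------------------
  if (n_pairs > 0) {
    fidx <- sample.int(nrow(te), n_pairs, replace = TRUE)
    s <- integer(n_pairs)
    for (j in unique(fidx)) {
      sel <- which(fidx == j)
      if (use_sites) {
        pool <- te$sites[[j]]$duplex_s
        s[sel] <- resample(pool, length(sel), replace = TRUE)
      } else {
        L <- nchar(te$seq[j])
        s[sel] <- resample(19:(L - max_sim_read_len), length(sel), replace = TRUE)
      }
    }
    ls <- draw_lengths(n_pairs, pi_dist)
    la <- draw_lengths(n_pairs, pi_dist)
    ref_seq <- te$seq[fidx]
    sense_seq <- substr(ref_seq, s + 1L, s + ls)
    sense_seq <- force_base(sense_seq, 10L, "A", params$a10_bias)
    p <- s + 9L
    anti_sub <- substr(ref_seq, p - la + 2L, p + 1L)
    anti_seq <- force_base(revcomp(anti_sub), 1L, "T", params$u1_bias)
    rows$pair_sense <- tibble::tibble(
      feature = te$name[fidx], class = "te_piRNA", orientation = "sense",
      start = s, length = ls, pos5 = s, seq = sense_seq,
      pair_id = seq_len(n_pairs))
    rows$pair_anti <- tibble::tibble(
      feature = te$name[fidx], class = "te_piRNA", orientation = "antisense",
      start = p - la + 1L, length = la, pos5 = p, seq = anti_seq,
      pair_id = seq_len(n_pairs))
  }

  ## unpaired transposon piRNAs -----------------------------------------
  if (n_te_single > 0) {
    fidx <- sample.int(nrow(te), n_te_single, replace = TRUE)
    is_sense <- runif(n_te_single) < params$sense_fraction
    len <- draw_lengths(n_te_single, pi_dist)
    pos5 <- integer(n_te_single)
    for (j in unique(fidx)) {
      for (sns in c(TRUE, FALSE)) {
        sel <- which(fidx == j & is_sense == sns)
        if (!length(sel)) next
        L <- nchar(te$seq[j])
        if (use_sites) {
          pool <- if (sns) te$sites[[j]]$sense else te$sites[[j]]$anti
          pos5[sel] <- resample(pool, length(sel), replace = TRUE)
        } else {
          pos5[sel] <- if (sns) {
            resample(0:(L - max_sim_read_len), length(sel), replace = TRUE)
          } else {
            resample((max_sim_read_len - 1L):(L - 1L), length(sel), replace = TRUE)
          }
        }
      }
    }
    ref_seq <- te$seq[fidx]
    start <- ifelse(is_sense, pos5, pos5 - len + 1L)
    seq <- ifelse(is_sense,
                  substr(ref_seq, pos5 + 1L, pos5 + len),
                  revcomp(substr(ref_seq, pos5 - len + 2L, pos5 + 1L)))
    seq[!is_sense] <- force_base(seq[!is_sense], 1L, "T", params$u1_bias)
    rows$te_single <- tibble::tibble(
      feature = te$name[fidx], class = "te_piRNA",
      orientation = ifelse(is_sense, "sense", "antisense"),
      start = as.integer(start), length = len, pos5 = pos5, seq = seq,
      pair_id = NA_integer_)
  }

  ## piRNA-cluster primary piRNAs ---------------------------------------
  if (n_cluster > 0) {
    fidx <- sample.int(nrow(cl), n_cluster, replace = TRUE)
    len <- draw_lengths(n_cluster, pi_dist)
    pos5 <- integer(n_cluster)
    for (j in unique(fidx)) {
      sel <- which(fidx == j)
      L <- nchar(cl$seq[j])
      if (use_sites) {
        pos5[sel] <- resample(cl$sites[[j]]$sense, length(sel), replace = TRUE)
      } else {
        pos5[sel] <- resample(0:(L - max_sim_read_len), length(sel), replace = TRUE)
      }
    }
    seq <- substr(cl$seq[fidx], pos5 + 1L, pos5 + len)
    seq <- force_base(seq, 1L, "T", params$u1_bias)
    rows$cluster <- tibble::tibble(
      feature = cl$name[fidx], class = "cluster_piRNA", orientation = "sense",
      start = pos5, length = len, pos5 = pos5, seq = seq,
      pair_id = NA_integer_)
  }

  ## endo-siRNAs on genes (fall back to transposons) ---------------------
  n_si <- counts[["siRNA"]]
  if (n_si > 0) {
    tgt <- if (nrow(gn)) gn else te
    fidx <- sample.int(nrow(tgt), n_si, replace = TRUE)
    len <- draw_lengths(n_si, si_dist)
    is_sense <- runif(n_si) < 0.5
    L <- nchar(tgt$seq[fidx])
    start <- as.integer(floor(runif(n_si) * (L - len + 1L)))
    seq <- substr(tgt$seq[fidx], start + 1L, start + len)
    seq[!is_sense] <- revcomp(seq[!is_sense])
    rows$sirna <- tibble::tibble(
      feature = tgt$name[fidx], class = "siRNA",
      orientation = ifelse(is_sense, "sense", "antisense"),
      start = start, length = len,
      pos5 = as.integer(ifelse(is_sense, start, start + len - 1L)), seq = seq,
      pair_id = NA_integer_)
  }

  ## miRNA hairpin fragments ---------------------------------------------
  n_mi <- counts[["miRNA_hairpin"]]
  if (n_mi > 0) {
    fidx <- sample.int(nrow(hp), n_mi, replace = TRUE)
    len <- resample(20:23, n_mi, replace = TRUE)
    L <- nchar(hp$seq[fidx])
    start <- as.integer(floor(runif(n_mi) * (L - len + 1L)))
    rows$hairpin <- tibble::tibble(
      feature = hp$name[fidx], class = "miRNA_hairpin", orientation = "sense",
      start = start, length = len, pos5 = start,
      seq = substr(hp$seq[fidx], start + 1L, start + len),
      pair_id = NA_integer_)
  }

  ## rRNA fragments -------------------------------------------------------
  n_rr <- counts[["rRNA"]]
  if (n_rr > 0) {
    fidx <- sample.int(nrow(rr), n_rr, replace = TRUE)
    len <- resample(18:30, n_rr, replace = TRUE)
    L <- nchar(rr$seq[fidx])
    start <- as.integer(floor(runif(n_rr) * (L - len + 1L)))
    rows$rrna <- tibble::tibble(
      feature = rr$name[fidx], class = "rRNA", orientation = "sense",
      start = start, length = len, pos5 = start,
      seq = substr(rr$seq[fidx], start + 1L, start + len),
      pair_id = NA_integer_)
  }

  truth_reads <- dplyr::bind_rows(rows)
  if (nrow(truth_reads)) {
    truth_reads$seq <- apply_errors(truth_reads$seq, params$error_rate)
    truth_reads <- truth_reads[sample.int(nrow(truth_reads)), ]
    truth_reads$read_id <- sprintf("sim_%07d", seq_len(nrow(truth_reads)))
  } else {
    truth_reads$read_id <- character()
  }

  out_seq <- truth_reads$seq
  if (!is.null(params$adapter)) out_seq <- paste0(out_seq, params$adapter)
  reads <- tibble::tibble(
    read_id = truth_reads$read_id,
    seq = out_seq,
    length = nchar(out_seq),
    qual = strrep("I", nchar(out_seq))
  )

  truth_features <- truth_ping_pong(truth_reads)
  truth_classes <- truth_reads %>% dplyr::count(.data$class, name = "reads")

  structure(list(reads = reads, truth = list(reads = truth_reads,
                                             features = truth_features,
                                             classes = truth_classes),
                 params = params),
            class = "pp_library")
}

# Definitional ping-pong accounting over the emission record: for every
# aligned-class feature, count emitted pairs and the reads participating in
# at least one qualifying (overlap-10, 10A-or-1U) pair, judged from the
# emitted positions and read sequences of 23-29 nt reads.
truth_ping_pong <- function(truth_reads) {
  pir <- truth_reads %>%
    dplyr::filter(.data$class %in% c("te_piRNA", "cluster_piRNA"),
                  .data$length >= 23, .data$length <= 29)
  if (!nrow(pir)) {
    return(tibble::tibble(feature = character(), sense_count = integer(),
                          antisense_count = integer(), emitted_pairs = integer(),
                          qualifying_reads = numeric(), total_piRNA_reads = integer(),
                          true_ratio = numeric()))
  }
  df <- pir %>%
    dplyr::mutate(weight = 1,
                  base10 = substr(.data$seq, 10, 10),
                  base1 = substr(.data$seq, 1, 1))
  q <- pp_qualify(df)
  pir %>%
    dplyr::group_by(.data$feature) %>%
    dplyr::summarise(
      sense_count = sum(.data$orientation == "sense"),
      antisense_count = sum(.data$orientation == "antisense"),
      emitted_pairs = sum(!is.na(.data$pair_id)) %/% 2L,
      .groups = "drop") %>%
    dplyr::left_join(
      df %>% dplyr::mutate(qual = q) %>%
        dplyr::group_by(.data$feature) %>%
        dplyr::summarise(qualifying_reads = sum(.data$weight[.data$qual]),
                         total_piRNA_reads = dplyr::n(), .groups = "drop"),
      by = "feature") %>%
    dplyr::mutate(true_ratio = ifelse(.data$total_piRNA_reads > 0,
                                      .data$qualifying_reads / .data$total_piRNA_reads, 0))
}

#' Simulate a two-condition replicate experiment
#'
#' Generates `n_replicates` libraries for a baseline condition A and a
#' perturbed condition B in which the expected per-class emission is scaled
#' by `fold_by_class` while miRNA-hairpin (normaliser) emission is held
#' fixed. Replicate seeds are derived deterministically from `seed`
#' (condition A replicate i uses `seed + i`, condition B uses
#' `seed + n_replicates + i`).
#'
#' @param params baseline [library_params()].
#' @param refs reference set shared by all libraries, or `NULL` to return
#'   only the design (parameters and derived replicate seeds).
#' @param fold_by_class named numeric fold factors (> 0) for classes among
#'   `transposon`, `piRNA_cluster`, `siRNA`; missing classes default to 1.
#' @param n_replicates replicates per condition (>= 2).
#' @param seed root seed; defaults to `params$seed`.
#' @return list with `condition_a`, `condition_b` (lists of `pp_library`;
#'   `NULL` when `refs` is `NULL`), `params_a`, `params_b`, `seeds_a`,
#'   `seeds_b`, `fold_by_class`.
#' @export
simulate_condition_pair <- function(params, refs = NULL,
                                    fold_by_class = c(transposon = 1),
                                    n_replicates = 3, seed = NULL) {
  stopifnot(inherits(params, "library_params"))
  if (n_replicates < 2) abort("`n_replicates` must be >= 2 (replicated tests)")
  if (any(fold_by_class <= 0)) abort("fold factors must be > 0")
  bad <- setdiff(names(fold_by_class), c("transposon", "piRNA_cluster", "siRNA"))
  if (length(bad)) abort(sprintf("unknown fold_by_class name(s): %s", paste(bad, collapse = ", ")))
  if (is.null(seed)) seed <- params$seed
  fold <- function(cls) if (cls %in% names(fold_by_class)) fold_by_class[[cls]] else 1

  mix <- params$class_mix
  n <- params$n_reads
  e_te <- n * mix[["te_piRNA"]] * (1 - params$cluster_fraction)
  e_cl <- n * mix[["te_piRNA"]] * params$cluster_fraction
  e_si <- n * mix[["siRNA"]]
  e_mi <- n * mix[["miRNA_hairpin"]]
  e_rr <- n * mix[["rRNA"]]

  b_te <- e_te * fold("transposon")
  b_cl <- e_cl * fold("piRNA_cluster")
  b_si <- e_si * fold("siRNA")
  n_b <- round(b_te + b_cl + b_si + e_mi + e_rr)

  params_b <- params
  params_b$n_reads <- as.integer(n_b)
  params_b$class_mix <- c(te_piRNA = (b_te + b_cl) / n_b, siRNA = b_si / n_b,
                          miRNA_hairpin = e_mi / n_b, rRNA = e_rr / n_b)
  params_b$class_mix <- params_b$class_mix / sum(params_b$class_mix)
  params_b$cluster_fraction <- if (b_te + b_cl > 0) b_cl / (b_te + b_cl) else 0

  design <- list(params_a = params, params_b = params_b,
                 fold_by_class = fold_by_class,
                 seeds_a = seed + seq_len(n_replicates),
                 seeds_b = seed + n_replicates + seq_len(n_replicates),
                 condition_a = NULL, condition_b = NULL)
  if (is.null(refs)) return(design)
  gen <- function(p, seeds) {
    lapply(seeds, function(s) {
      pi <- p
      pi$seed <- as.integer(s)
      simulate_library(pi, refs)
    })
  }
  design$condition_a <- gen(design$params_a, design$seeds_a)
  design$condition_b <- gen(design$params_b, design$seeds_b)
  design
}
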