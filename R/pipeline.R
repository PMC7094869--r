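#' Process one small RNA library end to end
#'
#' Runs the per-library stages in the fixed order clip -> deplete ->
#' classify -> align -> count/normalise -> ping-pong. Reads are depleted
#' against the rRNA and miRNA-hairpin references (the hairpin matches
#' giving the normaliser), piRNA-class (23-29 nt) reads are aligned to the
#' transposon / piRNA-cluster / gene references, and the ping-pong
#' statistics are computed per feature.
#'
#' @param reads read tibble ([read_fastq()] shape).
#' @param refs annotated reference set ([read_reference_set()] or
#'   [generate_reference_set()]).
#' @param adapter optional 3' adapter to clip (`NULL` = reads are already
#'   adapter-free).
#' @param max_mismatch substitutions allowed in depletion and alignment
#'   (default 1).
#' @param policy multi-mapper policy (see [align_reads()]).
#' @param o_max overlap histogram range (default 30).
#' @param numerator ping-pong numerator mode (see [pingpong_stats()]).
#' @param min_insert,min_match,keep_unclipped adapter-clipping parameters.
#' @return A `pp_library_result` list: `counts`, `class_summary`,
#'   `pingpong`, `profile` (5' base profile of retained reads),
#'   `alignments`, `hairpin_total`, `library_total`, `stage_counts`.
#' @export
process_library <- function(reads, refs, adapter = NULL, max_mismatch = 1,
                            policy = "fractional", o_max = 30,
                            numerator = "reads",
                            min_insert = 18, min_match = 8,
                            keep_unclipped = FALSE) {
  n_input <- nrow(reads)
  clip_stats <- c(input = n_input, clipped = NA, unclipped_kept = NA,
                  discarded_no_adapter = 0, discarded_short = 0)
  if (!is.null(adapter)) {
    reads <- clip_adapter(reads, adapter, min_insert = min_insert,
                          min_match = min_match, keep_unclipped = keep_unclipped)
    clip_stats <- attr(reads, "clip_stats")
  }
  library_total <- nrow(reads)

  depl <- deplete_matching(reads,
                           refs %>% dplyr::filter(.data$feature_class %in%
                                                    c("rRNA", "miRNA_hairpin")),
                           max_mismatch = max_mismatch)
  retained <- classify_by_length(depl$retained)
  profile <- if (nrow(retained)) five_prime_profile(retained) else NULL

  targets <- refs %>%
    dplyr::filter(.data$feature_class %in% c("transposon", "piRNA_cluster", "gene"))
  pir <- retained %>% dplyr::filter(.data$read_class == "piRNA")
  alignments <- align_reads(pir, targets, max_mismatch = max_mismatch,
                            policy = policy)
  counts <- count_by_feature(alignments, hairpin_total = depl$hairpin_total,
                             library_total = library_total)
  csum <- class_summary(counts,
                        refs %>% dplyr::select(name = "name", class = "feature_class"),
                        library_total = library_total,
                        depleted = c(miRNA_hairpin = depl$hairpin_total,
                                     rRNA = depl$rrna_total))
  pp <- pingpong_stats(alignments, pir, o_max = o_max, numerator = numerator)

  structure(list(
    counts = counts, class_summary = csum, pingpong = pp, profile = profile,
    alignments = alignments,
    hairpin_total = depl$hairpin_total, library_total = library_total,
    stage_counts = list(
      input = n_input, clip = as.list(clip_stats),
      after_clip = library_total,
      depleted_rrna = depl$rrna_total, depleted_hairpin = depl$hairpin_total,
      retained = nrow(retained),
      class_counts = as.list(table(retained$read_class)),
      align = as.list(attr(alignments, "align_stats")))),
    class = "pp_library_result")
}

#' Hairpin-normalised per-feature abundance of a processed library
#'
#' @param result a `pp_library_result`.
#' @param orientation `"both"` (default), `"sense"` or `"antisense"`.
#' @return tibble with `feature`, `abundance` (hairpin reads per million).
#' @export
library_abundance <- function(result, orientation = c("both", "sense", "antisense")) {
  orientation <- match.arg(orientation)
  w <- switch(orientation,
              both = result$counts$sense_weight + result$counts$antisense_weight,
              sense = result$counts$sense_weight,
              antisense = result$counts$antisense_weight)
  tibble::tibble(feature = result$counts$feature,
                 abundance = normalize_hairpin(w, result$hairpin_total))
}

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- c("libraries", "refs_fasta", "annotation", "out_dir")
  miss <- setdiff(req, names(config))
  if (length(miss)) abort(sprintf("pipeline config missing field(s): %s",
                                  paste(miss, collapse = ", ")))
  for (lib in config$libraries) {
    if (!all(c("condition", "replicate", "fastq") %in% names(lib))) {
      abort("each library entry needs condition, replicate, fastq")
    }
    if (!file.exists(lib$fastq)) abort(sprintf("missing FASTQ: %s", lib$fastq))
  }
  for (f in c("refs_fasta", "annotation")) {
    if (!file.exists(config[[f]])) abort(sprintf("missing file: %s", config[[f]]))
  }
  config
}

#' Run the full pipeline from a config
#'
#' Executes every stage for each listed library and, when two conditions
#' are present, the cross-condition analyses (per-feature differential
#' abundance, per-class differential, ping-pong ratio comparison). All
#' result tables are written as TSV under `out_dir`, together with a JSON
#' run manifest recording parameters, input checksums and per-stage read
#' counts. Identical config and inputs give identical outputs.
#'
#' @param config a list, or path to a YAML file, with fields `libraries`
#'   (list of `condition`/`replicate`/`fastq`), `refs_fasta`, `annotation`,
#'   `out_dir`, and optional `params` (adapter, max_mismatch, policy,
#'   o_max, numerator, fold_cut, fdr_cut, pseudocount, min_insert,
#'   min_match).
#' @return list (invisible) with per-library results and the
#'   cross-condition objects.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  p <- config$params %||% list()
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  refs <- read_reference_set(config$refs_fasta, config$annotation)

  lib_results <- list()
  abund <- list()
  csums <- list()
  ratios <- list()
  for (lib in config$libraries) {
    tag <- sprintf("%s_rep%s", lib$condition, lib$replicate)
    message("processing library ", tag)
    reads <- read_fastq(lib$fastq)
    res <- process_library(reads, refs,
                           adapter = p$adapter,
                           max_mismatch = p$max_mismatch %||% 1,
                           policy = p$policy %||% "fractional",
                           o_max = p$o_max %||% 30,
                           numerator = p$numerator %||% "reads",
                           min_insert = p$min_insert %||% 18,
                           min_match = p$min_match %||% 8)
    lib_results[[tag]] <- res
    write_result_tsv(res$counts, file.path(out_dir, paste0("counts_", tag, ".tsv")))
    write_result_tsv(res$class_summary, file.path(out_dir, paste0("class_summary_", tag, ".tsv")))
    write_result_tsv(res$pingpong$histogram, file.path(out_dir, paste0("overlap_histogram_", tag, ".tsv")))
    write_result_tsv(res$pingpong$ratios, file.path(out_dir, paste0("pingpong_ratio_", tag, ".tsv")))
    if (!is.null(res$profile)) {
      write_result_tsv(res$profile, file.path(out_dir, paste0("five_prime_profile_", tag, ".tsv")))
    }
    abund[[tag]] <- library_abundance(res) %>%
      dplyr::mutate(condition = lib$condition, replicate = lib$replicate)
    csums[[tag]] <- res$class_summary %>%
      dplyr::mutate(condition = lib$condition, replicate = lib$replicate)
    ratios[[tag]] <- res$pingpong$ratios %>%
      dplyr::select("feature", "ratio") %>%
      dplyr::mutate(condition = lib$condition, replicate = lib$replicate)
  }

  conds <- sort(unique(vapply(config$libraries, `[[`, "", "condition")))
  diff <- class_diff <- ratio_cmp <- NULL
  if (length(conds) == 2) {
    ab <- dplyr::bind_rows(abund)
    # features absent from a library have zero abundance there
    ab <- tidyr::crossing(tibble::tibble(feature = unique(ab$feature)),
                          dplyr::distinct(ab, .data$condition, .data$replicate)) %>%
      dplyr::left_join(ab, by = c("feature", "condition", "replicate")) %>%
      dplyr::mutate(abundance = tidyr::replace_na(.data$abundance, 0))
    diff <- differential_abundance(ab,
                                   fold_cut = p$fold_cut %||% 1.5,
                                   fdr_cut = p$fdr_cut %||% 0.1,
                                   pseudocount = p$pseudocount %||% 1,
                                   test = p$test %||% "t")
    write_result_tsv(tidy(diff), file.path(out_dir, "differential.tsv"))

    cs <- dplyr::bind_rows(csums)
    class_diff <- class_differential(cs)
    write_result_tsv(class_diff, file.path(out_dir, "class_differential.tsv"))

    rt <- dplyr::bind_rows(ratios)
    ratio_cmp <- compare_ratios(rt %>% dplyr::filter(.data$condition == conds[1]),
                                rt %>% dplyr::filter(.data$condition == conds[2]))
    write_result_tsv(ratio_cmp$per_feature, file.path(out_dir, "pingpong_comparison.tsv"))
  }

  manifest <- list(
    package = "pingpongr",
    version = as.character(utils::packageVersion("pingpongr")),
    parameters = p,
    inputs = list(
      refs_fasta = unname(tools::md5sum(config$refs_fasta)),
      annotation = unname(tools::md5sum(config$annotation)),
      libraries = lapply(config$libraries, function(l) {
        list(condition = l$condition, replicate = l$replicate,
             fastq = l$fastq, md5 = unname(tools::md5sum(l$fastq)))
      })),
    stage_counts = lapply(lib_results, `[[`, "stage_counts"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(libraries = lib_results, differential = diff,
                 class_differential = class_diff,
                 ratio_comparison = ratio_cmp,
                 out_dir = out_dir))
}

#' Write a simulated two-condition dataset to disk
#'
#' Generates a reference set and a replicated two-condition experiment and
#' writes everything the pipeline needs: one FASTQ per library, the
#' reference FASTA, the annotation TSV, per-library ground-truth tables and
#' a ready-to-run pipeline config YAML.
#'
#' @param dir output directory (created if needed).
#' @param params baseline [library_params()].
#' @param refs optional pre-built reference set; generated with
#'   `seed = params$seed` when `NULL`.
#' @param fold_by_class,n_replicates,seed see [simulate_condition_pair()].
#' @return path of the written config YAML, invisibly.
#' @export
simulate_dataset <- function(dir, params = library_params(), refs = NULL,
                             fold_by_class = c(transposon = 1),
                             n_replicates = 3, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(refs)) refs <- generate_reference_set(seed = params$seed)
  sim <- simulate_condition_pair(params, refs, fold_by_class = fold_by_class,
                                 n_replicates = n_replicates, seed = seed)
  write_fasta(refs, file.path(dir, "refs.fasta"))
  readr::write_tsv(refs %>% dplyr::select(name = "name", class = "feature_class"),
                   file.path(dir, "annotation.tsv"), col_names = FALSE)

  libraries <- list()
  truth <- list()
  for (cond in c("a", "b")) {
    libs <- sim[[paste0("condition_", cond)]]
    for (i in seq_along(libs)) {
      fq <- file.path(dir, sprintf("reads_%s_rep%d.fastq", cond, i))
      write_fastq(libs[[i]]$reads, fq)
      write_result_tsv(libs[[i]]$truth$features,
                       file.path(dir, sprintf("truth_features_%s_rep%d.tsv", cond, i)))
      libraries[[length(libraries) + 1]] <- list(condition = cond, replicate = i,
                                                 fastq = fq)
      truth[[sprintf("%s_rep%d", cond, i)]] <- libs[[i]]$truth
    }
  }
  config <- list(libraries = libraries,
                 refs_fasta = file.path(dir, "refs.fasta"),
                 annotation = file.path(dir, "annotation.tsv"),
                 out_dir = file.path(dir, "results"),
                 params = list(max_mismatch = 1, policy = "fractional",
                               o_max = 30, numerator = "reads",
                               fold_cut = 1.5, fdr_cut = 0.1, pseudocount = 1))
  if (!is.null(params$adapter)) config$params$adapter <- params$adapter
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
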