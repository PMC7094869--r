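#' Read a FASTQ file of small RNA reads
#'
#' Parses a 4-line-record FASTQ file into a tibble of reads. Bases are
#' uppercased and RNA `U` is stored as DNA `T` (outputs that report base
#' identity convert back to `U`). The quality string is carried along but is
#' not used by any downstream step.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return A tibble with columns `read_id` (first whitespace token of the
#'   header), `seq`, `length` and `qual`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGU", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0) {
    return(tibble::tibble(read_id = character(), seq = character(),
                          length = integer(), qual = character()))
  }
  if (n %% 4 != 0) {
    abort(sprintf("malformed FASTQ %s: %d lines is not a multiple of 4 (truncated record near line %d)",
                  path, n, 4L * (n %/% 4L) + 1L))
  }
  hdr <- lines[seq(1, n, by = 4)]
  seq <- lines[seq(2, n, by = 4)]
  plus <- lines[seq(3, n, by = 4)]
  qual <- lines[seq(4, n, by = 4)]

  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    abort(sprintf("malformed FASTQ %s: header missing '@' at line %d",
                  path, 4L * (bad_hdr[1] - 1L) + 1L))
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    abort(sprintf("malformed FASTQ %s: separator missing '+' at line %d",
                  path, 4L * (bad_plus[1] - 1L) + 3L))
  }
  bad_len <- which(nchar(seq) != nchar(qual))
  if (length(bad_len)) {
    abort(sprintf("malformed FASTQ %s: sequence/quality length mismatch at line %d",
                  path, 4L * (bad_len[1] - 1L) + 2L))
  }
  seq <- normalize_bases(seq)
  tibble::tibble(
    read_id = sub("\\s.*$", "", sub("^@", "", hdr)),
    seq = seq,
    length = nchar(seq),
    qual = qual
  )
}

#' Write reads as FASTQ
#'
#' @param reads tibble with `read_id`, `seq` and optionally `qual` (a run of
#'   `I` is written when absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else strrep("I", nchar(reads$seq))
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$read_id)
  out[seq(2, length(out), by = 4)] <- reads$seq
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Multi-line sequences are concatenated; the record name is the first
#' whitespace token of the header. Bases are uppercased with `U` stored as
#' `T`.
#'
#' @param path path to an uncompressed FASTA file.
#' @return tibble with columns `name` and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(tibble::tibble(name = character(), seq = character()))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) abort(sprintf("malformed FASTA %s: sequence before first '>' header", path))
  rec <- cumsum(is_hdr)
  name <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
  seq <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                paste0, character(1), collapse = "")
  # records with no sequence lines still appear, as empty strings
  full <- setNames(character(max(rec)), as.character(seq_len(max(rec))))
  full[names(seq)] <- seq
  tibble::tibble(name = name, seq = normalize_bases(unname(full)))
}

#' Write named sequences as FASTA
#'
#' @param x tibble with `name` and `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  out <- character(2L * nrow(x))
  out[seq(1, length(out), by = 2)] <- paste0(">", x$name)
  out[seq(2, length(out), by = 2)] <- x$seq
  writeLines(out, path)
  invisible(path)
}

#' Load a feature-class annotation table
#'
#' Reads a two-column TSV (`name`, `class`) mapping reference sequence names
#' to one of the five feature classes (see [feature_classes]).
#'
#' @param path path to the TSV (a header line `name<TAB>class` is accepted
#'   and skipped).
#' @return tibble with columns `name` and `class`.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  x <- readr::read_tsv(path, col_names = c("name", "class"),
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (nrow(x) && x$name[1] == "name" && x$class[1] == "class") x <- x[-1, ]
  bad <- which(!x$class %in% feature_classes)
  if (length(bad)) {
    abort(sprintf("annotation %s: unknown class token(s) [%s] at row(s) %s",
                  path,
                  paste(unique(x$class[bad]), collapse = ", "),
                  paste(head(bad, 10), collapse = ", ")))
  }
  dup <- x %>% dplyr::distinct(.data$name, .data$class) %>%
    dplyr::count(.data$name) %>% dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("annotation %s: conflicting classes for name(s): %s",
                  path, paste(dup$name, collapse = ", ")))
  }
  dplyr::distinct(x)
}

#' Combine a FASTA reference set with its class annotation
#'
#' @param fasta path to the reference FASTA.
#' @param annotation path to the annotation TSV, or a tibble as returned by
#'   [load_annotation()].
#' @return tibble with `name`, `seq`, `feature_class`.
#' @export
read_reference_set <- function(fasta, annotation) {
  refs <- read_fasta(fasta)
  ann <- if (is.character(annotation)) load_annotation(annotation) else annotation
  missing <- setdiff(refs$name, ann$name)
  if (length(missing)) {
    abort(sprintf("reference sequence(s) missing from annotation: %s",
                  paste(missing, collapse = ", ")))
  }
  refs %>%
    dplyr::left_join(ann, by = "name") %>%
    dplyr::rename(feature_class = "class")
}
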