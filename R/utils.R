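#' Feature classes recognised by the pipeline
#'
#' The five genomic feature classes an annotation may assign to a reference
#' sequence. Alignment targets are `transposon`, `piRNA_cluster` and `gene`;
#' `miRNA_hairpin` and `rRNA` sequences are depletion references (hairpin
#' matches double as the between-library normaliser).
#'
#' @export
feature_classes <- c("transposon", "piRNA_cluster", "gene", "miRNA_hairpin", "rRNA")

# reverse complement for plain character DNA (T alphabet, N self-complements)
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# normalise a base string: uppercase, RNA U -> DNA T
normalize_bases <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# report T as U for user-facing base tables
as_rna_base <- function(x) chartr("T", "U", x)

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1) || anyNA(x)) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  invisible(x)
}

# render a numeric column with 6 significant digits for TSV output
format_sig6 <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(signif(x, 6), format = "g", digits = 6))
}

#' Write a result table as TSV
#'
#' Writes a tibble as tab-separated text with a one-line header; numeric
#' (double) columns are rendered with 6 significant digits.
#'
#' @param x a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  out <- as.data.frame(x)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_sig6(out[[j]])
  }
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}
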