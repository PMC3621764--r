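# Shared small helpers: sequence arithmetic and input checks.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' `U` is normalised to `T` first so RNA input is accepted.
#'
#' @param x Character vector of DNA/RNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp_dna("ACGT")
revcomp_dna <- function(x) {
  stopifnot(is.character(x))
  x <- toupper(chartr("u", "U", x))
  x <- chartr("U", "T", x)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Translate DNA to protein with the standard genetic code
#'
#' Codon-wise lookup in [Biostrings::GENETIC_CODE] (NCBI table 1). Trailing
#' bases that do not fill a codon are dropped; codons containing non-ACGT
#' characters translate to `X`.
#'
#' @param x A single DNA string.
#' @return A single amino-acid string (stop = `*`).
#' @export
translate_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(chartr("U", "T", x))
  n <- nchar(x) %/% 3L
  if (n == 0L) return("")
  codons <- substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# single-codon translation, vectorised over codons
codon_aa <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[toupper(codon)])
  aa[is.na(aa)] <- "X"
  aa
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x))
  }
  invisible(x)
}

check_cols <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# sample bases, optionally GC-biased
random_bases <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}
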