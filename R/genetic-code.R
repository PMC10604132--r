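#' @useDynLib mitochar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BASES <- c("A", "C", "G", "T")

#' Genetic code lookup
#'
#' Returns the codon -> amino-acid map for an NCBI translation table,
#' as a named character vector over all 64 codons ("*" marks stops).
#' The package default is table 2 (vertebrate mitochondrial: AGA/AGG are
#' stops, ATA is Met, TGA is Trp).
#'
#' @param code_id NCBI translation table identifier ("1" standard,
#'   "2" vertebrate mitochondrial, ...). Anything accepted by
#'   [Biostrings::getGeneticCode()].
#' @return Named character vector of length 64.
#' @export
#' @examples
#' genetic_code("2")[c("ATA", "TGA", "AGA")]
genetic_code <- function(code_id = "2") {
  Biostrings::getGeneticCode(as.character(code_id))
}

#' Sense (non-stop) codons of a genetic code
#'
#' @inheritParams genetic_code
#' @return Character vector of codons that encode an amino acid
#'   (60 codons for table 2, 61 for table 1), in lexicographic order.
#' @export
sense_codons <- function(code_id = "2") {
  gc <- genetic_code(code_id)
  sort(names(gc)[gc != "*"])
}

#' Stop codons of a genetic code
#' @inheritParams genetic_code
#' @return Character vector of stop codons.
#' @export
stop_codons <- function(code_id = "2") {
  gc <- genetic_code(code_id)
  sort(names(gc)[gc == "*"])
}

#' Translate codons to amino acids
#'
#' @param codons Character vector of 3-mers (may include "---" gap codons,
#'   translated to "-").
#' @inheritParams genetic_code
#' @return Character vector of one-letter amino acids ("*" = stop).
#' @export
translate_codons <- function(codons, code_id = "2") {
  gc <- genetic_code(code_id)
  out <- unname(gc[codons])
  out[codons == "---"] <- "-"
  if (anyNA(out)) {
    bad <- unique(codons[is.na(out)])
    stop("not a codon: ", paste(bad, collapse = ", "))
  }
  out
}

#' Reverse complement of a nucleotide string
#'
#' Accepts A/C/G/T/N (case-insensitive; returned upper case) and the gap
#' character "-".
#'
#' @param seq Single nucleotide string.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

## Split a string into single characters.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

## Validate a nucleotide string: A/C/G/T plus optionally N. Other IUPAC
## ambiguity codes are rejected so downstream composition denominators
## stay well defined.
check_nucleotides <- function(seq, allow_n = TRUE, what = "sequence") {
  ok <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(ok, seq)) {
    bad <- setdiff(unique(seq_chars(seq)), c(BASES, if (allow_n) "N"))
    stop(what, " contains unsupported characters: ",
         paste(bad, collapse = ", "),
         " (only A/C/G/T", if (allow_n) "/N", " are accepted)")
  }
  invisible(seq)
}

## Whether the single-nucleotide change a->b is a transition (purine-purine
## or pyrimidine-pyrimidine).
is_transition <- function(a, b) {
  pur <- c("A", "G")
  (a %in% pur) == (b %in% pur) & a != b
}

## Round half away from zero, matching how the source tables print
## percentages (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
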