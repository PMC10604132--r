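## ---------------------------------------------------------------------------
## Base composition and strand-skew statistics.
##
## AT-skew = (A - T) / (A + T); GC-skew = (G - C) / (G + C), computed on
## whatever strand the input string represents. N bases are excluded from
## every denominator; a skew with a zero denominator is NA (undefined),
## never 0.
## ---------------------------------------------------------------------------

#' Base composition and skew of a nucleotide string
#'
#' @param seq Non-empty nucleotide string over A/C/G/T/N.
#' @return A one-row data.frame with counts `nA`, `nT`, `nG`, `nC`,
#'   percentages `at_percent`, `gc_percent` (over non-N bases) and
#'   `at_skew`, `gc_skew`. Percentages are unrounded; see
#'   [composition_report()] for the 2-decimal presentation.
#' @export
#' @examples
#' base_stats("AAAT")$at_skew   # (3 - 1) / 4 = 0.5
base_stats <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  check_nucleotides(seq, allow_n = TRUE)
  ch <- seq_chars(seq)
  n <- c(A = sum(ch == "A"), C = sum(ch == "C"),
         G = sum(ch == "G"), T = sum(ch == "T"))
  tot <- sum(n)
  if (tot == 0L) stop("sequence is all N")
  skew <- function(x, y) if (x + y == 0) NA_real_ else (x - y) / (x + y)
  data.frame(nA = n[["A"]], nT = n[["T"]], nG = n[["G"]], nC = n[["C"]],
             at_percent = 100 * (n[["A"]] + n[["T"]]) / tot,
             gc_percent = 100 * (n[["G"]] + n[["C"]]) / tot,
             at_skew = skew(n[["A"]], n[["T"]]),
             gc_skew = skew(n[["G"]], n[["C"]]))
}

#' Composition report over the standard mitogenome regions
#'
#' One row per region: the whole genome (H strand as stored), the
#' concatenated 13 protein-coding genes, each PCG individually, the
#' concatenated tRNAs, the concatenated rRNAs, and the control region
#' (an annotated `CR` feature if present, otherwise the longest
#' intergenic spacer per [locate_control_region()]). Per-gene rows are
#' computed on the gene's sense (coding) strand by default, so an
#' L-strand gene such as nad6 shows the skew signature of its own coding
#' sequence; set `sense_strand = FALSE` to measure every region in the
#' H-strand frame instead.
#'
#' @param g A `mito_genome` with sequence present.
#' @param sense_strand Compute per-gene rows on the sense strand (default
#'   TRUE).
#' @return data.frame with columns region, nA, nT, nG, nC, at_percent,
#'   gc_percent, at_skew, gc_skew. Missing feature classes are omitted
#'   with a warning.
#' @export
composition_report <- function(g, sense_strand = TRUE) {
  stopifnot(inherits(g, "mito_genome"))
  if (is.null(g$sequence)) stop("genome ", g$id, " has no sequence")
  f <- g$features
  rows <- list()
  add <- function(region, seq) {
    if (is.null(seq) || nchar(seq) == 0L) return()
    rows[[length(rows) + 1L]] <<- cbind(region = region, base_stats(seq))
  }
  get_seq <- function(rowdf) {
    if (sense_strand) return(extract_feature_sequence(g, rowdf))
    h <- rowdf; h$strand <- "H"
    extract_feature_sequence(g, h)
  }
  add("genome", g$sequence)
  cls <- function(cat) f[f$category == cat, , drop = FALSE]
  pcg <- cls("PCG")
  if (nrow(pcg) > 0L) {
    seqs <- vapply(seq_len(nrow(pcg)),
                   function(i) get_seq(pcg[i, , drop = FALSE]), "")
    add("PCG_concat", paste(seqs, collapse = ""))
    for (i in seq_len(nrow(pcg))) add(pcg$gene[i], seqs[i])
  } else warning("no PCG features; PCG rows omitted")
  trn <- cls("tRNA")
  if (nrow(trn) > 0L) {
    add("tRNA_concat", paste(vapply(seq_len(nrow(trn)),
        function(i) get_seq(trn[i, , drop = FALSE]), ""), collapse = ""))
  } else warning("no tRNA features; tRNA row omitted")
  rrn <- cls("rRNA")
  if (nrow(rrn) > 0L) {
    add("rRNA_concat", paste(vapply(seq_len(nrow(rrn)),
        function(i) get_seq(rrn[i, , drop = FALSE]), ""), collapse = ""))
  } else warning("no rRNA features; rRNA row omitted")
  cr <- tryCatch(suppressWarnings(locate_control_region(g)),
                 error = function(e) NULL)
  if (!is.null(cr)) {
    cr_seq <- if (cr$end >= cr$start) substr(g$sequence, cr$start, cr$end)
    else paste0(substr(g$sequence, cr$start, g$length),
                substr(g$sequence, 1L, cr$end))
    add("control_region", cr_seq)
  } else warning("no control-region candidate; CR row omitted")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round a composition report for presentation
#'
#' Percentages and skews to 2 / 4 decimals, half away from zero.
#'
#' @param report Output of [composition_report()] or [base_stats()].
#' @return The report with rounded numeric columns.
#' @export
format_composition <- function(report) {
  for (cl in c("at_percent", "gc_percent"))
    report[[cl]] <- round_half_up(report[[cl]], 2)
  for (cl in c("at_skew", "gc_skew"))
    report[[cl]] <- round_half_up(report[[cl]], 4)
  report
}
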