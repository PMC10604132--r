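## ---------------------------------------------------------------------------
## Codon extraction, start/stop classification (including incomplete
## stops completed by polyadenylation), codon counting, RSCU and
## amino-acid usage under a configurable genetic code (default: NCBI
## translation table 2, vertebrate mitochondrial).
## ---------------------------------------------------------------------------

#' Split a CDS into codons
#'
#' Reading frame starts at position 1. A trailing 1-2 nt that cannot
#' form a codon is returned as `incomplete_tail` and interpreted as an
#' incomplete stop (completed to TAA by post-transcriptional
#' polyadenylation); it is never counted as a codon. The stop codon is
#' the final complete codon when that codon is a stop under the genetic
#' code, else the incomplete tail.
#'
#' @param cds Nucleotide string, length >= 6.
#' @param gene Optional gene label carried through to the result.
#' @inheritParams genetic_code
#' @return List of class `cds_codons` with fields `gene`, `codons`,
#'   `incomplete_tail`, `start_codon`, `stop_codon`. An internal stop
#'   codon before the final codon triggers a warning naming its position.
#' @export
#' @examples
#' split_codons("ATGAAAT")$incomplete_tail  # "T"
split_codons <- function(cds, gene = NA_character_, code_id = "2") {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) < 6L)
    stop("CDS shorter than 6 nt (", nchar(cds), ")")
  check_nucleotides(cds, allow_n = TRUE, what = "CDS")
  n_cod <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  tail <- substr(cds, 3L * n_cod + 1L, nchar(cds))
  gc <- genetic_code(code_id)
  aa <- unname(gc[codons])
  internal_stop <- which(!is.na(aa) & aa == "*" & seq_along(aa) < n_cod)
  if (length(internal_stop) > 0L)
    warning(if (!is.na(gene)) paste0(gene, ": "),
            "internal stop codon at codon position ",
            paste(internal_stop, collapse = ", "))
  stop_codon <- if (nchar(tail) == 0L) {
    last <- codons[n_cod]
    if (!is.na(gc[last]) && gc[last] == "*") last else NA_character_
  } else tail
  structure(list(gene = gene, codons = codons, incomplete_tail = tail,
                 start_codon = codons[1L], stop_codon = stop_codon,
                 code_id = as.character(code_id)),
            class = "cds_codons")
}

#' Classify start and stop codons of a CDS
#'
#' Start class is one of ATG / GTG / other; stop class is one of
#' TAA / TAG / AGA / AGG / incomplete (AGA and AGG are stops under
#' translation table 2).
#'
#' @param x A `cds_codons` (from [split_codons()]).
#' @return Named character vector c(start = ..., stop = ...).
#' @export
classify_start_stop <- function(x) {
  stopifnot(inherits(x, "cds_codons"))
  start <- if (x$start_codon %in% c("ATG", "GTG")) x$start_codon else "other"
  stop_cl <- if (nchar(x$incomplete_tail) > 0L) "incomplete"
  else if (!is.na(x$stop_codon) &&
           x$stop_codon %in% c("TAA", "TAG", "AGA", "AGG")) x$stop_codon
  else "other"
  c(start = start, stop = stop_cl)
}

## Synonymous families of a genetic code: codons grouped by the amino
## acid they encode (so Leu and Ser are 6-codon families under table 2).
synonymous_families <- function(code_id = "2") {
  gc <- genetic_code(code_id)
  sense <- names(gc)[gc != "*"]
  split(sense, gc[sense])
}

#' Count codons across the protein-coding genes of a genome
#'
#' Codons are pooled over the sense-strand sequences of the 13 PCGs
#' (fewer with a warning), reading each gene in frame from its first
#' position. Incomplete terminal tails are never counted. Two totals are
#' reported: `n_triplets`, the pooled PCG nucleotide length divided by 3
#' (the convention under which a genome annotated like the bundled
#' *M. kuntee* table yields 3813), and `n_codons_no_stop`, the stricter
#' count of complete codons minus terminating stop codons.
#'
#' @param g A `mito_genome` with sequence and PCG features.
#' @inheritParams genetic_code
#' @return Object of class `codon_usage`: list with `counts` (named
#'   integer vector over the 64 codons), `n_triplets`,
#'   `n_codons_no_stop`, `code_id`, and `rscu` (NULL until [rscu()] is
#'   applied).
#' @export
genome_codon_counts <- function(g, code_id = "2") {
  stopifnot(inherits(g, "mito_genome"))
  pcg <- g$features[g$features$category == "PCG", , drop = FALSE]
  if (nrow(pcg) < 13L)
    warning("only ", nrow(pcg), " PCG features present; proceeding")
  if (nrow(pcg) == 0L) stop("no PCG features")
  if (is.null(g$sequence)) stop("genome ", g$id, " has no sequence")
  all_codons <- character(0)
  total_nt <- 0L
  n_stop <- 0L
  gc <- genetic_code(code_id)
  for (i in seq_len(nrow(pcg))) {
    cds <- extract_feature_sequence(g, pcg[i, , drop = FALSE])
    total_nt <- total_nt + nchar(cds)
    cc <- suppressWarnings(split_codons(cds, pcg$gene[i], code_id))
    last <- cc$codons[length(cc$codons)]
    if (nchar(cc$incomplete_tail) == 0L &&
        !is.na(gc[last]) && gc[last] == "*")
      n_stop <- n_stop + 1L
    all_codons <- c(all_codons, cc$codons)
  }
  counts <- table(factor(all_codons, levels = names(gc)))
  counts <- stats::setNames(as.integer(counts), names(gc))
  structure(list(counts = counts,
                 n_triplets = total_nt %/% 3L,
                 n_codons_no_stop = length(all_codons) - n_stop,
                 code_id = as.character(code_id), rscu = NULL),
            class = "codon_usage")
}

#' Build a codon_usage object from raw counts
#'
#' @param counts Named integer vector (codon -> count); codons absent
#'   from the vector count 0.
#' @inheritParams genetic_code
#' @return A `codon_usage` object.
#' @export
codon_usage_table <- function(counts, code_id = "2") {
  gc <- genetic_code(code_id)
  full <- stats::setNames(integer(64), names(gc))
  if (!all(names(counts) %in% names(full)))
    stop("unknown codon(s): ",
         paste(setdiff(names(counts), names(full)), collapse = ", "))
  full[names(counts)] <- as.integer(counts)
  structure(list(counts = full, n_triplets = sum(full),
                 n_codons_no_stop = sum(full[gc[names(full)] != "*"]),
                 code_id = as.character(code_id), rscu = NULL),
            class = "codon_usage")
}

#' Relative synonymous codon usage
#'
#' For codon j in a synonymous family i of size n_i with counts X,
#' RSCU_ij = X_ij * n_i / sum_j X_ij. Families are the amino-acid
#' synonym sets of the genetic code in force; stop codons are excluded.
#' Families with zero total get RSCU 0 and are flagged in
#' `rscu_undefined`.
#'
#' @param t A `codon_usage` object.
#' @return The object with `rscu` (named numeric over sense codons) and
#'   `rscu_undefined` (logical, same names) filled.
#' @export
rscu <- function(t) {
  stopifnot(inherits(t, "codon_usage"))
  fam <- synonymous_families(t$code_id)
  sense <- unlist(fam, use.names = FALSE)
  out <- stats::setNames(numeric(length(sense)), sense)
  undef <- stats::setNames(logical(length(sense)), sense)
  for (codons in fam) {
    tot <- sum(t$counts[codons])
    if (tot == 0) {
      out[codons] <- 0
      undef[codons] <- TRUE
    } else {
      out[codons] <- t$counts[codons] * length(codons) / tot
    }
  }
  t$rscu <- out[order(names(out))]
  t$rscu_undefined <- undef[order(names(undef))]
  t
}

#' Amino-acid usage from codon counts
#'
#' @param t A `codon_usage` object.
#' @return data.frame (amino_acid, count, frequency) sorted by
#'   decreasing count; stop codons excluded.
#' @export
amino_acid_usage <- function(t) {
  stopifnot(inherits(t, "codon_usage"))
  gc <- genetic_code(t$code_id)
  sense <- names(gc)[gc != "*"]
  agg <- tapply(t$counts[sense], gc[sense], sum)
  out <- data.frame(amino_acid = names(agg),
                    count = as.integer(agg),
                    stringsAsFactors = FALSE)
  out$frequency <- if (sum(out$count) > 0) out$count / sum(out$count) else 0
  out <- out[order(-out$count, out$amino_acid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Codon usage as a tidy table
#'
#' @param t A `codon_usage` object (with or without RSCU filled).
#' @return data.frame (codon, amino_acid, count, rscu) over sense codons,
#'   plus stop rows with NA rscu.
#' @export
codon_usage_report <- function(t) {
  stopifnot(inherits(t, "codon_usage"))
  if (is.null(t$rscu)) t <- rscu(t)
  gc <- genetic_code(t$code_id)
  codons <- sort(names(gc))
  out <- data.frame(codon = codons,
                    amino_acid = unname(gc[codons]),
                    count = unname(t$counts[codons]),
                    rscu = NA_real_,
                    stringsAsFactors = FALSE)
  out$rscu[match(names(t$rscu), out$codon)] <- unname(t$rscu)
  out
}
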