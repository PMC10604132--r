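## ---------------------------------------------------------------------------
## Multiple-alignment container and construction: pairwise global
## alignment with affine gaps, progressive alignment over a UPGMA guide
## tree, conserved-block trimming, and supermatrix concatenation.
## ---------------------------------------------------------------------------

#' Construct a multiple alignment
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (gap character "-").
#' @param partition Optional data.frame (gene, start, end) of disjoint
#'   column ranges.
#' @return Object of class `mito_aln`.
#' @export
mito_alignment <- function(seqs, partition = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length")
  if (!is.null(partition)) {
    stopifnot(all(c("gene", "start", "end") %in% colnames(partition)))
    o <- order(partition$start)
    partition <- partition[o, , drop = FALSE]
    if (any(partition$start > partition$end) ||
        any(utils::head(partition$end, -1L) >=
            partition$start[-1L]))
      stop("partition ranges must be disjoint and increasing")
    if (max(partition$end) > nchar(seqs[1L]))
      stop("partition exceeds alignment length")
  }
  structure(list(seqs = toupper(seqs), partition = partition),
            class = "mito_aln")
}

#' @export
print.mito_aln <- function(x, ...) {
  cat("<mito_aln> ", length(x$seqs), " taxa x ", nchar(x$seqs[1L]),
      " columns", sep = "")
  if (!is.null(x$partition))
    cat(" (", nrow(x$partition), " partitions)", sep = "")
  cat("\n")
  invisible(x)
}

#' Taxa of an alignment
#' @param aln A `mito_aln`.
#' @return Character vector of taxon labels.
#' @export
aln_taxa <- function(aln) names(aln$seqs)

#' Number of columns of an alignment
#' @param aln A `mito_aln`.
#' @return Integer column count.
#' @export
aln_ncol <- function(aln) nchar(aln$seqs[[1L]])

#' Alignment as a character matrix (taxa x columns)
#' @param aln A `mito_aln`.
#' @return Character matrix with taxon rownames.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  m
}

#' Read an aligned FASTA file
#' @param path FASTA path.
#' @return A `mito_aln`.
#' @export
read_alignment <- function(path) mito_alignment(read_fasta(path))

#' Write an alignment as FASTA
#' @param aln A `mito_aln`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) write_fasta(aln$seqs, path)

## One-hot profile (5 x L matrix over A,C,G,T,-) of a set of gapped rows.
profile_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  L <- ncol(m)
  prof <- matrix(0, nrow = 5L, ncol = L,
                 dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  for (i in seq_len(5L))
    prof[i, ] <- colMeans(m == rownames(prof)[i])
  prof
}

## Expand an alignment of profiles back to rows, given the column maps
## returned by the C++ aligner (0 = new gap column).
apply_column_map <- function(seqs, map) {
  out <- vapply(seqs, function(s) {
    ch <- seq_chars(s)
    paste(ifelse(map == 0L, "-", ch[pmax(map, 1L)]), collapse = "")
  }, "")
  names(out) <- names(seqs)
  out
}

#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch/Gotoh global alignment. A gap of length k scores
#' `gap_open + (k - 1) * gap_extend`. Ties are broken deterministically
#' (prefer the diagonal move, then the gap-in-second move), so the
#' output is unique.
#'
#' @param a,b Nucleotide strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A `mito_aln` of the two sequences (named "a" and "b" unless
#'   the inputs carry names), with attribute `score`.
#' @export
#' @examples
#' pairwise_align("ACGT", "ACGT")
pairwise_align <- function(a, b, match = 1, mismatch = -1,
                           gap_open = -5, gap_extend = -1) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty input sequence")
  na <- if (!is.null(names(a))) names(a) else "a"
  nb <- if (!is.null(names(b))) names(b) else "b"
  res <- cpp_align_profiles(profile_matrix(unname(a)),
                            profile_matrix(unname(b)),
                            match, mismatch, gap_open, gap_extend)
  seqs <- c(apply_column_map(stats::setNames(unname(a), na), res$map_a),
            apply_column_map(stats::setNames(unname(b), nb), res$map_b))
  out <- mito_alignment(seqs)
  attr(out, "score") <- res$score
  out
}

## p-distance between two unaligned sequences, on their common prefix
## length (guide-tree heuristic only).
crude_p_distance <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(1)
  cx <- seq_chars(substr(x, 1, n))
  cy <- seq_chars(substr(y, 1, n))
  mean(cx != cy) + abs(nchar(x) - nchar(y)) / max(nchar(x), nchar(y))
}

#' Progressive multiple alignment
#'
#' Profiles are merged leaf-to-root along a UPGMA guide tree built from
#' crude pairwise p-distances. Sequences are processed in sorted label
#' order, so the result is invariant to input order.
#'
#' @param seqs Named character vector of >= 2 sequences (unique labels).
#' @inheritParams pairwise_align
#' @return A `mito_aln` with rows in the input order.
#' @export
progressive_align <- function(seqs, match = 1, mismatch = -1,
                              gap_open = -5, gap_extend = -1) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique labels")
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  input_order <- names(seqs)
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- crude_p_distance(seqs[[i]], seqs[[j]])
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ## groups[[k]] holds the aligned rows of cluster k
  groups <- lapply(seq_len(n), function(i) seqs[i])
  merged <- vector("list", nrow(hc$merge))
  pick <- function(k) if (k < 0) groups[[-k]] else merged[[k]]
  for (m in seq_len(nrow(hc$merge))) {
    ga <- pick(hc$merge[m, 1L])
    gb <- pick(hc$merge[m, 2L])
    res <- cpp_align_profiles(profile_matrix(ga), profile_matrix(gb),
                              match, mismatch, gap_open, gap_extend)
    merged[[m]] <- c(apply_column_map(ga, res$map_a),
                     apply_column_map(gb, res$map_b))
  }
  final <- merged[[nrow(hc$merge)]]
  mito_alignment(final[input_order])
}

#' Trim ambiguously aligned columns into conserved blocks
#'
#' A simplified, fully parameterized conserved-block filter. Columns are
#' classified by the frequency of their most common residue:
#' "conserved" at `min_conserved_frac`, "highly conserved" at
#' `min_flank_frac`; with `allow_gaps = "none"` any gapped column is
#' nonconserved. Runs of more than `max_contig_nonconserved`
#' nonconserved columns are removed, surviving blocks are trimmed so
#' both flanks are highly conserved, and blocks shorter than `min_block`
#' are dropped. Retained columns keep their order and content.
#'
#' @param aln A `mito_aln`.
#' @param min_conserved_frac,min_flank_frac Identity thresholds in (0, 1].
#' @param max_contig_nonconserved Longest kept run of nonconserved
#'   columns inside a block.
#' @param min_block Minimum block length (columns).
#' @param allow_gaps "none" (default) or "all".
#' @return A `mito_aln` of the retained columns with attribute
#'   `kept_columns` (integer original column indices). Errors when no
#'   column survives or `min_block` exceeds the alignment length.
#' @export
trim_blocks <- function(aln, min_conserved_frac = 0.5,
                        min_flank_frac = 0.85,
                        max_contig_nonconserved = 8L,
                        min_block = 10L, allow_gaps = c("none", "all")) {
  allow_gaps <- match.arg(allow_gaps)
  m <- aln_matrix(aln)
  L <- ncol(m)
  if (min_block > L) stop("min_block exceeds alignment length")
  nseq <- nrow(m)
  top_frac <- apply(m, 2L, function(col) {
    counts <- table(col[col != "-"])
    if (length(counts) == 0L) 0 else max(counts) / nseq
  })
  gapped <- colSums(m == "-") > 0L
  conserved <- top_frac >= min_conserved_frac
  flank <- top_frac >= min_flank_frac
  if (allow_gaps == "none") {
    conserved <- conserved & !gapped
    flank <- flank & !gapped
  }
  keep <- rep(TRUE, L)
  r <- rle(conserved)
  bounds <- cumsum(r$lengths)
  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  for (k in seq_along(r$values))
    if (!r$values[k] && r$lengths[k] > max_contig_nonconserved)
      keep[starts[k]:bounds[k]] <- FALSE
  ## assemble candidate blocks, trim to highly conserved flanks
  kept_cols <- integer(0)
  rr <- rle(keep)
  bb <- cumsum(rr$lengths)
  ss <- c(1L, utils::head(bb, -1L) + 1L)
  for (k in seq_along(rr$values)) {
    if (!rr$values[k]) next
    cols <- ss[k]:bb[k]
    good <- which(flank[cols])
    if (length(good) == 0L) next
    cols <- cols[min(good):max(good)]
    if (length(cols) >= min_block) kept_cols <- c(kept_cols, cols)
  }
  if (length(kept_cols) == 0L) stop("no column survives trimming")
  seqs <- apply(m[, kept_cols, drop = FALSE], 1L, paste, collapse = "")
  out <- mito_alignment(stats::setNames(seqs, rownames(m)))
  attr(out, "kept_columns") <- kept_cols
  out
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param alns Named list of `mito_aln` objects (names = gene labels;
#'   unnamed lists get gene1, gene2, ...). Taxa missing from a gene get
#'   an all-gap row for that range, with a warning.
#' @return A `mito_aln` over the union of taxa, with a partition
#'   recording each gene's column range.
#' @export
concatenate_alignments <- function(alns) {
  if (length(alns) == 0L) stop("empty alignment list")
  if (is.null(names(alns)))
    names(alns) <- paste0("gene", seq_along(alns))
  taxa <- sort(unique(unlist(lapply(alns, aln_taxa))))
  pieces <- matrix("", nrow = length(taxa), ncol = length(alns),
                   dimnames = list(taxa, names(alns)))
  part <- data.frame(gene = names(alns), start = NA_integer_,
                     end = NA_integer_, stringsAsFactors = FALSE)
  at <- 1L
  for (k in seq_along(alns)) {
    a <- alns[[k]]
    w <- aln_ncol(a)
    missing <- setdiff(taxa, aln_taxa(a))
    if (length(missing) > 0L)
      warning("taxa missing from ", names(alns)[k], ": ",
              paste(missing, collapse = ", "), " (all-gap rows inserted)")
    for (tx in taxa)
      pieces[tx, k] <- if (tx %in% aln_taxa(a)) a$seqs[[tx]]
      else strrep("-", w)
    part$start[k] <- at
    part$end[k] <- at + w - 1L
    at <- at + w
  }
  seqs <- apply(pieces, 1L, paste, collapse = "")
  mito_alignment(stats::setNames(seqs, taxa), partition = part)
}
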