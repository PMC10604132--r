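## ---------------------------------------------------------------------------
## Gene architecture on a circular molecule: gene order, overlap and
## intergenic-spacer detection, control-region localization, and
## cross-genome arrangement comparison (signed, circular).
## ---------------------------------------------------------------------------

## Decompose a (possibly origin-spanning) feature into 1-2 linear segments.
interval_segments <- function(start, end, genome_length) {
  if (end >= start) list(c(start, end))
  else list(c(start, genome_length), c(1L, end))
}

## Length of the intersection of two circular intervals.
circular_overlap_length <- function(s1, e1, s2, e2, genome_length) {
  a <- interval_segments(s1, e1, genome_length)
  b <- interval_segments(s2, e2, genome_length)
  tot <- 0L
  for (x in a) for (y in b)
    tot <- tot + max(0L, min(x[2], y[2]) - max(x[1], y[1]) + 1L)
  tot
}

#' Gene order of a genome
#'
#' @param g A `mito_genome`.
#' @return data.frame (gene, strand) sorted by start coordinate. An
#'   error is raised if two features share a name (ambiguous order).
#' @export
gene_order <- function(g) {
  stopifnot(inherits(g, "mito_genome"))
  f <- g$features
  if (anyDuplicated(f$gene))
    stop("duplicated gene names: ",
         paste(unique(f$gene[duplicated(f$gene)]), collapse = ", "))
  data.frame(gene = f$gene, strand = f$strand, stringsAsFactors = FALSE)
}

#' Find overlapping feature pairs
#'
#' All pairwise intersections among annotated features, circular-aware.
#' `gene_a` is the member that starts first in coordinate order. When
#' the genome sequence is present, the overlap motif is reported in the
#' H-strand frame regardless of the member strands (a mixed-strand
#' overlap has no single sense frame).
#'
#' @param g A `mito_genome`.
#' @param min_len Minimum overlap length to report (default 1 bp).
#' @return data.frame (gene_a, gene_b, length, motif); zero rows if no
#'   overlaps.
#' @export
find_overlaps <- function(g, min_len = 1L) {
  stopifnot(inherits(g, "mito_genome"))
  f <- g$features
  out <- list()
  if (nrow(f) >= 2L) {
    for (i in seq_len(nrow(f) - 1L)) for (j in (i + 1L):nrow(f)) {
      len <- circular_overlap_length(f$start[i], f$end[i],
                                     f$start[j], f$end[j], g$length)
      if (len >= min_len) {
        motif <- NA_character_
        if (!is.null(g$sequence)) {
          segs_i <- interval_segments(f$start[i], f$end[i], g$length)
          segs_j <- interval_segments(f$start[j], f$end[j], g$length)
          pieces <- character(0)
          for (x in segs_i) for (y in segs_j) {
            lo <- max(x[1], y[1]); hi <- min(x[2], y[2])
            if (lo <= hi)
              pieces <- c(pieces, substr(g$sequence, lo, hi))
          }
          motif <- paste(pieces, collapse = "")
        }
        out[[length(out) + 1L]] <- data.frame(
          gene_a = f$gene[i], gene_b = f$gene[j],
          length = len, motif = motif, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      length = integer(), motif = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find intergenic spacers
#'
#' Maximal runs of positions covered by no feature, circular-aware. A
#' spacer that spans the origin is reported with `start > end`.
#'
#' @param g A `mito_genome`.
#' @param min_len Minimum spacer length to report (default 1 bp).
#' @return data.frame (gene_a, gene_b, start, end, length) in coordinate
#'   order, where gene_a/gene_b are the flanking features.
#' @export
find_spacers <- function(g, min_len = 1L) {
  stopifnot(inherits(g, "mito_genome"))
  f <- g$features
  L <- g$length
  covered <- logical(L)
  for (i in seq_len(nrow(f)))
    for (seg in interval_segments(f$start[i], f$end[i], L))
      covered[seg[1]:seg[2]] <- TRUE
  if (all(covered) || nrow(f) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      start = integer(), end = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  ## maximal uncovered runs on the circle
  r <- rle(covered)
  bounds <- cumsum(r$lengths)
  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  gaps <- data.frame(start = starts[!r$values],
                     end = bounds[!r$values])
  if (g$circular && nrow(gaps) >= 2L &&
      gaps$start[1L] == 1L && gaps$end[nrow(gaps)] == L) {
    ## merge the run touching position 1 with the run touching position L
    gaps$start[1L] <- gaps$start[nrow(gaps)]
    gaps <- gaps[-nrow(gaps), , drop = FALSE]
  }
  len <- ifelse(gaps$end >= gaps$start, gaps$end - gaps$start + 1L,
                (L - gaps$start + 1L) + gaps$end)
  gaps$length <- as.integer(len)
  gaps <- gaps[gaps$length >= min_len, , drop = FALSE]
  flank <- function(pos) {
    hits <- which(vapply(seq_len(nrow(f)), function(i) {
      any(vapply(interval_segments(f$start[i], f$end[i], L),
                 function(seg) pos >= seg[1] && pos <= seg[2], TRUE))
    }, TRUE))
    if (length(hits) == 0L) return(NA_character_)
    f$gene[hits[1L]]
  }
  prev_pos <- ifelse(gaps$start == 1L, L, gaps$start - 1L)
  next_pos <- ifelse(gaps$end == L, 1L, gaps$end + 1L)
  gaps$gene_a <- vapply(prev_pos, flank, "")
  gaps$gene_b <- vapply(next_pos, flank, "")
  res <- gaps[, c("gene_a", "gene_b", "start", "end", "length")]
  rownames(res) <- NULL
  res
}

#' Locate the control region
#'
#' If the genome carries an explicit control-region feature, its
#' interval is returned. Otherwise the longest intergenic spacer is
#' taken as the control-region candidate (in the typical vertebrate
#' arrangement it lies between trnP and trnF); a warning is issued when
#' its flanks are not trnP/trnF, and an error when no spacer reaches
#' `min_len`.
#'
#' @param g A `mito_genome`.
#' @param min_len Minimum credible control-region length (default 200 bp).
#' @return One-row data.frame (gene_a, gene_b, start, end, length).
#' @export
locate_control_region <- function(g, min_len = 200L) {
  stopifnot(inherits(g, "mito_genome"))
  f <- g$features
  cr <- which(f$category == "control_region")
  if (length(cr) > 0L) {
    i <- cr[1L]
    return(data.frame(gene_a = NA_character_, gene_b = NA_character_,
                      start = f$start[i], end = f$end[i],
                      length = feature_length(f[i, , drop = FALSE],
                                              g$length, g$circular),
                      stringsAsFactors = FALSE))
  }
  sp <- find_spacers(g)
  sp <- sp[sp$length >= min_len, , drop = FALSE]
  if (nrow(sp) == 0L)
    stop("no control region candidate (no spacer >= ", min_len, " bp)")
  best <- sp[which.max(sp$length), , drop = FALSE]
  if (!identical(sort(c(best$gene_a, best$gene_b)), c("trnF", "trnP")))
    warning("longest spacer is flanked by ", best$gene_a, "/",
            best$gene_b, ", not trnP/trnF")
  rownames(best) <- NULL
  best
}

## Signed circular adjacency set of an arrangement. Each adjacency
## (x_signed, y_signed) is canonicalized with its reading-direction
## equivalent (-y, -x).
signed_adjacencies <- function(ord) {
  sign <- ifelse(ord$strand == "H", "+", "-")
  lab <- paste0(sign, ord$gene)
  neg <- ifelse(ord$strand == "H", "-", "+")
  lab_neg <- paste0(neg, ord$gene)
  n <- nrow(ord)
  adj <- character(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- paste(lab[i], lab[j])
    b <- paste(lab_neg[j], lab_neg[i])
    adj[i] <- min(a, b)
  }
  adj
}

#' Compare the gene arrangements of two genomes
#'
#' Arrangements are compared as signed circular gene orders. `identical`
#' is TRUE when one order is a rotation of the other (same genes, same
#' strands, same succession); `breakpoints` counts the signed circular
#' adjacencies of `a` absent from `b` (0 iff identical up to rotation).
#'
#' @param a,b `mito_genome` objects over the same gene set.
#' @return list(identical = flag, breakpoints = count).
#' @export
compare_orders <- function(a, b) {
  oa <- gene_order(a); ob <- gene_order(b)
  if (!setequal(oa$gene, ob$gene)) {
    d <- c(setdiff(oa$gene, ob$gene), setdiff(ob$gene, oa$gene))
    stop("gene sets differ; symmetric difference: ",
         paste(d, collapse = ", "))
  }
  sa <- paste0(ifelse(oa$strand == "H", "+", "-"), oa$gene)
  sb <- paste0(ifelse(ob$strand == "H", "+", "-"), ob$gene)
  ## rotation check by the doubling trick on the signed string
  wrap <- function(x) paste0("|", paste(x, collapse = "|"), "|")
  ident <- length(sa) == length(sb) &&
    grepl(wrap(sa), wrap(c(sb, sb)), fixed = TRUE)
  aa <- signed_adjacencies(oa)
  ab <- signed_adjacencies(ob)
  list(identical = ident, breakpoints = sum(!aa %in% ab))
}

#' Multi-genome arrangement table
#'
#' One row per genome with its ordered signed gene string, for
#' cross-species arrangement comparison.
#'
#' @param genomes List of `mito_genome` objects.
#' @return data.frame (id, n_genes, arrangement).
#' @export
arrangement_table <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    o <- gene_order(g)
    data.frame(id = g$id, n_genes = nrow(o),
               arrangement = paste(
                 paste0(ifelse(o$strand == "H", "+", "-"), o$gene),
                 collapse = " "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
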