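## ---------------------------------------------------------------------------
## Non-coding region analytics: conserved sequence blocks (CSBs) in
## control-region alignments, and stem-loop (light-strand replication
## origin) detection by exhaustive inverted-repeat search.
## ---------------------------------------------------------------------------

## Per-column majority-base identity (gap-inclusive denominator) and gap
## fraction of an alignment character matrix.
column_scores <- function(m) {
  nseq <- nrow(m)
  identity <- apply(m, 2L, function(col) {
    counts <- table(col[col %in% BASES])
    if (length(counts) == 0L) 0 else max(counts) / nseq
  })
  list(identity = identity, gap_frac = colMeans(m == "-"))
}

#' Detect conserved sequence blocks in a control-region alignment
#'
#' Columns are scored by majority-base identity with a gap-inclusive
#' denominator. A window of `window` consecutive columns qualifies when
#' its mean identity reaches `min_identity` and no column in it exceeds
#' `max_gap_frac` gaps. Qualifying windows are merged into runs; runs
#' shorter than `min_block` columns are dropped, and surviving blocks
#' are numbered CSB-I, CSB-II, ... in coordinate order.
#'
#' @param aln A `mito_aln` of >= 3 aligned control regions.
#' @param window Window width in columns (default 15).
#' @param min_identity Mean identity threshold per window (default 0.85).
#' @param min_block Minimum block width in columns (default 12).
#' @param max_gap_frac Maximum per-column gap fraction (default 0.2).
#' @return data.frame with one row per block: block label, `aln_start`,
#'   `aln_end`, `length`, `mean_identity`, `consensus` (per-column
#'   majority base, ties to the alphabetically first), and pooled
#'   composition columns nA, nT, nG, nC, a_percent, t_percent,
#'   g_percent, c_percent over the ungapped block residues of all
#'   sequences.
#' @export
detect_csbs <- function(aln, window = 15L, min_identity = 0.85,
                        min_block = 12L, max_gap_frac = 0.2) {
  stopifnot(inherits(aln, "mito_aln"))
  if (length(aln$seqs) < 3L)
    stop("need at least 3 aligned sequences (got ", length(aln$seqs), ")")
  m <- aln_matrix(aln)
  L <- ncol(m)
  sc <- column_scores(m)
  qual_cols <- rep(FALSE, L)
  if (L >= window) {
    gap_ok <- sc$gap_frac <= max_gap_frac
    for (i in seq_len(L - window + 1L)) {
      cols <- i:(i + window - 1L)
      if (all(gap_ok[cols]) && mean(sc$identity[cols]) >= min_identity)
        qual_cols[cols] <- TRUE
    }
  }
  empty <- data.frame(block = character(), aln_start = integer(),
                      aln_end = integer(), length = integer(),
                      mean_identity = numeric(), consensus = character(),
                      nA = integer(), nT = integer(), nG = integer(),
                      nC = integer(), a_percent = numeric(),
                      t_percent = numeric(), g_percent = numeric(),
                      c_percent = numeric(), stringsAsFactors = FALSE)
  if (!any(qual_cols)) return(empty)
  r <- rle(qual_cols)
  bounds <- cumsum(r$lengths)
  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  rows <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_block) next
    cols <- starts[k]:bounds[k]
    sub <- m[, cols, drop = FALSE]
    consensus <- apply(sub, 2L, function(col) {
      counts <- table(factor(col[col %in% BASES], levels = BASES))
      if (sum(counts) == 0L) "N" else BASES[which.max(counts)]
    })
    res <- sub[sub %in% BASES]
    n <- c(A = sum(res == "A"), T = sum(res == "T"),
           G = sum(res == "G"), C = sum(res == "C"))
    tot <- sum(n)
    rows[[length(rows) + 1L]] <- data.frame(
      block = NA_character_, aln_start = cols[1L],
      aln_end = cols[length(cols)], length = length(cols),
      mean_identity = mean(sc$identity[cols]),
      consensus = paste(consensus, collapse = ""),
      nA = n[["A"]], nT = n[["T"]], nG = n[["G"]], nC = n[["C"]],
      a_percent = 100 * n[["A"]] / tot, t_percent = 100 * n[["T"]] / tot,
      g_percent = 100 * n[["G"]] / tot, c_percent = 100 * n[["C"]] / tot,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$block <- paste0("CSB-", as.character(utils::as.roman(seq_len(nrow(out)))))
  rownames(out) <- NULL
  out
}

#' Base-composition table of detected blocks
#'
#' @param blocks Output of [detect_csbs()].
#' @return data.frame block x {A, T, G, C} percentages, 2 decimals
#'   (half away from zero), rows in block order.
#' @export
block_composition_table <- function(blocks) {
  data.frame(block = blocks$block,
             A = round_half_up(blocks$a_percent, 2),
             T = round_half_up(blocks$t_percent, 2),
             G = round_half_up(blocks$g_percent, 2),
             C = round_half_up(blocks$c_percent, 2),
             stringsAsFactors = FALSE)
}

## Watson-Crick pair check for two single characters.
wc_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

#' Find stem-loop structures (inverted repeats)
#'
#' Exhaustive search for hairpins: a 5' arm, a loop of `loop_min` to
#' `loop_max` nt, and a 3' arm that is the reverse complement of the 5'
#' arm up to `max_mismatch` violated pairs. Only maximal hairpins are
#' reported: ones whose stem can be extended neither outward nor inward
#' (into the loop) without breaking the constraints. G-U wobble pairs do
#' not count as pairs. Results are ranked by (gc_pairs, stem_len)
#' descending, then by position.
#'
#' @param seq Nucleotide string (intended for short regions; the search
#'   is exhaustive and quadratic).
#' @param min_stem Minimum stem length in pairs (default 5).
#' @param loop_min,loop_max Loop length bounds in nt (defaults 3, 20).
#' @param max_mismatch Maximum number of non-pairing stem positions
#'   (default 0).
#' @return data.frame with columns start, end, stem_len, gc_pairs,
#'   mismatches, loop_start, loop_end, arm5, loop_seq, arm3,
#'   dot_bracket (structure over [start, end]).
#' @export
#' @examples
#' find_stem_loops("GGGGGAAAACCCCC")
find_stem_loops <- function(seq, min_stem = 5L, loop_min = 3L,
                            loop_max = 20L, max_mismatch = 0L) {
  seq <- toupper(seq)
  check_nucleotides(seq, allow_n = TRUE)
  ch <- seq_chars(seq)
  n <- length(ch)
  rows <- list()
  if (n >= 2L * min_stem + loop_min) {
    for (a in seq_len(n)) {      # loop start
      for (l in loop_min:loop_max) {
        b <- a + l - 1L          # loop end
        if (b > n - 1L) break
        ## grow the stem outward from the loop
        k <- 0L
        mism <- integer(0)
        while (a - k - 1L >= 1L && b + k + 1L <= n) {
          k <- k + 1L
          mism <- c(mism, !wc_pair(ch[a - k], ch[b + k]))
          if (sum(mism) > max_mismatch) {
            k <- k - 1L
            mism <- mism[-length(mism)]
            break
          }
        }
        if (k < min_stem) next
        ## outward-maximal by construction of the while loop; check it
        ## is not inward-extensible (shrinking the loop by 2)
        if (l - 2L >= loop_min &&
            sum(mism) + !wc_pair(ch[a], ch[b]) <= max_mismatch) next
        i5 <- (a - k):(a - 1L)
        i3 <- (b + k):(b + 1L)   # descending: i3[j] pairs with i5[j]
        pair_ok <- wc_pair(ch[i5], ch[i3])
        gc <- sum(pair_ok & (ch[i5] %in% c("G", "C")))
        db <- paste0(paste(ifelse(pair_ok, "(", "."), collapse = ""),
                     strrep(".", l),
                     paste(rev(ifelse(pair_ok, ")", ".")), collapse = ""))
        rows[[length(rows) + 1L]] <- data.frame(
          start = a - k, end = b + k, stem_len = k, gc_pairs = gc,
          mismatches = sum(!pair_ok), loop_start = a, loop_end = b,
          arm5 = paste(ch[i5], collapse = ""),
          loop_seq = paste(ch[a:b], collapse = ""),
          arm3 = paste(ch[(b + 1L):(b + k)], collapse = ""),
          dot_bracket = db, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      stem_len = integer(), gc_pairs = integer(),
                      mismatches = integer(), loop_start = integer(),
                      loop_end = integer(), arm5 = character(),
                      loop_seq = character(), arm3 = character(),
                      dot_bracket = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(-out$gc_pairs, -out$stem_len, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
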