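## Independent brute-force oracles used across the test files. These are
## deliberately naive (position sets, full enumeration, recursive
## scoring) and share no code with the implementation paths they check.

## All-pairs interval intersection by explicit position sets on the
## circle.
oracle_overlaps <- function(features, genome_length) {
  posset <- function(s, e) {
    if (e >= s) s:e else c(s:genome_length, 1:e)
  }
  out <- list()
  n <- nrow(features)
  if (n < 2L) return(data.frame(gene_a = character(),
                                gene_b = character(),
                                length = integer()))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    len <- length(intersect(posset(features$start[i], features$end[i]),
                            posset(features$start[j], features$end[j])))
    if (len > 0L)
      out[[length(out) + 1L]] <- data.frame(
        gene_a = features$gene[i], gene_b = features$gene[j],
        length = len, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      length = integer()))
  do.call(rbind, out)
}

## Exhaustive hairpin enumeration over all (arm length, loop) placements.
oracle_stem_loops <- function(seq, min_stem = 5L, loop_min = 3L,
                              loop_max = 20L, max_mismatch = 0L) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  n <- length(ch)
  comp <- c(A = "T", T = "A", G = "C", C = "G", N = "X")
  pairs_ok <- function(i5, i3) comp[ch[i5]] == ch[i3]
  hits <- list()
  for (start in seq_len(n)) {
    for (k in min_stem:floor((n - loop_min) / 2)) {
      for (l in loop_min:loop_max) {
        end <- start + 2L * k + l - 1L
        if (end > n) next
        i5 <- start:(start + k - 1L)
        i3 <- end:(end - k + 1L)
        mism <- sum(!pairs_ok(i5, i3))
        if (mism > max_mismatch) next
        ## maximality: no outward or inward extension
        out_ok <- start > 1L && end < n &&
          (mism + !pairs_ok(start - 1L, end + 1L)) <= max_mismatch
        in_ok <- (l - 2L) >= loop_min &&
          (mism + !pairs_ok(start + k, end - k)) <= max_mismatch
        if (out_ok || in_ok) next
        hits[[length(hits) + 1L]] <- c(start = start, end = end,
                                       stem_len = k, mism = mism)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      stem_len = integer(), mism = integer()))
  unique(as.data.frame(do.call(rbind, hits)))
}

## Brute-force per-window CSB scoring (the definition restated naively).
oracle_csb_columns <- function(mat, window, min_identity, max_gap_frac) {
  L <- ncol(mat)
  nseq <- nrow(mat)
  ident <- numeric(L)
  gapf <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    counts <- table(col[col %in% c("A", "C", "G", "T")])
    ident[j] <- if (length(counts) == 0L) 0 else max(counts) / nseq
    gapf[j] <- mean(col == "-")
  }
  qual <- rep(FALSE, L)
  if (L >= window) {
    for (i in 1:(L - window + 1L)) {
      cols <- i:(i + window - 1L)
      if (mean(ident[cols]) >= min_identity &&
          all(gapf[cols] <= max_gap_frac))
        qual[cols] <- TRUE
    }
  }
  qual
}

## Exhaustive global alignment score by recursion (tiny strings only);
## gap of length k costs open + (k - 1) * extend.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -5, gap_extend = -1) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  memo <- new.env(parent = emptyenv())
  ## state: position in a, position in b, previous move (0 none/diag,
  ## 1 gap-in-b, 2 gap-in-a)
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= length(ca)) {
      g <- if (prev == 1L) gap_extend else gap_open
      best <- max(best, g + rec(i + 1L, j, 1L))
    }
    if (j <= length(cb)) {
      g <- if (prev == 2L) gap_extend else gap_open
      best <- max(best, g + rec(i, j + 1L, 2L))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

## Minimum Fitch change count by exhaustive assignment of internal
## states (states restricted to those observed at the leaves, which is
## sufficient for the parsimony minimum).
oracle_fitch_changes <- function(tree, column) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- sort(unique(column[!is.na(column) & column != "---"]))
  tipstate <- column[tree$tip.label]
  internal <- ntip + seq_len(nnode)
  grid <- expand.grid(rep(list(states), nnode),
                      stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_all <- c(tipstate, unlist(grid[r, ]))
    cost <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- assign_all[tree$edge[e, 1L]]
      c_ <- assign_all[tree$edge[e, 2L]]
      if (is.na(p) || is.na(c_) || p == "---" || c_ == "---") next
      if (p != c_) cost <- cost + 1L
    }
    best <- min(best, cost)
  }
  best
}

## Enumerate syn/nonsyn over stop-free orderings between two codons.
oracle_pathway_counts <- function(from, to, code_id = "2") {
  gc <- mitochar::genetic_code(code_id)
  cf <- strsplit(from, "")[[1L]]
  ct <- strsplit(to, "")[[1L]]
  diffs <- which(cf != ct)
  perms <- if (length(diffs) <= 1L) list(diffs) else {
    if (length(diffs) == 2L) list(diffs, rev(diffs)) else {
      out <- list()
      for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                     c(3, 1, 2), c(3, 2, 1)))
        out[[length(out) + 1L]] <- diffs[p]
      out
    }
  }
  rows <- list()
  for (ord in perms) {
    cur <- cf; syn <- 0; nonsyn <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- ct[pos]
      if (gc[paste(nxt, collapse = "")] == "*") { ok <- FALSE; break }
      if (gc[paste(nxt, collapse = "")] ==
          gc[paste(cur, collapse = "")]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    if (ok) rows[[length(rows) + 1L]] <- c(syn, nonsyn)
  }
  if (length(rows) == 0L) return(NULL)
  colMeans(do.call(rbind, rows))
}

## A random annotated feature set on a circular genome (possibly with
## origin-spanning features).
random_features <- function(n, genome_length, allow_wrap = TRUE) {
  starts <- sample.int(genome_length, n, replace = TRUE)
  lens <- sample.int(max(2L, genome_length %/% 4L), n, replace = TRUE)
  ends <- starts + lens - 1L
  wrap <- ends > genome_length
  if (!allow_wrap) {
    ends[wrap] <- genome_length
  } else {
    ends[wrap] <- ends[wrap] - genome_length
  }
  data.frame(gene = paste0("g", seq_len(n)),
             category = "other",
             start = starts, end = ends,
             strand = sample(c("H", "L"), n, replace = TRUE),
             anticodon = NA_character_, start_codon = NA_character_,
             stop_codon = NA_character_, stringsAsFactors = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
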