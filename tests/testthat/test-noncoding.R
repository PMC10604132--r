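test_that("identical sequences form one block spanning all columns", {
  seqs <- stats::setNames(rep(strrep("ACGTT", 10), 5),
                          paste0("s", 1:5))
  aln <- mito_alignment(seqs)
  b <- detect_csbs(aln)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$aln_start, b$aln_end), c(1L, 50L))
  expect_equal(b$mean_identity, 1)
  expect_equal(b$consensus, strrep("ACGTT", 10))
  expect_error(detect_csbs(mito_alignment(seqs[1:2])), "at least 3")
})

test_that("an embedded invariant motif is the only block called", {
  set.seed(21)
  n <- 8L; L <- 120L
  motif <- strsplit("ACGGATTACCAGTACGGATT", "")[[1]]  # 20 columns
  at <- 51L
  rows <- replicate(n, sample(c("A", "C", "G", "T"), L, replace = TRUE))
  rows <- t(rows)
  for (i in seq_len(n)) rows[i, at:(at + 19L)] <- motif
  seqs <- apply(rows, 1L, paste, collapse = "")
  names(seqs) <- paste0("s", seq_len(n))
  aln <- mito_alignment(seqs)
  b <- detect_csbs(aln)
  expect_equal(nrow(b), 1L)
  expect_lte(abs(b$aln_start - at), 4L)
  expect_lte(abs(b$aln_end - (at + 19L)), 4L)
  ## block columns agree with the naive per-window scorer
  qual <- oracle_csb_columns(aln_matrix(aln), 15L, 0.85, 0.2)
  expect_equal(b$aln_start, min(which(qual)))
  expect_equal(b$aln_end, max(which(qual)))
  ## an alignment with nothing above threshold yields no blocks
  seqs2 <- apply(rows[, 1:40], 1L, paste, collapse = "")
  names(seqs2) <- names(seqs)
  expect_equal(nrow(detect_csbs(mito_alignment(seqs2))), 0L)
})

test_that("window qualification equals the brute-force scorer on random alignments", {
  set.seed(22)
  for (rep in 1:8) {
    n <- sample(3:10, 1)
    L <- sample(40:150, 1)
    p_gap <- runif(1, 0, 0.15)
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    m <- t(replicate(n, ifelse(runif(L) < 0.6, base,
                               sample(c("A", "C", "G", "T", "-"), L,
                                      replace = TRUE,
                                      prob = c(rep((1 - p_gap) / 4, 4),
                                               p_gap)))))
    seqs <- apply(m, 1L, paste, collapse = "")
    names(seqs) <- paste0("s", seq_len(n))
    aln <- mito_alignment(seqs)
    b <- detect_csbs(aln, window = 10L, min_identity = 0.8,
                     min_block = 10L, max_gap_frac = 0.2)
    qual <- oracle_csb_columns(aln_matrix(aln), 10L, 0.8, 0.2)
    runs <- rle(qual)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    keep <- runs$values & runs$lengths >= 10L
    expect_equal(b$aln_start, starts[keep])
    expect_equal(b$aln_end, ends[keep])
  }
})

test_that("block composition percentages come from pooled residues", {
  seqs <- stats::setNames(rep("AATTCCAATTCCAATTCC", 3), paste0("s", 1:3))
  b <- detect_csbs(mito_alignment(seqs), window = 6L, min_block = 6L)
  comp <- block_composition_table(b)
  expect_equal(comp$A, 33.33)
  expect_equal(comp$T, 33.33)
  expect_equal(comp$C, 33.33)
  expect_equal(comp$G, 0)
  allA <- detect_csbs(mito_alignment(
    stats::setNames(rep(strrep("A", 20), 3), paste0("s", 1:3))),
    window = 6L, min_block = 6L)
  expect_equal(block_composition_table(allA)$A, 100)
})

test_that("the seeded C-rich conserved block keeps its composition", {
  ## control regions from a study-set-like construction: frozen CSB
  ## columns over a highly divergent background
  set.seed(23)
  g <- make_genome(genome_spec(seed = 23))
  cr <- attr(g, "cr_interval")
  base <- strsplit(substr(g$sequence, cr[1], cr[2]), "")[[1]]
  csb <- attr(g, "csb_offsets") - cr[1] + 1L
  csb_cols <- unlist(lapply(csb, function(o) o:(o + 19L)))
  seqs <- vapply(1:8, function(i) {
    x <- base
    hit <- setdiff(which(runif(length(x)) < 0.75), csb_cols)
    x[hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    paste(x, collapse = "")
  }, "")
  names(seqs) <- paste0("s", 1:8)
  blocks <- detect_csbs(mito_alignment(seqs), min_identity = 0.95)
  expect_equal(nrow(blocks), 5L)
  comp <- block_composition_table(blocks)
  expect_equal(comp$C[4L], 70, tolerance = 5 / 70)
})

test_that("hairpin detection finds the canonical example exactly", {
  h <- find_stem_loops("GGGGGAAAACCCCC")
  expect_equal(nrow(h), 1L)
  expect_equal(h$stem_len, 5L)
  expect_equal(h$gc_pairs, 5L)
  expect_equal(h$loop_seq, "AAAA")
  expect_equal(h$arm5, "GGGGG")
  expect_equal(h$arm3, "CCCCC")
  expect_equal(h$dot_bracket, "(((((....)))))")
  expect_equal(nrow(find_stem_loops("ACACACACAC")), 0L)
})

test_that("every reported hairpin satisfies the arm complement relation", {
  set.seed(24)
  for (rep in 1:10) {
    s <- random_dna(sample(20:60, 1))
    h <- find_stem_loops(s, min_stem = 3L, max_mismatch = 1L)
    if (nrow(h) == 0L) next
    for (r in seq_len(nrow(h))) {
      mism <- sum(strsplit(h$arm3[r], "")[[1]] !=
                    strsplit(revcomp(h$arm5[r]), "")[[1]])
      expect_lte(mism, 1L)
      expect_equal(mism, h$mismatches[r])
    }
  }
})

test_that("hairpin search equals exhaustive enumeration on short strings", {
  set.seed(25)
  cases <- c(replicate(12, random_dna(sample(15:50, 1))),
             "GGGGGAAAACCCCC", "GCGCGCAAAGCGCGC")
  for (s in cases) {
    got <- find_stem_loops(s, min_stem = 4L)
    want <- oracle_stem_loops(s, min_stem = 4L)
    key <- function(d) sort(paste(d$start, d$end, d$stem_len))
    expect_equal(key(got), key(want))
  }
})

test_that("the synthetic replication origin carries its designed stem", {
  for (gcn in c(7L, 8L)) {
    g <- make_genome(genome_spec(ol_stem_gc = gcn, seed = 30 + gcn))
    iv <- attr(g, "ol_interval")
    h <- find_stem_loops(substr(g$sequence, iv[1], iv[2]))
    expect_gte(nrow(h), 1L)
    expect_equal(h$gc_pairs[1L], gcn)
    expect_equal(h$mismatches[1L], 0L)
  }
})
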