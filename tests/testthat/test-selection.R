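test_that("ng_sites matches hand enumeration for canonical codons", {
  ## TTT (Phe): only the third-position TTC change is synonymous
  expect_equal(ng_sites("TTT"), c(S = 1 / 3, N = 8 / 3))
  ## a 4-fold third position contributes a full synonymous site
  gca <- ng_sites("GCA")
  expect_equal(unname(gca["S"]), 1)
  ## ATG: positions 1-2 fully nonsynonymous; position 3 has ATA = Met
  ## (code 2), so S = 1/3 in total
  atg <- ng_sites("ATG")
  expect_equal(unname(atg["S"]), 1 / 3)
  expect_error(ng_sites("TAA"), "stop")
  expect_error(ng_sites("---"), "gap")
})

test_that("ng_sites equals exhaustive neighbor enumeration for all 60 codons", {
  gc <- genetic_code("2")
  for (codon in sense_codons("2")) {
    ch <- strsplit(codon, "")[[1]]
    S <- 0; N <- 0
    for (pos in 1:3) {
      syn <- 0; non <- 0; stp <- 0
      for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
        mut <- ch; mut[pos] <- b
        aa <- gc[paste(mut, collapse = "")]
        if (aa == "*") stp <- stp + 1
        else if (aa == gc[codon]) syn <- syn + 1
        else non <- non + 1
      }
      if (syn + non > 0) {
        S <- S + syn / (syn + non)
        N <- N + non / (syn + non)
      }
    }
    expect_equal(ng_sites(codon), c(S = S, N = N), info = codon)
    ## under the stops-as-nonsynonymous flag every position counts 1
    alt <- ng_sites(codon, stops_as_nonsyn = TRUE)
    expect_equal(unname(alt["S"] + alt["N"]), 3)
  }
})

test_that("Fitch reconstruction matches examples and brute force", {
  t4 <- ape::read.tree(text = "((A,B),(C,D));")
  ## invariant column: zero changes
  inv <- fitch_ancestral(t4, c(A = "TTT", B = "TTT", C = "TTT",
                               D = "TTT"))
  expect_equal(inv$changes, 0L)
  expect_true(all(inv$states == "TTT"))
  ## one change on the internal edge
  two <- fitch_ancestral(t4, c(A = "TTT", B = "TTT", C = "TTC",
                               D = "TTC"))
  expect_equal(two$changes, 1L)
  ## a missing leaf does not add changes
  mis <- fitch_ancestral(t4, c(A = "TTT", B = "---", C = "TTC",
                               D = "TTC"))
  expect_equal(mis$changes, 1L)
  ## brute-force equivalence on random trees and columns
  set.seed(51)
  states_pool <- c("TTT", "TTC", "CTT", "ATT")
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n)
    col <- stats::setNames(sample(states_pool, n, replace = TRUE),
                           tr$tip.label)
    if (rep %% 3 == 0) col[sample(n, 1)] <- "---"
    got <- fitch_ancestral(tr, col)
    if (all(col == "---")) next
    expect_equal(got$changes, oracle_fitch_changes(tr, col))
  }
})

test_that("pathway averaging preserves the step count and avoids stops", {
  ## single-step synonymous change
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  ca <- codon_alignment(matrix(c("TTT", "TTC"), nrow = 2,
                               dimnames = list(c("A", "B"), NULL)))
  res <- slac(ca, t2)
  expect_equal(res$OS, 1)
  expect_equal(res$ON, 0)
  ## two-step change: counts equal the mean over stop-free orderings
  for (pair in list(c("TTT", "GTA"), c("ATG", "CTA"), c("TCA", "ACC"),
                    c("TTT", "CAG"))) {
    want <- oracle_pathway_counts(pair[1], pair[2])
    if (is.null(want)) next
    ca2 <- codon_alignment(matrix(pair, nrow = 2,
                                  dimnames = list(c("A", "B"), NULL)))
    got <- slac(ca2, t2)
    expect_equal(got$OS, want[[1]], info = paste(pair, collapse = ">"))
    expect_equal(got$ON, want[[2]], info = paste(pair, collapse = ">"))
    nd <- sum(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]])
    expect_equal(got$OS + got$ON, nd)   # conservation
  }
})

test_that("OS + ON equals the summed codon Hamming distance over branches", {
  set.seed(52)
  tr <- ape::rtree(6)
  sense <- sense_codons("2")
  m <- matrix(sample(sense, 6 * 20, replace = TRUE), nrow = 6,
              dimnames = list(tr$tip.label, NULL))
  ca <- codon_alignment(m)
  res <- slac(ca, tr)
  ## recompute expected steps from the reconstructions used
  for (s in sample(20, 5)) {
    fr <- fitch_ancestral(tr, stats::setNames(m[, s], tr$tip.label))
    steps <- 0L
    for (e in seq_len(nrow(tr$edge))) {
      a <- fr$states[tr$edge[e, 1]]
      b <- fr$states[tr$edge[e, 2]]
      steps <- steps + sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }
    expect_equal(res$OS[s] + res$ON[s], steps)
  }
})

test_that("slac classifies an invariant alignment as neutral", {
  tr <- ape::rtree(5)
  m <- matrix("ATG", nrow = 5, ncol = 4,
              dimnames = list(tr$tip.label, NULL))
  res <- slac(codon_alignment(m), tr)
  expect_true(all(res$OS == 0))
  expect_true(all(res$ON == 0))
  expect_true(all(res$classification == "neutral/ns"))
  expect_equal(res$ES + res$EN, rep(3, 4), tolerance = 0.2)
  expect_error(slac(codon_alignment(m), ape::rtree(4)), "taxa")
})

test_that("backtranslation maps aligned residues to source codons", {
  paln <- mito_alignment(stats::setNames(c("MK-", "MKV"), c("x", "y")))
  ca <- backtranslate(paln, c(x = "ATGAAATAA", y = "ATGAAAGTT"))
  expect_equal(unname(ca$codons["x", ]), c("ATG", "AAA", "---"))
  expect_equal(unname(ca$codons["y", ]), c("ATG", "AAA", "GTT"))
  ## translation mismatch is an error naming the taxon
  expect_error(backtranslate(paln, c(x = "ATGATTTAA", y = "ATGAAAGTT")),
               "x")
  ## column count equals summed protein length on a simulated set
  set.seed(53)
  tr <- ape::rtree(4)
  root <- sample(sense_codons("2"), 30, replace = TRUE)
  ev <- evolve_codons(root, tr, seed = 5)
  prot <- vapply(rownames(ev$alignment$codons), function(tx)
    paste(translate_codons(ev$alignment$codons[tx, ]), collapse = ""),
    "")
  cds <- vapply(rownames(ev$alignment$codons), function(tx)
    paste(ev$alignment$codons[tx, ], collapse = ""), "")
  ca2 <- backtranslate(mito_alignment(prot), cds)
  expect_equal(ncol(ca2$codons), 30L)
  expect_equal(ca2$codons, ev$alignment$codons)
})

test_that("summaries split significant sites by selection direction", {
  empty <- classify_summary(data.frame(dn_minus_ds = numeric(),
                                       p_value = numeric()))
  expect_equal(unname(empty$counts), c(0L, 0L, 0L))
  res <- data.frame(dn_minus_ds = c(-1, -2, 1, -0.5),
                    p_value = c(0.01, 0.2, 0.01, 0.04),
                    gene = c("g1", "g1", "g2", "g2"),
                    stringsAsFactors = FALSE)
  s <- classify_summary(res)
  expect_equal(unname(s$counts["purifying_sig"]), 2L)
  expect_equal(unname(s$counts["positive_sig"]), 1L)
  expect_equal(s$per_gene$purifying_sig[s$per_gene$gene == "g2"], 1L)
})

test_that("fel_lite flags invariant sites as untestable-neutral", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  m <- matrix("GCT", nrow = 4, ncol = 2,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  res <- fel_lite(codon_alignment(m), tr)
  expect_equal(res$beta_rate, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
  expect_true(all(res$classification == "neutral/ns"))
})

test_that("fel_lite ranks purifying sites below neutral ones", {
  set.seed(54)
  tr <- ape::read.tree(text = paste0(
    "(((t1:0.2,t2:0.2):0.2,(t3:0.2,t4:0.2):0.2):0.2,",
    "((t5:0.2,t6:0.2):0.2,(t7:0.2,t8:0.2):0.2):0.2);"))
  root <- sample(sense_codons("2"), 30, replace = TRUE)
  ev <- evolve_codons(root, tr, kappa = 1, omega = 0.2, seed = 8)
  res <- fel_lite(ev$alignment, tr)
  ratio <- res$beta_rate / pmax(res$alpha_rate, 1e-9)
  expect_lt(median(ratio[res$alpha_rate > 0], na.rm = TRUE), 1)
})
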