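test_that("distance models match their closed forms", {
  ## identical rows are at distance 0 under every model
  aln <- mito_alignment(stats::setNames(rep("ACGTACGTAC", 3),
                                        c("a", "b", "c")))
  for (m in c("p", "JC69", "K2P"))
    expect_true(all(distance_matrix(aln, m) == 0))
  ## p = 0.5 gives the textbook JC69 value
  a2 <- mito_alignment(stats::setNames(c("AAAA", "AACC"), c("x", "y")))
  D <- distance_matrix(a2, "JC69")
  expect_equal(D["x", "y"], -0.75 * log(1 / 3))
  expect_equal(distance_matrix(a2, "p")["x", "y"], 0.5)
  ## K2P with only transitions at proportion P: d = -1/2 log(1 - 2P)
  a3 <- mito_alignment(stats::setNames(c("AAAAAAAA", "GGAAAAAA"),
                                       c("x", "y")))
  P <- 0.25
  expect_equal(distance_matrix(a3, "K2P")["x", "y"],
               -0.5 * log(1 - 2 * P))
  ## saturation is an error naming the pair
  a4 <- mito_alignment(stats::setNames(c("AAAA", "CCCC"), c("u", "v")))
  expect_error(distance_matrix(a4, "JC69"), "u/v")
})

test_that("gap handling drops sites pairwise or completely", {
  aln <- mito_alignment(stats::setNames(c("ACGT", "AC-T", "ACGA"),
                                        c("a", "b", "c")))
  Dp <- distance_matrix(aln, "p", gap_deletion = "pairwise")
  expect_equal(Dp["a", "b"], 0)          # 3 comparable sites, all equal
  expect_equal(Dp["a", "c"], 0.25)
  Dc <- distance_matrix(aln, "p", gap_deletion = "complete")
  expect_equal(Dc["a", "c"], 1 / 3)       # column 3 dropped for all
})

test_that("JC69 increases strictly with p below saturation", {
  ps <- seq(0.05, 0.7, by = 0.05)
  d <- -0.75 * log(1 - 4 * ps / 3)
  expect_true(all(diff(d) > 0))
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(41)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    true <- ape::unroot(true)
    D <- ape::cophenetic.phylo(true)
    o <- sample(rownames(D))      # taxon order should not matter
    est <- nj_tree(D[o, o])
    expect_equal(rf_distance(est, true), 0L)
    ## branch lengths are recovered too: path lengths match
    De <- ape::cophenetic.phylo(est)
    expect_equal(De[rownames(D), colnames(D)], D, tolerance = 1e-6)
  }
})

test_that("neighbor joining is deterministic under ties", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- suppressWarnings(nj_tree(D))
  t2 <- suppressWarnings(nj_tree(D))
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  Dn <- D; Dn[1, 2] <- 5
  expect_error(nj_tree(Dn), "symmetric")
})

test_that("Robinson-Foulds distance counts bipartition differences", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  t3 <- ape::read.tree(text = "((a,b),(c,e));")
  expect_error(rf_distance(t1, t3), "leaf sets")
  ## agrees with the independent implementation on random trees
  skip_if_not_installed("phangorn")
  set.seed(42)
  for (rep in 1:10) {
    x <- ape::unroot(ape::rtree(8))
    y <- ape::unroot(ape::rtree(8, tip.label = x$tip.label))
    expect_equal(rf_distance(x, y),
                 as.integer(phangorn::RF.dist(x, y)))
  }
})

test_that("monophyly means forming one side of an edge bipartition", {
  t <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  expect_true(is_monophyletic(t, c("a", "b")))
  expect_true(is_monophyletic(t, c("d", "e")))
  expect_true(is_monophyletic(t, c("c", "d", "e")))
  expect_false(is_monophyletic(t, c("a", "c")))
  expect_true(is_monophyletic(t, "a"))          # trivial
  expect_error(is_monophyletic(t, "zzz"), "not in tree")
})

test_that("bootstrap supports are reproducible and sensible", {
  set.seed(43)
  ## two clear clades separated by many substitutions
  mutate <- function(base, k) {
    ch <- strsplit(base, "")[[1]]
    idx <- sample(seq_along(ch), k)
    ch[idx] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  block <- function(base, k) vapply(1:k, function(i) mutate(base, 4), "")
  b1 <- random_dna(200)
  b2 <- mutate(b1, 70)
  seqs <- stats::setNames(c(block(b1, 3), block(b2, 3)),
                          c("a1", "a2", "a3", "b1", "b2", "b3"))
  aln <- mito_alignment(seqs)
  tr1 <- bootstrap_support(aln, n_reps = 50, seed = 99)
  tr2 <- bootstrap_support(aln, n_reps = 50, seed = 99)
  expect_equal(ape::write.tree(tr1), ape::write.tree(tr2))
  sup <- suppressWarnings(as.integer(tr1$node.label))
  expect_true(any(sup >= 95, na.rm = TRUE))
  expect_true(is_monophyletic(tr1, c("a1", "a2", "a3")))
  expect_error(bootstrap_support(aln, n_reps = 0), "n_reps")
  ## identical sequences: no informative bipartition gets a support
  same <- mito_alignment(stats::setNames(rep(random_dna(50), 4),
                                         c("w", "x", "y", "z")))
  trs <- bootstrap_support(same, n_reps = 10, seed = 7)
  expect_true(all(trs$node.label %in% c("", NA)))
})
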