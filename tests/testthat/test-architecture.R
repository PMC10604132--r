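test_that("gene order and strand inventory match the annotation", {
  g <- mkuntee_annotation()
  o <- gene_order(g)
  expect_equal(o$gene[1:3], c("cox1", "trnS2", "trnD"))
  expect_equal(o$strand[1:3], c("H", "L", "H"))
  trn <- o[grepl("^trn", o$gene), ]
  expect_equal(sum(trn$strand == "H"), 14L)
  expect_equal(sum(trn$strand == "L"), 8L)
  ## the only L-strand PCG is nad6
  pcg_l <- g$features$gene[g$features$category == "PCG" &
                             g$features$strand == "L"]
  expect_equal(pcg_l, "nad6")
  g0 <- mito_genome("empty", length = 10L)
  expect_equal(nrow(gene_order(g0)), 0L)
  gd <- mito_genome("dup", rbind(gene_feature("a", 1, 5),
                                 gene_feature("a", 7, 9)))
  expect_error(gene_order(gd), "duplicated")
})

test_that("the annotated genome has the three conserved PCG overlaps", {
  ov <- find_overlaps(mkuntee_annotation())
  pick <- function(a, b) ov$length[ov$gene_a == a & ov$gene_b == b]
  expect_equal(pick("atp8", "atp6"), 10L)
  expect_equal(pick("nad4l", "nad4"), 7L)
  expect_equal(pick("nad5", "nad6"), 5L)
  ## touching features do not overlap
  g <- mito_genome("t", rbind(gene_feature("a", 1, 10),
                              gene_feature("b", 11, 20)), length = 30L)
  expect_equal(nrow(find_overlaps(g)), 0L)
})

test_that("overlap detection matches the all-pairs position-set oracle", {
  set.seed(13)
  for (rep in 1:15) {
    L <- sample(50:200, 1)
    f <- random_features(sample(2:12, 1), L)
    g <- mito_genome("r", f, length = L)
    got <- find_overlaps(g)
    want <- oracle_overlaps(g$features, L)
    key <- function(d) sort(paste(d$gene_a, d$gene_b, d$length))
    expect_equal(key(got), key(want))
  }
})

test_that("spacers are the maximal uncovered runs, circular-aware", {
  g <- mkuntee_annotation()
  sp <- find_spacers(g)
  cr <- sp[sp$gene_a == "trnP" & sp$gene_b == "trnF", ]
  expect_equal(cr$length, 862L)
  expect_equal(c(cr$start, cr$end), c(10192L, 11053L))
  ol <- sp[sp$gene_a == "trnN" & sp$gene_b == "trnC", ]
  expect_equal(ol$length, 33L)
  ## contiguous features leave no spacer
  gc_ <- mito_genome("c", rbind(gene_feature("a", 1, 6),
                                gene_feature("b", 7, 12)),
                     length = 12L)
  expect_equal(nrow(find_spacers(gc_)), 0L)
  ## a gap across the origin is one spacer
  gw <- mito_genome("w", rbind(gene_feature("a", 3, 6)), length = 10L)
  sw <- find_spacers(gw)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$length, 6L)
  expect_equal(c(sw$start, sw$end), c(7L, 2L))
})

test_that("feature coverage plus spacers account for the whole circle", {
  set.seed(14)
  for (rep in 1:10) {
    L <- sample(60:200, 1)
    f <- random_features(sample(2:10, 1), L)
    g <- mito_genome("r", f, length = L)
    covered <- logical(L)
    for (i in seq_len(nrow(g$features))) {
      s <- g$features$start[i]; e <- g$features$end[i]
      idx <- if (e >= s) s:e else c(s:L, 1:e)
      covered[idx] <- TRUE
    }
    expect_equal(sum(find_spacers(g)$length), L - sum(covered))
  }
})

test_that("control-region localization prefers annotation, else longest gap", {
  g <- mkuntee_annotation()
  cr <- locate_control_region(g)
  expect_equal(cr$length, 862L)
  expect_equal(sort(c(cr$gene_a, cr$gene_b)), c("trnF", "trnP"))
  ## explicit CR feature takes precedence
  feats <- rbind(gene_feature("a", 1, 100), gene_feature("CR", 301, 900),
                 gene_feature("b", 901, 1000))
  ge <- mito_genome("e", feats, length = 1000L)
  expect_equal(locate_control_region(ge)$start, 301L)
  expect_equal(locate_control_region(ge)$length, 600L)
  ## no credible gap
  gn <- mito_genome("n", rbind(gene_feature("a", 1, 90)), length = 100L)
  expect_error(locate_control_region(gn), "no control region")
  ## warning when flanks are unexpected
  gwarn <- mito_genome("w", rbind(gene_feature("a", 1, 100),
                                  gene_feature("b", 400, 500)),
                       length = 500L)
  expect_warning(locate_control_region(gwarn), "not trnP/trnF")
})

test_that("arrangement comparison is rotation-invariant and signed", {
  g <- mkuntee_annotation()
  self <- compare_orders(g, g)
  expect_true(self$identical)
  expect_equal(self$breakpoints, 0L)
  ## rotation: renumber so a later gene starts the circle
  f <- g$features
  k <- 20L
  shift <- function(x, L) ((x - f$start[k]) %% L) + 1L
  f2 <- f
  f2$start <- shift(f$start, g$length)
  f2$end <- shift(f$end, g$length)
  g2 <- mito_genome("rot", f2, length = g$length)
  rot <- compare_orders(g, g2)
  expect_true(rot$identical)
  expect_equal(rot$breakpoints, 0L)
  ## swapping two genes breaks adjacencies
  f3 <- f
  i <- which(f$gene == "trnP"); j <- which(f$gene == "trnT")
  f3$gene[c(i, j)] <- f$gene[c(j, i)]
  g3 <- mito_genome("swap", f3, length = g$length)
  sw <- compare_orders(g, g3)
  expect_false(sw$identical)
  expect_gte(sw$breakpoints, 2L)
  expect_equal(compare_orders(g3, g)$identical, sw$identical)
  ## differing gene sets are an error
  f4 <- f[-1L, ]
  expect_error(compare_orders(g, mito_genome("m", f4, length = g$length)),
               "cox1")
})
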