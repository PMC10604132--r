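test_that("the bundled annotation reproduces the printed sizes", {
  g <- mkuntee_annotation()
  expect_equal(nrow(g$features), 37L)
  expect_equal(sum(g$features$category == "PCG"), 13L)
  expect_equal(sum(g$features$category == "tRNA"), 22L)
  expect_equal(sum(g$features$category == "rRNA"), 2L)
  expect_equal(g$length, 16529L)
  ## the size column of the source table was validated on read (all 37
  ## rows); spot-check a couple directly
  lens <- feature_length(g)
  names(lens) <- g$features$gene
  expect_equal(lens[["nad4"]], 1381L)
  expect_equal(lens[["trnC"]], 65L)
  expect_equal(lens[["cox2"]] %% 3L, 1L)   # incomplete-stop gene
})

test_that("feature_length handles origin-spanning features", {
  f <- data.frame(gene = "x", start = 16500L, end = 30L)
  expect_equal(feature_length(f, 16529L), 60L)
  expect_error(feature_length(f, 16529L, circular = FALSE),
               "non-circular")
  expect_equal(feature_length(data.frame(gene = "y", start = 5L,
                                         end = 5L), 100L), 1L)
})

test_that("feature tables round-trip losslessly", {
  g <- mkuntee_annotation()
  path <- tempfile(fileext = ".tsv")
  write_feature_table(g, path)
  g2 <- read_feature_table(path, id = g$id)
  expect_equal(g2$features, g$features)
  expect_equal(g2$length, g$length)
  ## empty genome: header-only file
  g0 <- mito_genome("empty", length = 100L)
  p0 <- tempfile(fileext = ".tsv")
  write_feature_table(g0, p0)
  expect_equal(length(readLines(p0)), 1L)
})

test_that("a size/coordinate inconsistency is rejected with the gene named", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tstart\tend\tstrand\tsize",
               "cox1\t1\t99\t+\t100"), path)
  expect_error(read_feature_table(path), "cox1")
})

test_that("extract_feature_sequence returns the sense strand", {
  feats <- rbind(
    gene_feature("a", 1, 4, "H"),
    gene_feature("b", 1, 4, "L"),
    gene_feature("w", 8, 3, "H"))   # wraps the origin
  g <- mito_genome("t", feats, sequence = "AACGTTTCCG")
  expect_equal(extract_feature_sequence(g, "a"), "AACG")
  expect_equal(extract_feature_sequence(g, "b"), revcomp("AACG"))
  expect_equal(extract_feature_sequence(g, "w"), "CCGAAC")
  g2 <- mito_genome("t2", feats[1:2, ], length = 10L)
  expect_error(extract_feature_sequence(g2, "a"), "no sequence")
})

test_that("L-strand extraction equals revcomp of the H-strand extraction", {
  set.seed(42)
  for (rep in 1:10) {
    s <- random_dna(60)
    st <- sample(1:50, 1)
    en <- st + sample(3:9, 1)
    fh <- gene_feature("x", st, en, "H")
    fl <- gene_feature("x", st, en, "L")
    g <- mito_genome("t", fh, sequence = s)
    expect_equal(extract_feature_sequence(g, fl),
                 revcomp(extract_feature_sequence(g, fh)))
  }
})

test_that("GenBank records are parsed and gene names normalized", {
  gb <- c(
    "LOCUS       TEST0001               60 bp    DNA     circular VRT",
    "VERSION     TEST0001.1",
    "SOURCE      Testus fishus",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(5..22)",
    "                     /gene=\"ND6\"",
    "     tRNA            25..40",
    "                     /product=\"tRNA-Ser\"",
    "                     /anticodon=(pos:30..32,aa:Ser,seq:gct)",
    "     rRNA            41..55",
    "                     /product=\"12S ribosomal RNA\"",
    "                     /gene=\"12S\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac",
    "       51 gtacgtacgt",
    "//")
  path <- tempfile(fileext = ".gb")
  writeLines(gb, path)
  gs <- read_genbank(path)
  expect_length(gs, 1L)
  g <- gs[[1L]]
  expect_equal(g$id, "TEST0001.1")
  expect_true(g$circular)
  expect_equal(nchar(g$sequence), 60L)
  f <- g$features
  expect_equal(f$gene[f$category == "PCG"], "nad6")
  expect_equal(f$strand[f$gene == "nad6"], "L")
  expect_equal(f$gene[f$category == "tRNA"], "trnS1")  # GCT anticodon
  expect_equal(f$gene[f$category == "rRNA"], "rrnS")
  ## record with no features
  gb0 <- c("LOCUS       EMPTY001               10 bp    DNA     linear",
           "ORIGIN", "        1 acgtacgtac", "//")
  p0 <- tempfile(fileext = ".gb")
  writeLines(gb0, p0)
  expect_equal(nrow(read_genbank(p0)[[1L]]$features), 0L)
})

test_that("the canonical 13 PCG names all classify as PCG", {
  expect_equal(unname(feature_category(
    c("atp6", "atp8", "cob", "cox1", "cox2", "cox3", "nad1", "nad2",
      "nad3", "nad4", "nad4l", "nad5", "nad6"))),
    rep("PCG", 13L))
  expect_warning(normalize_gene_name("mystery_orf"), "cannot normalize")
})
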