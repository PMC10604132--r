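## ---------------------------------------------------------------------------
## Containers and I/O for annotated circular mitochondrial genomes.
##
## A mito_genome is a list with: id, species, sequence (scalar string or
## NULL), length (bp), circular (flag) and features (a data.frame with one
## row per annotated feature). Coordinates are 1-based inclusive throughout;
## end < start is permitted only for origin-spanning features on a circular
## molecule.
## ---------------------------------------------------------------------------

PCG_NAMES <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
               "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")
RRNA_NAMES <- c("rrnS", "rrnL")
FEATURE_CATEGORIES <- c("PCG", "tRNA", "rRNA", "control_region",
                        "origin_light", "other")

## Empty feature frame with the canonical column set.
empty_features <- function() {
  data.frame(gene = character(), category = character(),
             start = integer(), end = integer(), strand = character(),
             anticodon = character(), start_codon = character(),
             stop_codon = character(), stringsAsFactors = FALSE)
}

#' Assign a feature category from a gene symbol
#'
#' `trn*` is tRNA, `rrn*` is rRNA, the 13 canonical oxidative-phosphorylation
#' genes are PCG, `CR` is the control region and `OL` the light-strand
#' replication origin; anything else is "other".
#'
#' @param gene Character vector of gene symbols in the package lexicon
#'   (cox1, nad4l, trnS2, rrnL, CR, OL, ...).
#' @return Character vector of categories.
#' @export
feature_category <- function(gene) {
  out <- rep("other", length(gene))
  out[gene %in% PCG_NAMES] <- "PCG"
  out[grepl("^trn", gene)] <- "tRNA"
  out[gene %in% RRNA_NAMES] <- "rRNA"
  out[gene == "CR"] <- "control_region"
  out[gene == "OL"] <- "origin_light"
  out
}

#' Construct one gene feature
#'
#' @param gene Gene symbol (package lexicon: cox1, trnS2, rrnL, CR, OL ...).
#' @param start,end 1-based inclusive coordinates. `end < start` marks an
#'   origin-spanning feature on a circular molecule.
#' @param strand "H" (heavy, "+") or "L" (light, "-").
#' @param anticodon Optional anticodon 3-mer (tRNAs only).
#' @param start_codon,stop_codon Optional codon annotation (PCGs only);
#'   stop may be an incomplete "T" or "TA".
#' @param category Feature category; inferred from `gene` by default.
#' @return One-row data.frame.
#' @export
gene_feature <- function(gene, start, end, strand = "H",
                         anticodon = NA_character_,
                         start_codon = NA_character_,
                         stop_codon = NA_character_,
                         category = feature_category(gene)) {
  stopifnot(strand %in% c("H", "L"))
  data.frame(gene = gene, category = category,
             start = as.integer(start), end = as.integer(end),
             strand = strand, anticodon = anticodon,
             start_codon = start_codon, stop_codon = stop_codon,
             stringsAsFactors = FALSE)
}

#' Construct an annotated mitogenome
#'
#' @param id Accession or label.
#' @param features data.frame of features as built by [gene_feature()]
#'   (rows may come in any order; they are sorted by start).
#' @param sequence Optional nucleotide string over A/C/G/T/N.
#' @param length Genome length in bp. Defaults to `nchar(sequence)` when a
#'   sequence is given, else to the maximum feature end coordinate (the
#'   terminal feature of a fully annotated circular genome ends at the
#'   genome terminus).
#' @param species Free-text species name.
#' @param circular Is the molecule circular? Default TRUE.
#' @return An object of class `mito_genome`.
#' @export
mito_genome <- function(id, features = empty_features(), sequence = NULL,
                        length = NULL, species = "", circular = TRUE) {
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    check_nucleotides(sequence, allow_n = TRUE, what = "genome sequence")
    if (!is.null(length) && length != nchar(sequence))
      stop("declared length ", length, " != sequence length ",
           nchar(sequence))
    length <- nchar(sequence)
  }
  if (is.null(length)) {
    if (nrow(features) == 0L)
      stop("genome length cannot be inferred: no sequence and no features")
    length <- max(features$end, features$start)
  }
  length <- as.integer(length)
  if (nrow(features) > 0L) {
    need <- setdiff(colnames(empty_features()), colnames(features))
    for (cl in need) features[[cl]] <- NA_character_
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
    bad <- features$start < 1L | features$start > length |
      features$end < 1L | features$end > length
    if (any(bad))
      stop("feature coordinates outside [1, ", length, "]: ",
           paste(features$gene[bad], collapse = ", "))
    if (!circular && any(features$end < features$start))
      stop("end < start is only valid on a circular molecule")
    if (any(!features$strand %in% c("H", "L")))
      stop("feature strand must be 'H' or 'L'")
  }
  structure(list(id = id, species = species, sequence = sequence,
                 length = length, circular = circular, features = features),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome> ", x$id,
      if (nzchar(x$species)) paste0(" (", x$species, ")"), "\n",
      "  length:   ", x$length, " bp",
      if (x$circular) " (circular)", "\n",
      "  sequence: ", if (is.null(x$sequence)) "absent" else "present", "\n",
      "  features: ", nrow(x$features), sep = "")
  if (nrow(x$features) > 0L) {
    tab <- table(factor(x$features$category, levels = FEATURE_CATEGORIES))
    tab <- tab[tab > 0L]
    cat(" (", paste(paste0(tab, " ", names(tab)), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Feature length on a (possibly circular) genome
#'
#' For `end >= start` the length is `end - start + 1`; for an
#' origin-spanning feature on a circular genome it is
#' `(genome_length - start + 1) + end`.
#'
#' @param features data.frame with `start`/`end` columns (or a full
#'   `mito_genome`, in which case all its features are measured).
#' @param genome_length Genome length in bp; taken from the genome when a
#'   `mito_genome` is passed.
#' @param circular Is the molecule circular?
#' @return Integer vector of lengths in bp.
#' @export
#' @examples
#' feature_length(data.frame(start = 16500, end = 30), 16529)
feature_length <- function(features, genome_length = NULL, circular = TRUE) {
  if (inherits(features, "mito_genome")) {
    genome_length <- features$length
    circular <- features$circular
    features <- features$features
  }
  s <- features$start
  e <- features$end
  wrap <- e < s
  if (any(wrap) && !circular)
    stop("end < start on a non-circular genome: ",
         paste(features$gene[wrap], collapse = ", "))
  out <- ifelse(wrap, (genome_length - s + 1L) + e, e - s + 1L)
  as.integer(out)
}

#' Extract the sense-strand sequence of a feature
#'
#' H-strand features return the stored subsequence; L-strand features
#' return its reverse complement, so the result is always the
#' coding/sense sequence. Origin-spanning features concatenate the
#' sequence tail and head.
#'
#' @param g A `mito_genome` with sequence present.
#' @param feature A gene symbol (must be unique in `g`), or a one-row
#'   feature data.frame.
#' @return Nucleotide string.
#' @export
extract_feature_sequence <- function(g, feature) {
  stopifnot(inherits(g, "mito_genome"))
  if (is.null(g$sequence))
    stop("genome ", g$id, " has no sequence")
  if (is.character(feature)) {
    hit <- which(g$features$gene == feature)
    if (length(hit) != 1L)
      stop("feature '", feature, "' matches ", length(hit), " rows")
    feature <- g$features[hit, , drop = FALSE]
  }
  s <- feature$start[1L]
  e <- feature$end[1L]
  if (e >= s) {
    out <- substr(g$sequence, s, e)
  } else {
    if (!g$circular) stop("end < start on a non-circular genome")
    out <- paste0(substr(g$sequence, s, g$length), substr(g$sequence, 1L, e))
  }
  if (identical(feature$strand[1L], "L")) out <- revcomp(out)
  out
}

## ---------------------------------------------------------------------------
## Feature-table TSV (the printed-annotation format: gene / start / end /
## strand / size / start codon / stop codon / anticodon; "-" = absent).
## ---------------------------------------------------------------------------

#' Read a feature-table TSV into a mito_genome
#'
#' The table format mirrors published mitogenome annotation summaries:
#' columns `gene`, `start`, `end`, `strand` ("+" = heavy, "-" = light),
#' and optionally `size`, `start_codon`, `stop_codon`, `anticodon`, with
#' "-" (or an en-dash) marking absent cells. When a `size` column is
#' present it is validated against the coordinate span.
#'
#' @param path Path to the TSV file.
#' @param sequence Optional path to a FASTA file holding the genome
#'   sequence (first record used), or a nucleotide string.
#' @param id Genome label; defaults to the file name.
#' @param circular Is the molecule circular? Default TRUE.
#' @return A `mito_genome`.
#' @export
read_feature_table <- function(path, sequence = NULL, id = NULL,
                               circular = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  colnames(tab) <- tolower(gsub("[ ().]", "_", colnames(tab)))
  need <- c("gene", "start", "end", "strand")
  if (!all(need %in% colnames(tab)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  absent <- function(x) is.na(x) | x %in% c("-", "−", "")
  clean <- function(x) ifelse(absent(x), NA_character_, x)
  strand <- ifelse(tab$strand %in% c("+", "H"), "H",
                   ifelse(tab$strand %in% c("-", "−", "L"), "L", NA))
  if (anyNA(strand))
    stop("unrecognized strand value(s): ",
         paste(unique(tab$strand[is.na(strand)]), collapse = ", "))
  feats <- data.frame(
    gene = tab$gene,
    category = feature_category(tab$gene),
    start = as.integer(gsub(",", "", tab$start)),
    end = as.integer(gsub(",", "", tab$end)),
    strand = strand,
    anticodon = if ("anticodon" %in% colnames(tab))
      clean(tab$anticodon) else NA_character_,
    start_codon = if ("start_codon" %in% colnames(tab))
      clean(tab$start_codon) else NA_character_,
    stop_codon = if ("stop_codon" %in% colnames(tab))
      clean(tab$stop_codon) else NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(sequence) && file.exists(sequence))
    sequence <- read_fasta(sequence)[[1L]]
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  g <- mito_genome(id = id, features = feats, sequence = sequence,
                   circular = circular)
  if ("size" %in% colnames(tab)) {
    size <- as.integer(gsub(",", "", tab$size))
    got <- feature_length(g)[match(tab$gene, g$features$gene)]
    bad <- !is.na(size) & size != got
    if (any(bad))
      stop("size column disagrees with coordinates for: ",
           paste(sprintf("%s (printed %d, computed %d)",
                         tab$gene[bad], size[bad], got[bad]),
                 collapse = "; "))
  }
  g
}

#' Write a mito_genome's features as a feature-table TSV
#'
#' Round-trips losslessly through [read_feature_table()].
#'
#' @param g A `mito_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(g, path) {
  stopifnot(inherits(g, "mito_genome"))
  f <- g$features
  dash <- function(x) ifelse(is.na(x), "-", x)
  out <- data.frame(
    gene = f$gene, start = f$start, end = f$end,
    strand = ifelse(f$strand == "H", "+", "-"),
    size = feature_length(g),
    start_codon = dash(f$start_codon),
    stop_codon = dash(f$stop_codon),
    anticodon = dash(f$anticodon),
    stringsAsFactors = FALSE)
  if (nrow(f) == 0L)
    out <- out[0, c("gene", "start", "end", "strand", "size",
                    "start_codon", "stop_codon", "anticodon")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The bundled M. kuntee annotation table
#'
#' Convenience accessor for the packaged feature table of the
#' *Myripristis kuntee* (shoulderbar soldierfish) mitochondrial genome:
#' 37 features (13 protein-coding genes, 22 tRNAs, 2 rRNAs) on a
#' 16,529 bp circular molecule. No sequence is attached.
#'
#' @return A `mito_genome` (annotation only).
#' @export
#' @examples
#' g <- mkuntee_annotation()
#' table(g$features$category)
mkuntee_annotation <- function() {
  read_feature_table(
    system.file("extdata", "mkuntee_feature_table.tsv",
                package = "mitochar", mustWork = TRUE),
    id = "M_kuntee", circular = TRUE)
}

## ---------------------------------------------------------------------------
## FASTA
## ---------------------------------------------------------------------------

#' Read sequences from a FASTA file
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file (70-column wrap)
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

## ---------------------------------------------------------------------------
## GenBank flat files
## ---------------------------------------------------------------------------

## Load the editable raw-name -> canonical-name map shipped with the
## package (or a user-supplied file of the same two-column format).
load_gene_name_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gene_name_map.tsv",
                        package = "mitochar", mustWork = TRUE)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(m$canonical, toupper(m$raw))
}

## Amino-acid one/three-letter -> trn symbol; Ser/Leu resolved by anticodon.
TRNA_AA <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LYS = "K", MET = "M", PHE = "F", PRO = "P", THR = "T",
             TRP = "W", TYR = "Y", VAL = "V", SER = "S", LEU = "L")

normalize_trna_name <- function(product, anticodon = NA) {
  aa3 <- toupper(sub("^TRNA[-_ ]", "", toupper(product)))
  aa3 <- substr(aa3, 1, 3)
  aa1 <- TRNA_AA[aa3]
  if (is.na(aa1)) return(NA_character_)
  if (aa1 %in% c("S", "L")) {
    ## two isoacceptors: S1 = GCT (AGN box), S2 = TGA (TCN box);
    ## L1 = TAG (CTN box), L2 = TAA (TTR box)
    idx <- switch(toupper(as.character(anticodon)),
                  GCT = "1", TGA = "2", TAG = "1", TAA = "2", "")
    return(paste0("trn", aa1, idx))
  }
  paste0("trn", aa1)
}

#' Normalize a raw annotation gene name to the package lexicon
#'
#' ND1 becomes nad1, COX1/COI becomes cox1, CYTB becomes cob, 12S/16S
#' become rrnS/rrnL, D-loop becomes CR, tRNA products become trnX symbols
#' (Ser/Leu isoacceptors resolved by anticodon). Unmappable names are
#' kept as-is with a warning.
#'
#' @param raw Character vector of raw names/products.
#' @param anticodon Optional anticodons (for Ser/Leu disambiguation).
#' @param map Optional replacement name map (named character vector,
#'   names = upper-case raw names), e.g. from a user-edited copy of the
#'   shipped `gene_name_map.tsv`.
#' @return Character vector of normalized names.
#' @export
normalize_gene_name <- function(raw, anticodon = rep(NA, length(raw)),
                                map = load_gene_name_map()) {
  out <- character(length(raw))
  for (i in seq_along(raw)) {
    key <- toupper(gsub("[ _]", "", raw[i]))
    if (key %in% names(map)) {
      out[i] <- map[[key]]
    } else if (grepl("^TRNA", toupper(raw[i]))) {
      nm <- normalize_trna_name(raw[i], anticodon[i])
      if (is.na(nm)) {
        warning("cannot normalize tRNA name '", raw[i], "'; keeping as-is")
        nm <- raw[i]
      }
      out[i] <- nm
    } else if (raw[i] %in% c(PCG_NAMES, RRNA_NAMES, "CR", "OL") ||
               grepl("^trn", raw[i])) {
      out[i] <- raw[i]
    } else {
      warning("cannot normalize gene name '", raw[i], "'; keeping as-is")
      out[i] <- raw[i]
    }
  }
  out
}

#' Read a GenBank flat file into mito_genome objects
#'
#' A minimal reader for single- or multi-record GenBank flat files with
#' CDS / tRNA / rRNA / D-loop features. Gene names are normalized via
#' [normalize_gene_name()]; complement-strand features get strand "L".
#' Join/order locations are reduced to their overall span; `<`/`>`
#' partial-end markers are dropped.
#'
#' @param path GenBank flat-file path.
#' @param name_map Optional gene-name map (see [normalize_gene_name()]).
#' @return A list of `mito_genome` objects (one per record).
#' @export
read_genbank <- function(path, name_map = load_gene_name_map()) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//", lines)
  if (length(ends) == 0L)
    stop("malformed GenBank file (no record terminator '//'): ", path)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    rec <- lines[starts[k]:ends[k]]
    out[[k]] <- parse_genbank_record(rec, path, name_map)
  }
  out
}

parse_genbank_record <- function(rec, path, name_map) {
  locus_i <- grep("^LOCUS", rec)
  if (length(locus_i) == 0L)
    stop("malformed GenBank record (no LOCUS line) in ", path)
  locus <- strsplit(trimws(rec[locus_i[1L]]), "\\s+")[[1L]]
  id <- locus[2L]
  circular <- any(grepl("circular", rec[locus_i[1L]], ignore.case = TRUE))
  acc_i <- grep("^VERSION", rec)
  if (length(acc_i) > 0L) {
    v <- strsplit(trimws(rec[acc_i[1L]]), "\\s+")[[1L]]
    if (length(v) >= 2L) id <- v[2L]
  }
  org_i <- grep("^ {0,2}SOURCE", rec)
  species <- if (length(org_i) > 0L)
    trimws(sub("^ {0,2}SOURCE", "", rec[org_i[1L]])) else ""

  feat_i <- grep("^FEATURES", rec)
  seq_i <- grep("^ORIGIN", rec)
  feats <- empty_features()
  if (length(feat_i) > 0L) {
    stop_at <- if (length(seq_i) > 0L) seq_i[1L] - 1L else length(rec)
    fl <- rec[(feat_i[1L] + 1L):stop_at]
    feats <- parse_genbank_features(fl, path, name_map)
  }
  sequence <- NULL
  if (length(seq_i) > 0L) {
    sl <- rec[(seq_i[1L] + 1L):length(rec)]
    sl <- sl[!grepl("^//", sl)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(sl, collapse = "")))
    if (!grepl("^[ACGTN]*$", sequence))
      stop("record ", id, " contains ambiguity codes other than N")
  }
  mito_genome(id = id, features = feats, sequence = sequence,
              length = if (is.null(sequence))
                suppressWarnings(as.integer(locus[3L])) else NULL,
              species = species, circular = circular)
}

parse_genbank_features <- function(fl, path, name_map) {
  ## a new feature starts with a key at indentation 5
  key_i <- grep("^ {5}\\S", fl)
  keep_keys <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")
  feats <- empty_features()
  for (j in seq_along(key_i)) {
    i0 <- key_i[j]
    i1 <- if (j < length(key_i)) key_i[j + 1L] - 1L else length(fl)
    key <- trimws(substr(fl[i0], 1, 20))
    if (!key %in% keep_keys) next
    block <- fl[i0:i1]
    loc <- sub("^ {5}\\S+\\s+", "", block[1L])
    ## continuation lines of the location (no '=' qualifier yet)
    ii <- 2L
    while (ii <= length(block) && !grepl("^\\s+/", block[ii])) {
      loc <- paste0(loc, trimws(block[ii]))
      ii <- ii + 1L
    }
    comp <- grepl("complement", loc)
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
    if (length(nums) < 1L)
      stop("cannot parse feature location '", loc, "' in ", path)
    start <- min(nums); end <- max(nums)
    qual <- function(name) {
      m <- regmatches(block,
                      regexpr(paste0("/", name, '="?[^"]*"?'), block))
      if (length(m) == 0L) return(NA_character_)
      gsub(paste0('^/', name, '="?|"$'), "", m[1L])
    }
    raw <- qual("gene")
    if (is.na(raw)) raw <- qual("product")
    if (is.na(raw)) raw <- if (key == "D-loop") "D-loop" else key
    anticodon <- NA_character_
    ac <- grep("/anticodon", block, value = TRUE)
    if (length(ac) > 0L) {
      m <- regmatches(ac[1L], regexpr("seq:[A-Za-z]+", ac[1L]))
      if (length(m) > 0L) anticodon <- toupper(sub("seq:", "", m))
    }
    nm <- normalize_gene_name(raw, anticodon, map = name_map)
    category <- switch(key,
                       CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       `D-loop` = "control_region", "other")
    if (!nm %in% PCG_NAMES && category == "PCG") category <- "other"
    if (nm == "CR") category <- "control_region"
    if (nm == "OL") category <- "origin_light"
    feats <- rbind(feats, gene_feature(
      gene = nm, start = start, end = end,
      strand = if (comp) "L" else "H",
      anticodon = anticodon, category = category))
  }
  feats
}
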