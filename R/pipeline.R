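## ---------------------------------------------------------------------------
## End-to-end orchestration: run every analysis stage over a set of
## genomes and emit one TSV (or Newick) per stage plus a general-features
## summary. Stage failures are recorded and later independent stages
## still run.
## ---------------------------------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-genome general-features summary
#'
#' Length, gene counts by category, strand inventory, and start/stop
#' codon classes of the PCGs (from annotation metadata when present,
#' else from the sequence).
#'
#' @param genomes Named list of `mito_genome` objects.
#' @return data.frame, one row per genome.
#' @export
general_features <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    f <- g$features
    pcg <- f[f$category == "PCG", , drop = FALSE]
    starts <- pcg$start_codon
    stops <- pcg$stop_codon
    if ((all(is.na(starts)) || all(is.na(stops))) &&
        !is.null(g$sequence) && nrow(pcg) > 0L) {
      cls <- vapply(seq_len(nrow(pcg)), function(i) {
        cc <- suppressWarnings(split_codons(
          extract_feature_sequence(g, pcg[i, , drop = FALSE]),
          pcg$gene[i]))
        classify_start_stop(cc)
      }, c(start = "", stop = ""))
      starts <- cls["start", ]
      stops <- cls["stop", ]
    }
    stops_class <- ifelse(!is.na(stops) & stops %in% c("T", "TA"),
                          "incomplete", stops)
    data.frame(
      id = g$id, length_bp = g$length,
      n_features = nrow(f),
      n_pcg = sum(f$category == "PCG"),
      n_trna = sum(f$category == "tRNA"),
      n_rrna = sum(f$category == "rRNA"),
      n_trna_L = sum(f$category == "tRNA" & f$strand == "L"),
      n_pcg_L = sum(f$category == "PCG" & f$strand == "L"),
      n_start_ATG = sum(starts == "ATG", na.rm = TRUE),
      n_start_GTG = sum(starts == "GTG", na.rm = TRUE),
      n_stop_TAA = sum(stops_class == "TAA", na.rm = TRUE),
      n_stop_TAG = sum(stops_class == "TAG", na.rm = TRUE),
      n_stop_AGA = sum(stops_class == "AGA", na.rm = TRUE),
      n_stop_AGG = sum(stops_class == "AGG", na.rm = TRUE),
      n_stop_incomplete = sum(stops_class == "incomplete", na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes composition, codon-usage, architecture, conserved-block,
#' stem-loop, phylogeny and selection stages over the input genomes and
#' writes one report per stage under `out_dir`. Stages that need a
#' sequence are skipped with a notice for annotation-only genomes; a
#' failing stage is recorded and the rest still run.
#'
#' @param genomes Named list of `mito_genome` objects (or a single one).
#' @param out_dir Output directory (created if missing).
#' @param stages Character vector of stages to run; default all.
#' @param boot_reps Bootstrap replicates for the phylogeny stage
#'   (default 100).
#' @param alpha Significance level for the selection stage.
#' @param model Distance model for tree building (default "JC69").
#' @param seed Integer seed for the stochastic stages.
#' @param outgroup Optional outgroup taxon labels (rooting annotation
#'   in the written tree).
#' @param csb_params List of [detect_csbs()] arguments.
#' @return Invisibly, a list with per-stage results and a `status`
#'   data.frame; non-TRUE status rows carry the error/skip message.
#' @export
run_pipeline <- function(genomes, out_dir, stages = c(
  "summary", "composition", "codons", "architecture", "csb",
  "hairpin", "phylo", "selection"),
  boot_reps = 100L, alpha = 0.05, model = "JC69", seed = 1L,
  outgroup = NULL, csb_params = list()) {
  if (inherits(genomes, "mito_genome")) genomes <- list(genomes)
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$id, "")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  status <- list()
  note <- function(stage, ok, msg = "") {
    status[[stage]] <<- data.frame(stage = stage, ok = ok, message = msg,
                                   stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% stages) return()
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      note(stage, FALSE, conditionMessage(res))
    } else {
      results[[stage]] <<- res
      note(stage, TRUE)
    }
  }
  with_seq <- Filter(function(g) !is.null(g$sequence), genomes)

  run_stage("summary", function() {
    out <- general_features(genomes)
    write_tsv(out, file.path(out_dir, "summary.tsv"))
    out
  })
  run_stage("composition", function() {
    if (length(with_seq) == 0L) stop("no genome has a sequence")
    out <- do.call(rbind, lapply(names(with_seq), function(nm)
      cbind(genome = nm, format_composition(
        suppressWarnings(composition_report(with_seq[[nm]]))))))
    write_tsv(out, file.path(out_dir, "composition.tsv"))
    out
  })
  run_stage("codons", function() {
    if (length(with_seq) == 0L) stop("no genome has a sequence")
    tabs <- lapply(with_seq, function(g)
      rscu(suppressWarnings(genome_codon_counts(g))))
    long <- do.call(rbind, lapply(names(tabs), function(nm)
      cbind(genome = nm, codon_usage_report(tabs[[nm]]))))
    write_tsv(long, file.path(out_dir, "codon_usage.tsv"))
    mat <- do.call(cbind, lapply(tabs, function(t) t$rscu))
    write_tsv(cbind(codon = rownames(mat), as.data.frame(mat)),
              file.path(out_dir, "rscu_matrix.tsv"))
    tabs
  })
  run_stage("architecture", function() {
    ov <- do.call(rbind, lapply(names(genomes), function(nm)
      cbind(genome = nm, find_overlaps(genomes[[nm]]))))
    sps <- do.call(rbind, lapply(names(genomes), function(nm)
      cbind(genome = nm, find_spacers(genomes[[nm]]))))
    crs <- do.call(rbind, lapply(names(genomes), function(nm)
      cbind(genome = nm, suppressWarnings(
        locate_control_region(genomes[[nm]])))))
    arr <- arrangement_table(genomes)
    write_tsv(ov, file.path(out_dir, "overlaps.tsv"))
    write_tsv(sps, file.path(out_dir, "spacers.tsv"))
    write_tsv(crs, file.path(out_dir, "control_region.tsv"))
    write_tsv(arr, file.path(out_dir, "arrangement.tsv"))
    list(overlaps = ov, spacers = sps, control_region = crs,
         arrangement = arr)
  })
  run_stage("csb", function() {
    if (length(with_seq) < 3L)
      stop("conserved-block detection needs >= 3 genomes with sequence")
    crs <- vapply(with_seq, function(g) {
      cr <- suppressWarnings(locate_control_region(g))
      if (cr$end >= cr$start) substr(g$sequence, cr$start, cr$end)
      else paste0(substr(g$sequence, cr$start, g$length),
                  substr(g$sequence, 1L, cr$end))
    }, "")
    aln <- if (length(unique(nchar(crs))) == 1L) mito_alignment(crs)
    else progressive_align(crs)
    blocks <- do.call(detect_csbs, c(list(aln), csb_params))
    write_tsv(blocks, file.path(out_dir, "csb.tsv"))
    write_tsv(block_composition_table(blocks),
              file.path(out_dir, "csb_composition.tsv"))
    blocks
  })
  run_stage("hairpin", function() {
    if (length(with_seq) == 0L) stop("no genome has a sequence")
    rows <- lapply(names(with_seq), function(nm) {
      g <- with_seq[[nm]]
      sp <- find_spacers(g)
      cand <- sp[sp$gene_a == "trnN" & sp$gene_b == "trnC", ,
                 drop = FALSE]
      if (nrow(cand) == 0L) return(NULL)
      region <- substr(g$sequence, cand$start[1L], cand$end[1L])
      hp <- find_stem_loops(region)
      if (nrow(hp) == 0L) return(NULL)
      cbind(genome = nm, region_start = cand$start[1L],
            hp[1L, , drop = FALSE])
    })
    out <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(out)) stop("no stem-loop candidate found")
    write_tsv(out, file.path(out_dir, "hairpin.tsv"))
    out
  })
  gene_alignments <- function() {
    pcg_names <- Reduce(intersect, lapply(with_seq, function(g)
      g$features$gene[g$features$category == "PCG"]))
    alns <- lapply(stats::setNames(pcg_names, pcg_names), function(gn) {
      seqs <- vapply(with_seq, function(g)
        extract_feature_sequence(g, gn), "")
      if (length(unique(nchar(seqs))) == 1L) mito_alignment(seqs)
      else progressive_align(seqs)
    })
    alns
  }
  run_stage("phylo", function() {
    if (length(with_seq) < 4L) stop("phylogeny needs >= 4 genomes")
    alns <- gene_alignments()
    trimmed <- lapply(alns, function(a)
      tryCatch(trim_blocks(a), error = function(e) a))
    sup <- concatenate_alignments(trimmed)
    tree <- bootstrap_support(sup, model = model, n_reps = boot_reps,
                              seed = seed)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    part <- sup$partition
    writeLines(sprintf("%s = %d-%d", part$gene, part$start, part$end),
               file.path(out_dir, "partition.txt"))
    list(tree = tree, supermatrix = sup)
  })
  run_stage("selection", function() {
    if (length(with_seq) < 3L) stop("selection needs >= 3 genomes")
    alns <- gene_alignments()
    codon_alns <- lapply(names(alns), function(gn) {
      a <- alns[[gn]]
      ## trim to full codons, drop terminal (possibly incomplete) stop
      cds <- vapply(with_seq, function(g)
        extract_feature_sequence(g, gn), "")
      prot <- vapply(names(cds), function(tx) {
        cc <- suppressWarnings(split_codons(cds[[tx]], tx))
        codons <- cc$codons
        gc2 <- genetic_code("2")
        if (nchar(cc$incomplete_tail) == 0L &&
            gc2[codons[length(codons)]] == "*")
          codons <- codons[-length(codons)]
        paste(translate_codons(codons), collapse = "")
      }, "")
      paln <- if (length(unique(nchar(prot))) == 1L)
        mito_alignment(prot) else progressive_align(prot)
      ca <- backtranslate(paln, cds)
      ca$genes <- rep(gn, ncol(ca$codons))
      ca
    })
    big <- codon_alns[[1L]]
    if (length(codon_alns) > 1L) {
      mats <- lapply(codon_alns, function(x)
        x$codons[codon_aln_taxa(codon_alns[[1L]]), , drop = FALSE])
      big <- codon_alignment(do.call(cbind, mats),
                             genes = unlist(lapply(codon_alns,
                                                   function(x) x$genes)))
    }
    tree <- if (!is.null(results$phylo)) results$phylo$tree
    else {
      nt <- mito_alignment(vapply(
        stats::setNames(codon_aln_taxa(big), codon_aln_taxa(big)),
        function(tx) paste(big$codons[tx, ], collapse = ""), ""))
      nt$seqs <- gsub("---", "NNN", nt$seqs, fixed = TRUE)
      suppressWarnings(nj_tree(distance_matrix(nt, model)))
    }
    sites <- slac(big, tree, alpha = alpha)
    write_tsv(sites, file.path(out_dir, "selection_sites.tsv"))
    summ <- classify_summary(sites, alpha = alpha)
    write_tsv(summ$per_gene, file.path(out_dir, "selection_summary.tsv"))
    list(sites = sites, summary = summ)
  })
  st <- do.call(rbind, status)
  rownames(st) <- NULL
  write_tsv(st, file.path(out_dir, "pipeline_status.tsv"))
  invisible(c(results, list(status = st)))
}
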