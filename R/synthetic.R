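## ---------------------------------------------------------------------------
## Synthetic mitogenomes with known truth.
##
## make_genome() builds a fully annotated circular genome on the typical
## vertebrate 37-gene plan (the bundled M. kuntee-style template):
## in-frame stop-free PCGs with the annotated start/stop classes
## (including the three incomplete-stop genes), the three conserved
## PCG-PCG overlaps realized with their motifs, a control region
## carrying five seeded conserved sequence blocks, and a stem-loop
## replication origin inside the WANCY tRNA cluster. evolve_codons()
## runs an MG94-style codon substitution simulation along a tree with a
## full substitution log; make_study_set() combines both into a
## multi-species data set with a known two-clade ingroup phylogeny.
## ---------------------------------------------------------------------------

#' Default control-region conserved-block motifs
#'
#' Five 20-nt motifs whose base compositions echo the distinct
#' signatures of control-region CSBs: I is T/A-rich, II is A/T/C, III
#' is T/C-rich, IV is C-rich (70% C), V is A/C-rich.
#'
#' @return Named character vector of 5 motifs.
#' @export
default_csb_motifs <- function() {
  c("CSB-I"   = "TTAATATTTGATTACTTTAA",
    "CSB-II"  = "ACTACATCCTAACCATCAAT",
    "CSB-III" = "TCCTTTCTTGCTTTCCTTCT",
    "CSB-IV"  = "CCACCTCCCGCCCACCCTAC",
    "CSB-V"   = "ACCAAACACCAAACCAACAA")
}

#' Default PCG-overlap motifs
#'
#' The three conserved overlap motifs of the holocentrid-type
#' arrangement, keyed by gene pair. Motif letters are reconciled with
#' the overlapping genes' reading frames at generation time (annotated
#' start/stop codons take precedence over motif letters where the two
#' conflict).
#'
#' @return Named character vector keyed "geneA:geneB".
#' @export
default_overlap_motifs <- function() {
  c("atp8:atp6" = "AGCTTCTTCG",
    "nad4l:nad4" = "ATGCTAA",
    "nad5:nad6" = "CCTAA")
}

#' Specification of a synthetic mitogenome
#'
#' @param at_content Target whole-genome A+T fraction (default 0.55;
#'   the clade's observed range is roughly 0.53-0.57).
#' @param at_skew,gc_skew Target whole-genome skews on the H strand
#'   (defaults 0.05 and -0.25, typical of fish mitogenomes).
#' @param cr_length Control-region length in bp, in [838, 960]
#'   (default 862, the template's trnP-trnF gap).
#' @param length_target Optional total genome length; when given,
#'   `cr_length` is derived from it (the control region absorbs all
#'   length variation, as in the real genomes).
#' @param ol_stem_gc Number of G-C pairs in the replication-origin
#'   stem, 7 or 8 (default 8).
#' @param csb_motifs Named character vector of 5 conserved-block motifs
#'   seeded into the control region.
#' @param overlap_motifs Named character vector of overlap motifs keyed
#'   "geneA:geneB" (pairs must be overlapping in the template).
#' @param codon_weights Optional named numeric of per-codon sampling
#'   weight multipliers (e.g. to bias usage toward leucine codons).
#' @param seed Integer seed driving all randomness of the generator.
#' @return Object of class `genome_spec`.
#' @export
genome_spec <- function(at_content = 0.55, at_skew = 0.05,
                        gc_skew = -0.25, cr_length = 862L,
                        length_target = NULL, ol_stem_gc = 8L,
                        csb_motifs = default_csb_motifs(),
                        overlap_motifs = default_overlap_motifs(),
                        codon_weights = NULL, seed = 1L) {
  template <- mkuntee_annotation()
  base_cr <- 862L
  if (!is.null(length_target))
    cr_length <- base_cr + (as.integer(length_target) - template$length)
  cr_length <- as.integer(cr_length)
  if (cr_length < 838L || cr_length > 960L)
    stop("cr_length ", cr_length, " outside the supported [838, 960] bp")
  if (!ol_stem_gc %in% c(7L, 8L))
    stop("ol_stem_gc must be 7 or 8")
  if (length(csb_motifs) != 5L)
    stop("need exactly 5 CSB motifs")
  if (at_content <= 0 || at_content >= 1) stop("at_content in (0,1)")
  structure(list(at_content = at_content, at_skew = at_skew,
                 gc_skew = gc_skew, cr_length = cr_length,
                 ol_stem_gc = as.integer(ol_stem_gc),
                 csb_motifs = csb_motifs,
                 overlap_motifs = overlap_motifs,
                 codon_weights = codon_weights,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

## Base sampling probabilities (A, C, G, T) from content/skew targets.
base_probs <- function(at, at_skew, gc_skew) {
  gc <- 1 - at
  p <- c(A = at / 2 * (1 + at_skew), C = gc / 2 * (1 - gc_skew),
         G = gc / 2 * (1 + gc_skew), T = at / 2 * (1 - at_skew))
  if (any(p < 0)) stop("infeasible composition/skew targets")
  p / sum(p)
}

## Codon sampling probabilities over sense codons.
codon_probs <- function(pbase, code_id = "2", weights = NULL) {
  sense <- sense_codons(code_id)
  chars <- strsplit(sense, "", fixed = TRUE)
  p <- vapply(chars, function(ch) prod(pbase[ch]), 0)
  names(p) <- sense
  if (!is.null(weights)) {
    w <- weights[names(p)]
    w[is.na(w)] <- 1
    p <- p * w
  }
  p / sum(p)
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Generate a synthetic annotated mitogenome
#'
#' See [genome_spec()] for the tunable targets. The gene plan is the
#' bundled 37-gene template; changing `cr_length` shifts everything
#' downstream of the control region. All PCGs are valid stop-free ORFs
#' under the vertebrate mitochondrial code with the template's
#' annotated start/stop classes (cox2, nad4 and cob end in the
#' incomplete stop "T"); the three PCG-PCG overlaps carry their motifs
#' (reading-frame requirements take precedence over motif letters at
#' conflicting positions); the control region carries the five CSB
#' motifs at randomized offsets; the trnN-trnC gap carries a stem-loop
#' with the requested number of G-C pairs. Composition is polished to
#' the targets using the unconstrained positions.
#'
#' @param spec A `genome_spec`.
#' @param id Genome label (default "synthetic").
#' @return A `mito_genome` with attributes `forced` (logical per
#'   position: TRUE where content is structurally constrained),
#'   `cr_interval`, `ol_interval`, `csb_offsets`.
#' @export
#' @examples
#' g <- make_genome(genome_spec(seed = 42))
#' find_overlaps(g)[find_overlaps(g)$length >= 5, 1:3]
make_genome <- function(spec = genome_spec(), id = "synthetic") {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  template <- mkuntee_annotation()
  feats <- template$features
  delta <- spec$cr_length - 862L
  if (delta != 0L) {
    shift <- feats$start >= 11054L   # trnF onward in template coords
    feats$start[shift] <- feats$start[shift] + delta
    feats$end[shift] <- feats$end[shift] + delta
  }
  L <- max(feats$end)
  seqv <- rep(NA_character_, L)
  forced <- logical(L)
  code_id <- "2"
  gc_tab <- genetic_code(code_id)

  put_h <- function(at, str, force = TRUE) {
    ch <- seq_chars(str)
    idx <- at:(at + length(ch) - 1L)
    seqv[idx] <<- ch
    if (force) forced[idx] <<- TRUE
  }
  ## sense-position k of feature row -> H coordinate
  sense_to_h <- function(row, k) {
    if (row$strand == "H") row$start + k - 1L else row$end - k + 1L
  }
  get_sense <- function(row, k) {
    h <- sense_to_h(row, k)
    ch <- seqv[h]
    if (row$strand == "L") ch <- unname(COMP[ch])
    ch
  }
  put_sense <- function(row, k, str, force = TRUE) {
    ch <- seq_chars(str)
    for (t in seq_along(ch)) {
      h <- sense_to_h(row, k + t - 1L)
      seqv[h] <<- if (row$strand == "L") unname(COMP[ch[t]]) else ch[t]
      if (force) forced[h] <<- TRUE
    }
  }
  frow <- function(gene) feats[feats$gene == gene, , drop = FALSE]

  ## 1. overlap motifs (H frame)
  for (key in names(spec$overlap_motifs)) {
    pair <- strsplit(key, ":", fixed = TRUE)[[1L]]
    a <- frow(pair[1L]); b <- frow(pair[2L])
    if (nrow(a) != 1L || nrow(b) != 1L)
      stop("overlap pair not in template: ", key)
    lo <- max(a$start, b$start); hi <- min(a$end, b$end)
    if (lo > hi) stop("genes ", key, " do not overlap in the template")
    motif <- spec$overlap_motifs[[key]]
    if (nchar(motif) != hi - lo + 1L)
      stop("motif for ", key, " has length ", nchar(motif),
           " but the overlap is ", hi - lo + 1L, " bp")
    put_h(lo, motif)
  }

  ## 2. start and stop codons / incomplete tails of every PCG
  pcg <- feats[feats$category == "PCG", , drop = FALSE]
  sizes <- feature_length(pcg, L)
  for (i in seq_len(nrow(pcg))) {
    row <- pcg[i, , drop = FALSE]
    size <- sizes[i]
    put_sense(row, 1L, row$start_codon)
    stopc <- row$stop_codon
    if (stopc %in% c("TAA", "TAG", "AGA", "AGG")) {
      put_sense(row, size - 2L, stopc)
    } else {
      ## incomplete stop: the trailing 1-2 nt
      put_sense(row, size - nchar(stopc) + 1L, stopc)
    }
  }

  ## 3. fill PCG codons under the fixed-position constraints
  pb <- base_probs(spec$at_content, spec$at_skew, spec$gc_skew)
  cp_main <- codon_probs(pb, code_id, spec$codon_weights)
  ## nad6's sense strand mirrors the genome skews (T over A, G over C)
  pb_flip <- base_probs(spec$at_content, -spec$at_skew, -spec$gc_skew)
  cp_nad6 <- codon_probs(pb_flip, code_id, spec$codon_weights)
  sense <- names(cp_main)
  sense_chars <- strsplit(sense, "", fixed = TRUE)
  for (i in seq_len(nrow(pcg))) {
    row <- pcg[i, , drop = FALSE]
    size <- sizes[i]
    n_cod <- size %/% 3L
    cp <- if (row$gene == "nad6") cp_nad6 else cp_main
    for (ci in seq_len(n_cod)) {
      k <- 3L * ci - 2L
      fixed <- vapply(0:2, function(t) get_sense(row, k + t), "")
      if (!anyNA(fixed)) next               # fully determined
      ok <- vapply(sense_chars, function(ch) {
        all(is.na(fixed) | fixed == ch)
      }, TRUE)
      if (!any(ok))
        stop("no sense codon fits constraints in ", row$gene,
             " codon ", ci)
      pick <- sample(sense[ok], 1L, prob = cp[ok])
      ch <- seq_chars(pick)
      for (t in 0:2) {
        if (is.na(fixed[t + 1L]))
          put_sense(row, k + t, ch[t + 1L], force = FALSE)
      }
    }
  }

  ## 4. control region: CSB motifs at randomized offsets over background
  sp <- find_spacers(mito_genome("tmp", feats, length = L))
  cr <- sp[which.max(sp$length), , drop = FALSE]
  cr_pos <- cr$start:cr$end
  zone <- length(cr_pos) %/% 5L
  csb_offsets <- integer(5L)
  for (m in seq_len(5L)) {
    motif <- spec$csb_motifs[[m]]
    lo <- 10L
    hi <- zone - nchar(motif) - 10L
    off <- if (hi > lo) sample(lo:hi, 1L) else lo
    at <- cr$start + (m - 1L) * zone + off
    put_h(at, motif)
    csb_offsets[m] <- at
  }

  ## 5. replication-origin stem-loop in the trnN-trnC gap
  ol <- sp[sp$gene_a == "trnN" & sp$gene_b == "trnC", , drop = FALSE]
  if (nrow(ol) != 1L) stop("template has no trnN-trnC gap")
  gap <- ol$length
  stem <- 12L
  loop_len <- gap - 2L * stem
  if (loop_len < 3L) { stem <- (gap - 3L) %/% 2L; loop_len <- gap - 2L * stem }
  gc_pos <- sample(seq_len(stem), spec$ol_stem_gc)
  arm5 <- character(stem)
  arm5[gc_pos] <- sample(c("G", "C"), spec$ol_stem_gc, replace = TRUE)
  arm5[-gc_pos] <- sample(c("A", "T"), stem - spec$ol_stem_gc,
                          replace = TRUE)
  arm5 <- paste(arm5, collapse = "")
  loop <- paste(sample(c("A", "C", "G", "T"), loop_len, replace = TRUE,
                       prob = c(0.4, 0.35, 0.2, 0.05)), collapse = "")
  hair <- paste0(arm5, loop, revcomp(arm5))
  put_h(ol$start, hair)

  ## 6. composition polishing over the remaining free positions
  free <- which(is.na(seqv))
  tgt <- round(base_probs(spec$at_content, spec$at_skew, spec$gc_skew) * L)
  have <- c(A = sum(seqv == "A", na.rm = TRUE),
            C = sum(seqv == "C", na.rm = TRUE),
            G = sum(seqv == "G", na.rm = TRUE),
            T = sum(seqv == "T", na.rm = TRUE))
  need <- pmax(tgt[names(have)] - have, 0)
  if (sum(need) == 0) need <- tgt[names(have)]
  need <- round(need / sum(need) * length(free))
  while (sum(need) < length(free)) need[which.max(need)] <-
    need[which.max(need)] + 1L
  while (sum(need) > length(free)) need[which.max(need)] <-
    need[which.max(need)] - 1L
  fill <- sample(rep(names(need), times = need))
  seqv[free] <- fill

  sequence <- paste(seqv, collapse = "")
  g <- mito_genome(id = id, features = feats, sequence = sequence,
                   species = "synthetic", circular = TRUE)
  ## sanity: every PCG is a clean ORF
  for (i in seq_len(nrow(pcg))) {
    cds <- extract_feature_sequence(g, pcg[i, , drop = FALSE])
    cc <- withCallingHandlers(
      split_codons(cds, pcg$gene[i], code_id),
      warning = function(w) stop("generator produced an internal stop in ",
                                 pcg$gene[i], ": ", conditionMessage(w)))
  }
  at_got <- base_stats(sequence)$at_percent
  if (abs(at_got - 100 * spec$at_content) > 0.5)
    warning("whole-genome A+T ", round(at_got, 2),
            "% misses the target by more than 0.5 points")
  attr(g, "forced") <- forced
  attr(g, "cr_interval") <- c(cr$start, cr$end)
  attr(g, "ol_interval") <- c(ol$start, ol$end)
  attr(g, "csb_offsets") <- csb_offsets
  attr(g, "spec") <- spec
  g
}

## ---------------------------------------------------------------------------
## Codon-level sequence evolution
## ---------------------------------------------------------------------------

## Neighbor structure of the sense codons: for each codon, the indices
## of its single-nucleotide sense neighbors plus transition and
## synonymy flags, and the normalization constant making branch lengths
## read as expected substitutions per codon site at omega = 1.
codon_neighbors <- function(code_id = "2", kappa = 2) {
  sense <- sense_codons(code_id)
  gc <- genetic_code(code_id)
  chars <- strsplit(sense, "", fixed = TRUE)
  nb <- vector("list", length(sense))
  for (i in seq_along(sense)) {
    js <- integer(0); ts <- logical(0); syn <- logical(0)
    for (j in seq_along(sense)) {
      if (i == j) next
      d <- which(chars[[i]] != chars[[j]])
      if (length(d) != 1L) next
      js <- c(js, j)
      ts <- c(ts, is_transition(chars[[i]][d], chars[[j]][d]))
      syn <- c(syn, gc[sense[i]] == gc[sense[j]])
    }
    w <- ifelse(ts, kappa, 1)
    nb[[i]] <- list(j = js, w = w, syn = syn)
  }
  z <- mean(vapply(nb, function(x) sum(x$w), 0))
  list(sense = sense, nb = nb, z = z)
}

#' Simulate codon evolution along a tree
#'
#' MG94-style continuous-time simulation: the rate of a
#' single-nucleotide codon change is proportional to `kappa` for
#' transitions (1 for transversions), multiplied by the site's omega
#' when nonsynonymous; changes into stop codons have rate zero. Rates
#' are normalized so a branch length of 1 equals one expected
#' substitution per codon site at omega = 1 under uniform codon
#' frequencies. No indels are simulated.
#'
#' @param root_codons Character vector of sense codons at the root.
#' @param tree `ape::phylo` with branch lengths.
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param omega Scalar or per-site vector of dN/dS values (>= 0).
#' @param frozen Optional logical per-site mask; frozen sites never
#'   change.
#' @inheritParams genetic_code
#' @param seed Optional integer seed.
#' @return list(alignment = `codon_aln` of the tips, node_states =
#'   codon matrix (rows = all node numbers), log = data.frame(branch =
#'   child node, site, from, to, syn) of every substitution event).
#' @export
evolve_codons <- function(root_codons, tree, kappa = 2, omega = 1,
                          frozen = NULL, code_id = "2", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_sites <- length(root_codons)
  if (length(omega) == 1L) omega <- rep(omega, n_sites)
  stopifnot(length(omega) == n_sites, all(omega >= 0))
  if (is.null(frozen)) frozen <- rep(FALSE, n_sites)
  cn <- codon_neighbors(code_id, kappa)
  state0 <- match(root_codons, cn$sense)
  if (anyNA(state0))
    stop("root contains non-sense codons: ",
         paste(unique(root_codons[is.na(state0)]), collapse = ", "))
  ts <- tree_structure(tree)
  ntip <- ts$ntip
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nrow = nnode, ncol = n_sites)
  states[ts$root, ] <- state0
  child_edge <- match(seq_len(nnode), tree$edge[, 2L])
  log_rows <- list()
  for (v in rev(ts$postorder)) {           # preorder: parents first
    if (v == ts$root) next
    t_branch <- tree$edge.length[child_edge[v]]
    parent <- tree$edge[child_edge[v], 1L]
    cur <- states[parent, ]
    for (s in seq_len(n_sites)) {
      if (frozen[s]) next
      st <- cur[s]
      t_rem <- t_branch
      repeat {
        nbs <- cn$nb[[st]]
        rate_w <- nbs$w * ifelse(nbs$syn, 1, omega[s])
        tot <- sum(rate_w) / cn$z
        if (tot <= 0) break
        wait <- stats::rexp(1L, tot)
        if (wait > t_rem) break
        t_rem <- t_rem - wait
        pick <- sample.int(length(nbs$j), 1L, prob = rate_w)
        log_rows[[length(log_rows) + 1L]] <- c(
          branch = v, site = s, from = st, to = nbs$j[pick],
          syn = as.integer(nbs$syn[pick]))
        st <- nbs$j[pick]
      }
      cur[s] <- st
    }
    states[v, ] <- cur
  }
  codons <- matrix(cn$sense[states], nrow = nnode)
  tips <- codons[seq_len(ntip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  rownames(codons) <- as.character(seq_len(nnode))
  log_df <- if (length(log_rows) == 0L)
    data.frame(branch = integer(), site = integer(), from = character(),
               to = character(), syn = logical(),
               stringsAsFactors = FALSE)
  else {
    lm <- do.call(rbind, log_rows)
    data.frame(branch = lm[, "branch"], site = lm[, "site"],
               from = cn$sense[lm[, "from"]], to = cn$sense[lm[, "to"]],
               syn = lm[, "syn"] == 1L, stringsAsFactors = FALSE)
  }
  list(alignment = codon_alignment(tips, code_id = code_id),
       node_states = codons, log = log_df)
}

## ---------------------------------------------------------------------------
## Multi-species study set
## ---------------------------------------------------------------------------

## Caterpillar newick fragment over labels with given tip/internal
## branch lengths.
caterpillar <- function(labels, tip_len, int_len) {
  if (length(labels) == 1L)
    return(paste0(labels, ":", tip_len))
  cur <- paste0("(", labels[1L], ":", tip_len, ",", labels[2L], ":",
                tip_len, ")")
  for (k in seq_along(labels)[-(1:2)])
    cur <- paste0("(", cur, ":", int_len, ",", labels[k], ":",
                  tip_len, ")")
  paste0(cur, ":", int_len)
}

#' Generate a multi-species study set with a known phylogeny
#'
#' An ancestral genome from [make_genome()] is evolved gene-by-gene
#' along a known tree whose ingroup splits into two reciprocally
#' monophyletic clades, each containing two "genera" (mirroring a
#' squirrelfish/soldierfish-type two-subfamily structure), plus an
#' outgroup. PCGs evolve under [evolve_codons()] with per-gene omega
#' (structurally constrained codons - annotated starts/stops and
#' overlap joints - are held fixed); control-region background columns
#' outside the seeded CSB motifs are highly variable (independent
#' per-taxon resampling); tRNAs, rRNAs and the replication origin stay
#' conserved.
#'
#' @param n_ingroup Number of ingroup taxa (>= 4, default 14).
#' @param n_outgroup Number of outgroup taxa (default 3).
#' @param seed Integer seed (default 1).
#' @param spec `genome_spec` for the ancestor (seed defaults to `seed`).
#' @param omega Per-gene dN/dS, scalar or named vector (default 0.1,
#'   strong purifying selection as in mitochondrial PCGs).
#' @param kappa Transition/transversion ratio (default 2).
#' @param branch_lengths Named list: clade (ingroup clade stems,
#'   default 0.15), within (intra-clade internals, 0.04), tip
#'   (terminal, 0.05), og_stem (outgroup stem, 0.25), og_tip (outgroup
#'   terminals, 0.08); units are expected substitutions per codon site
#'   at omega = 1.
#' @param cr_divergence Per-position substitution probability of the
#'   control-region background (default 0.3).
#' @return list(genomes = named list of `mito_genome`, tree = true
#'   `phylo`, clades = list(A =, B =, outgroup =) of taxon labels,
#'   omega = named per-gene vector, gene_data = per-gene list with the
#'   codon alignment (all taxa), node_states, substitution log, frozen
#'   mask, ancestor = the ancestral genome).
#' @export
make_study_set <- function(n_ingroup = 14L, n_outgroup = 3L, seed = 1L,
                           spec = NULL, omega = 0.1, kappa = 2,
                           branch_lengths = list(clade = 0.15,
                                                 within = 0.04,
                                                 tip = 0.05,
                                                 og_stem = 0.25,
                                                 og_tip = 0.08),
                           cr_divergence = 0.3) {
  if (n_ingroup < 4L) stop("n_ingroup must be >= 4")
  if (n_outgroup < 1L) stop("n_outgroup must be >= 1")
  if (is.null(spec)) spec <- genome_spec(seed = seed)
  bl <- branch_lengths
  ## taxon layout: clade A = genera A1/A2, clade B = genera B1/B2
  nA <- max(2L, as.integer(floor(n_ingroup / 2)) - 1L)
  nB <- n_ingroup - nA
  split2 <- function(n) c(n - max(1L, round(n / 5)), max(1L, round(n / 5)))
  sA <- split2(nA); sB <- split2(nB)
  taxa_A1 <- sprintf("cladeA_g1_sp%d", seq_len(sA[1L]))
  taxa_A2 <- sprintf("cladeA_g2_sp%d", seq_len(sA[2L]))
  taxa_B1 <- sprintf("cladeB_g1_sp%d", seq_len(sB[1L]))
  taxa_B2 <- sprintf("cladeB_g2_sp%d", seq_len(sB[2L]))
  taxa_out <- sprintf("outgroup_sp%d", seq_len(n_outgroup))
  subtree <- function(tx) base::sub(":[0-9.]+$", "",
                          caterpillar(tx, bl$tip, bl$within))
  cladeA <- paste0("(", subtree(taxa_A1), ":", bl$within, ",",
                   subtree(taxa_A2), ":", bl$within, ")")
  cladeB <- paste0("(", subtree(taxa_B1), ":", bl$within, ",",
                   subtree(taxa_B2), ":", bl$within, ")")
  ingroup <- paste0("(", cladeA, ":", bl$clade, ",",
                    cladeB, ":", bl$clade, ")")
  og <- if (n_outgroup == 1L) paste0(taxa_out, ":", bl$og_tip)
  else paste0(subtree(taxa_out), ":", bl$og_stem)
  nwk <- paste0("(", ingroup, ":", bl$og_stem, ",", og, ");")
  tree <- ape::read.tree(text = nwk)

  ancestor <- make_genome(spec, id = "ancestor")
  forced <- attr(ancestor, "forced")
  feats <- ancestor$features
  pcg <- feats[feats$category == "PCG", , drop = FALSE]
  sizes <- feature_length(pcg, ancestor$length)
  if (length(omega) == 1L)
    omega <- stats::setNames(rep(omega, nrow(pcg)), pcg$gene)
  gc_tab <- genetic_code("2")

  set.seed(seed)
  gene_data <- list()
  taxa <- tree$tip.label
  tip_chars <- lapply(stats::setNames(taxa, taxa),
                      function(tx) seq_chars(ancestor$sequence))
  for (i in seq_len(nrow(pcg))) {
    row <- pcg[i, , drop = FALSE]
    size <- sizes[i]
    cds <- extract_feature_sequence(ancestor, row)
    cc <- suppressWarnings(split_codons(cds, row$gene))
    codons <- cc$codons
    n_cod <- length(codons)
    has_stop <- nchar(cc$incomplete_tail) == 0L &&
      gc_tab[codons[n_cod]] == "*"
    n_ev <- if (has_stop) n_cod - 1L else n_cod
    ## frozen codons: any codon touching a structurally forced position
    frozen <- vapply(seq_len(n_ev), function(ci) {
      hpos <- vapply(0:2, function(t) {
        k <- 3L * ci - 2L + t
        if (row$strand == "H") row$start + k - 1L else row$end - k + 1L
      }, 0L)
      any(forced[hpos])
    }, TRUE)
    ev <- evolve_codons(codons[seq_len(n_ev)], tree, kappa = kappa,
                        omega = omega[[row$gene]], frozen = frozen,
                        seed = seed * 1000L + i)
    gene_data[[row$gene]] <- list(alignment = ev$alignment,
                                  node_states = ev$node_states,
                                  log = ev$log, frozen = frozen,
                                  omega = omega[[row$gene]])
    ## write evolved codons into each taxon's sequence
    for (tx in taxa) {
      tip <- ev$alignment$codons[tx, ]
      changed <- which(tip != codons[seq_len(n_ev)])
      for (ci in changed) {
        ch <- seq_chars(tip[ci])
        for (t in 0:2) {
          k <- 3L * ci - 2L + t
          h <- if (row$strand == "H") row$start + k - 1L
          else row$end - k + 1L
          tip_chars[[tx]][h] <- if (row$strand == "L")
            unname(COMP[ch[t + 1L]]) else ch[t + 1L]
        }
      }
    }
  }
  ## control-region background: highly variable across taxa
  cr_iv <- attr(ancestor, "cr_interval")
  csb_off <- attr(ancestor, "csb_offsets")
  csb_pos <- unlist(lapply(seq_along(csb_off), function(m)
    csb_off[m]:(csb_off[m] + nchar(spec$csb_motifs[[m]]) - 1L)))
  cr_bg <- setdiff(cr_iv[1L]:cr_iv[2L], csb_pos)
  for (tx in taxa) {
    hit <- cr_bg[stats::runif(length(cr_bg)) < cr_divergence]
    if (length(hit) > 0L)
      tip_chars[[tx]][hit] <- sample(BASES, length(hit), replace = TRUE)
  }
  genomes <- lapply(stats::setNames(taxa, taxa), function(tx)
    mito_genome(id = tx, features = feats,
                sequence = paste(tip_chars[[tx]], collapse = ""),
                species = tx, circular = TRUE))
  list(genomes = genomes, tree = tree,
       clades = list(A = c(taxa_A1, taxa_A2),
                     B = c(taxa_B1, taxa_B2),
                     outgroup = taxa_out),
       omega = omega, gene_data = gene_data, ancestor = ancestor)
}
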