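## ---------------------------------------------------------------------------
## Per-site selection analysis on codon alignments.
##
## - ng_sites: synonymous / nonsynonymous site counts per codon
##   (counting convention: at each position, among the three
##   single-nucleotide changes, changes to stops are excluded from both
##   numerator and denominator; a position whose three changes are all
##   stops contributes 0).
## - fitch_ancestral: 60-state codon Fitch parsimony with a
##   deterministic resolution rule.
## - slac: counting test per site; observed substitutions classified
##   along branches with equal-weight averaging over stop-free shortest
##   mutational pathways; two-tailed binomial test of the
##   nonsynonymous count against its neutral expectation.
## - fel_lite: per-site two-rate (alpha = synonymous, beta =
##   nonsynonymous) likelihood-ratio test under an MG94-style codon
##   model with equal nucleotide exchangeabilities and uniform codon
##   frequencies, branch lengths held fixed.
## ---------------------------------------------------------------------------

#' Construct a codon alignment
#'
#' @param codons Character matrix (taxa x sites) of codon 3-mers; the
#'   gap codon "---" marks missing data. Every non-gap cell must be a
#'   sense codon under the genetic code (stop codons are rejected).
#' @param genes Optional per-site gene labels (length = ncol).
#' @inheritParams genetic_code
#' @return Object of class `codon_aln`.
#' @export
codon_alignment <- function(codons, genes = NULL, code_id = "2") {
  stopifnot(is.matrix(codons), is.character(codons))
  if (is.null(rownames(codons)) || anyDuplicated(rownames(codons)))
    stop("codon matrix must have unique taxon rownames")
  sense <- sense_codons(code_id)
  bad <- !(codons %in% c(sense, "---"))
  if (any(bad))
    stop("non-sense codon cells (stop or malformed): ",
         paste(utils::head(unique(codons[bad]), 5L), collapse = ", "))
  if (!is.null(genes)) stopifnot(length(genes) == ncol(codons))
  structure(list(codons = codons, genes = genes,
                 code_id = as.character(code_id)),
            class = "codon_aln")
}

#' @export
print.codon_aln <- function(x, ...) {
  cat("<codon_aln> ", nrow(x$codons), " taxa x ", ncol(x$codons),
      " codon sites (code ", x$code_id, ")\n", sep = "")
  invisible(x)
}

#' Taxa of a codon alignment
#' @param x A `codon_aln`.
#' @return Character vector of taxon labels.
#' @export
codon_aln_taxa <- function(x) rownames(x$codons)

#' Convert an in-frame nucleotide alignment to a codon alignment
#'
#' Columns are read in non-overlapping triplets from position 1; a
#' triplet containing any gap becomes the gap codon "---".
#'
#' @param aln A `mito_aln` whose length is a multiple of 3.
#' @inheritParams genetic_code
#' @return A `codon_aln` (gene labels carried from the partition when
#'   present).
#' @export
aln_to_codons <- function(aln, code_id = "2") {
  L <- aln_ncol(aln)
  if (L %% 3L != 0L) stop("alignment length not a multiple of 3")
  n_sites <- L %/% 3L
  m <- t(vapply(aln$seqs, function(s)
    substring(s, 3L * seq_len(n_sites) - 2L, 3L * seq_len(n_sites)),
    character(n_sites)))
  if (n_sites == 1L) {
    m <- matrix(m, ncol = 1L, dimnames = list(names(aln$seqs), NULL))
  } else rownames(m) <- names(aln$seqs)
  m[grepl("-", m)] <- "---"
  genes <- NULL
  if (!is.null(aln$partition)) {
    genes <- character(n_sites)
    for (k in seq_len(nrow(aln$partition))) {
      s0 <- (aln$partition$start[k] + 2L) %/% 3L
      e0 <- aln$partition$end[k] %/% 3L
      if (s0 <= e0) genes[s0:e0] <- aln$partition$gene[k]
    }
  }
  codon_alignment(m, genes = genes, code_id = code_id)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column is replaced by the source codon of the
#' corresponding unaligned CDS; protein gaps become "---". An
#' incomplete terminal stop (or complete terminal stop codon) in a CDS
#' is trimmed before matching, and the CDS translation must equal the
#' ungapped protein row.
#'
#' @param protein_aln A `mito_aln` of aligned amino-acid sequences.
#' @param cds Named character vector of unaligned CDS nucleotides, one
#'   per taxon of `protein_aln`.
#' @inheritParams genetic_code
#' @return A `codon_aln`.
#' @export
backtranslate <- function(protein_aln, cds, code_id = "2") {
  taxa <- aln_taxa(protein_aln)
  if (!all(taxa %in% names(cds)))
    stop("CDS missing for: ",
         paste(setdiff(taxa, names(cds)), collapse = ", "))
  gc <- genetic_code(code_id)
  L <- aln_ncol(protein_aln)
  out <- matrix("---", nrow = length(taxa), ncol = L,
                dimnames = list(taxa, NULL))
  for (tx in taxa) {
    cc <- suppressWarnings(split_codons(cds[[tx]], gene = tx,
                                        code_id = code_id))
    codons <- cc$codons
    n <- length(codons)
    if (nchar(cc$incomplete_tail) == 0L && gc[codons[n]] == "*")
      codons <- codons[-n]
    prot <- translate_codons(codons, code_id)
    row <- seq_chars(protein_aln$seqs[[tx]])
    ungapped <- row[row != "-"]
    if (length(ungapped) != length(prot) || any(ungapped != prot)) {
      pos <- if (length(ungapped) == length(prot))
        which(ungapped != prot)[1L] else min(length(ungapped),
                                             length(prot)) + 1L
      stop("translation of ", tx, " CDS does not match its protein row",
           " (first difference at residue ", pos, ")")
    }
    out[tx, row != "-"] <- codons
  }
  codon_alignment(out, code_id = code_id)
}

## ---------------------------------------------------------------------------
## Site counting
## ---------------------------------------------------------------------------

ng_cache <- new.env(parent = emptyenv())

#' Synonymous and nonsynonymous site counts of a codon
#'
#' At each of the three positions, the single-nucleotide changes are
#' classified against the genetic code. With the default convention,
#' changes to stop codons are excluded from both numerator and
#' denominator: the position contributes `syn / non_stop` to S and the
#' remainder of 1 to N, and a position whose three changes all create
#' stops contributes 0 to both. With `stops_as_nonsyn = TRUE`, changes
#' to stops count as nonsynonymous and every position contributes
#' exactly 1.
#'
#' @param codon A sense codon 3-mer.
#' @inheritParams genetic_code
#' @param stops_as_nonsyn Count stop-bound changes as nonsynonymous
#'   (default FALSE).
#' @return Named numeric c(S = ..., N = ...).
#' @export
#' @examples
#' ng_sites("TTT")  # S = 1/3, N = 8/3 under the mitochondrial code
ng_sites <- function(codon, code_id = "2", stops_as_nonsyn = FALSE) {
  key <- paste(codon, code_id, stops_as_nonsyn)
  hit <- ng_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code(code_id)
  if (codon == "---" || grepl("-", codon)) stop("gap codon")
  aa <- gc[codon]
  if (is.na(aa)) stop("not a codon: ", codon)
  if (aa == "*") stop("stop codon: ", codon)
  ch <- seq_chars(codon)
  S <- 0; N <- 0
  for (pos in 1:3) {
    syn <- 0L; nonsyn <- 0L; stops <- 0L
    for (b in setdiff(BASES, ch[pos])) {
      mut <- ch; mut[pos] <- b
      maa <- gc[paste(mut, collapse = "")]
      if (maa == "*") stops <- stops + 1L
      else if (maa == aa) syn <- syn + 1L
      else nonsyn <- nonsyn + 1L
    }
    if (stops_as_nonsyn) {
      S <- S + syn / 3
      N <- N + (nonsyn + stops) / 3
    } else {
      valid <- syn + nonsyn
      if (valid > 0L) {
        S <- S + syn / valid
        N <- N + nonsyn / valid
      }
    }
  }
  out <- c(S = S, N = N)
  ng_cache[[key]] <- out
  out
}

## ---------------------------------------------------------------------------
## Ancestral reconstruction
## ---------------------------------------------------------------------------

## Children list and a postorder node sequence of a phylo tree (the tree
## may be rooted or have a basal multifurcation; node ntip+1 acts as
## root).
tree_structure <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  children <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    children[[p]] <- c(children[[p]], tree$edge[e, 2L])
  }
  root <- ntip + 1L
  ## postorder via explicit stack
  post <- integer(0)
  stack <- root
  seen <- integer(0)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    stack <- c(stack, children[[v]])
  }
  post <- rev(seen)
  list(ntip = ntip, root = root, children = children, postorder = post)
}

#' Fitch parsimony over codon states for one site
#'
#' Minimum-change ancestral codon assignment on the tree (rooted at its
#' basal node; the minimum change count is root-invariant). Ambiguities
#' in the final pass are resolved deterministically: the root takes the
#' lexicographically smallest codon of its state set, and each child
#' keeps its parent's state when possible, else takes its
#' lexicographically smallest option. Leaves with a gap/missing state
#' are treated as unconstrained (full state set).
#'
#' @param tree An `ape::phylo` whose tip labels match `column` names.
#' @param column Named character vector of tip codons ("---"/NA =
#'   missing).
#' @return list(states = character vector indexed by node number (tips
#'   then internals), changes = minimum change count, n_ambiguous =
#'   number of internal nodes with more than one equally parsimonious
#'   option at resolution time).
#' @export
fitch_ancestral <- function(tree, column) {
  ts <- tree_structure(tree)
  ntip <- ts$ntip
  tips <- tree$tip.label
  if (!all(tips %in% names(column)))
    stop("column missing states for: ",
         paste(setdiff(tips, names(column)), collapse = ", "))
  obs <- column[tips]
  missing <- is.na(obs) | obs == "---"
  universe <- sort(unique(obs[!missing]))
  if (length(universe) == 0L)
    stop("column has no observed states")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip))
    sets[[i]] <- if (missing[i]) universe else obs[[i]]
  changes <- 0L
  for (v in ts$postorder) {
    kids <- ts$children[[v]]
    if (length(kids) == 0L) next
    cur <- NULL
    for (k in kids) {
      if (is.null(cur)) { cur <- sets[[k]]; next }
      inter <- intersect(cur, sets[[k]])
      if (length(inter) > 0L) cur <- inter
      else {
        cur <- union(cur, sets[[k]])
        changes <- changes + 1L
      }
    }
    sets[[v]] <- sort(cur)
  }
  ## final pass (preorder)
  states <- character(ntip + tree$Nnode)
  n_amb <- 0L
  pre <- rev(ts$postorder)
  parent <- integer(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    parent[tree$edge[e, 2L]] <- tree$edge[e, 1L]
  for (v in pre) {
    s <- sets[[v]]
    if (v == ts$root) {
      if (length(s) > 1L) n_amb <- n_amb + 1L
      states[v] <- s[1L]
    } else {
      ps <- states[parent[v]]
      if (ps %in% s) states[v] <- ps
      else {
        if (length(s) > 1L && v > ntip) n_amb <- n_amb + 1L
        states[v] <- s[1L]
      }
    }
  }
  list(states = states, changes = changes, n_ambiguous = n_amb)
}

## ---------------------------------------------------------------------------
## Pathway-averaged substitution classification
## ---------------------------------------------------------------------------

## Average syn/nonsyn step counts over all stop-free shortest mutational
## pathways between two sense codons (equal pathway weights). If every
## shortest pathway passes through a stop, averaging falls back to all
## pathways. Returns c(syn = ..., nonsyn = ...); syn + nonsyn equals the
## Hamming distance of the codons.
path_cache <- new.env(parent = emptyenv())

count_codon_change <- function(from, to, code_id = "2") {
  if (from == to) return(c(syn = 0, nonsyn = 0))
  key <- paste(from, to, code_id)
  hit <- path_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code(code_id)
  cf <- seq_chars(from); ct <- seq_chars(to)
  diffs <- which(cf != ct)
  perms <- if (length(diffs) == 1L) list(diffs)
  else if (length(diffs) == 2L) list(diffs, rev(diffs))
  else {
    idx <- list()
    for (p in list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                   c(3,1,2), c(3,2,1)))
      idx[[length(idx) + 1L]] <- diffs[p]
    idx
  }
  score_path <- function(ord) {
    cur <- cf
    syn <- 0; nonsyn <- 0
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- ct[pos]
      aa_cur <- gc[paste(cur, collapse = "")]
      aa_nxt <- gc[paste(nxt, collapse = "")]
      if (aa_nxt == "*") return(NULL)      # pathway through a stop
      if (aa_nxt == aa_cur) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  scored <- Filter(Negate(is.null), lapply(perms, score_path))
  if (length(scored) == 0L) {
    ## all pathways blocked by stops: average over them anyway, counting
    ## each step by its amino-acid effect (stop steps as nonsynonymous)
    score_any <- function(ord) {
      cur <- cf; syn <- 0; nonsyn <- 0
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- ct[pos]
        if (gc[paste(nxt, collapse = "")] ==
            gc[paste(cur, collapse = "")]) syn <- syn + 1
        else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn)
    }
    scored <- lapply(perms, score_any)
  }
  out <- colMeans(do.call(rbind, scored))
  path_cache[[key]] <- out
  out
}

## ---------------------------------------------------------------------------
## SLAC
## ---------------------------------------------------------------------------

## Two-tailed binomial p-value for x successes in n trials at null
## probability p0; fractional counts are rounded to the nearest integer
## (documented approximation of the extended counting test).
binom_two_tail <- function(x, n, p0) {
  n <- round(n); x <- min(round(x), n)
  if (n == 0L) return(1)
  if (p0 <= 0) return(if (x > 0) 0 else 1)
  if (p0 >= 1) return(if (x < n) 0 else 1)
  stats::binom.test(x, n, p = p0)$p.value
}

#' SLAC-style per-site counting selection test
#'
#' For every codon site: ancestral codons are reconstructed by Fitch
#' parsimony (or supplied); along each branch the observed codon change
#' is split into synonymous/nonsynonymous steps, averaging over all
#' stop-free shortest mutational pathways with equal weights; expected
#' site counts ES/EN are branch-length-weighted averages of [ng_sites()]
#' over the codons at the ends of every branch. dN = ON/EN and
#' dS = OS/ES; the p-value is a two-tailed binomial test of ON against
#' the neutral expectation EN/(ES+EN) given ON+OS observed
#' substitutions; sites are classified positive / purifying /
#' neutral-ns at level `alpha` by the sign of dN - dS.
#'
#' @param codon_aln A `codon_aln`.
#' @param tree An `ape::phylo` with branch lengths; tip labels must
#'   match the alignment taxa.
#' @param alpha Significance level (default 0.05).
#' @param ancestral Optional matrix of known ancestral codon states
#'   (rows = internal node numbers as character, columns = sites), e.g.
#'   the truth matrix of [evolve_codons()]; when absent, Fitch
#'   reconstruction is used.
#' @param stops_as_nonsyn Site-counting convention flag (see
#'   [ng_sites()]).
#' @return data.frame with one row per site: site, gene, ES, EN, OS,
#'   ON, dN, dS, dn_minus_ds, p_value, classification, n_ambiguous.
#' @export
slac <- function(codon_aln, tree, alpha = 0.05, ancestral = NULL,
                 stops_as_nonsyn = FALSE) {
  stopifnot(inherits(codon_aln, "codon_aln"))
  taxa <- codon_aln_taxa(codon_aln)
  if (!setequal(taxa, tree$tip.label))
    stop("tree and alignment taxa differ: ",
         paste(c(setdiff(taxa, tree$tip.label),
                 setdiff(tree$tip.label, taxa)), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths")
  code_id <- codon_aln$code_id
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  elen <- tree$edge.length
  n_sites <- ncol(codon_aln$codons)
  res <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    col <- codon_aln$codons[, s]
    names(col) <- taxa
    states <- character(ntip + tree$Nnode)
    n_amb <- NA_integer_
    if (is.null(ancestral)) {
      fr <- fitch_ancestral(tree, col)
      states <- fr$states
      n_amb <- fr$n_ambiguous
    } else {
      states[seq_len(ntip)] <- col[tree$tip.label]
      inodes <- (ntip + 1L):(ntip + tree$Nnode)
      states[inodes] <- ancestral[as.character(inodes), s]
    }
    OS <- 0; ON <- 0
    es_num <- 0; en_num <- 0; w_tot <- 0
    for (e in seq_len(nrow(edges))) {
      p <- states[edges[e, 1L]]
      c_ <- states[edges[e, 2L]]
      skip_p <- is.na(p) || p == "---" || p == ""
      skip_c <- is.na(c_) || c_ == "---" || c_ == ""
      if (!skip_p && !skip_c && p != c_) {
        cnt <- count_codon_change(p, c_, code_id)
        OS <- OS + cnt[["syn"]]
        ON <- ON + cnt[["nonsyn"]]
      }
      w <- elen[e]
      sn_p <- if (!skip_p) ng_sites(p, code_id, stops_as_nonsyn) else NULL
      sn_c <- if (!skip_c) ng_sites(c_, code_id, stops_as_nonsyn) else NULL
      if (!is.null(sn_p) || !is.null(sn_c)) {
        avg <- colMeans(do.call(rbind, Filter(Negate(is.null),
                                              list(sn_p, sn_c))))
        es_num <- es_num + w * avg[["S"]]
        en_num <- en_num + w * avg[["N"]]
        w_tot <- w_tot + w
      }
    }
    if (w_tot > 0) {
      ES <- es_num / w_tot
      EN <- en_num / w_tot
    } else {
      ## zero-length tree: unweighted mean over observed tip codons
      obs <- col[col != "---" & !is.na(col)]
      sn <- t(vapply(obs, ng_sites, c(S = 0, N = 0),
                     code_id = code_id,
                     stops_as_nonsyn = stops_as_nonsyn))
      ES <- mean(sn[, "S"]); EN <- mean(sn[, "N"])
    }
    dS <- if (ES > 0) OS / ES else NA_real_
    dN <- if (EN > 0) ON / EN else NA_real_
    dnds_diff <- if (!is.na(dN) && !is.na(dS)) dN - dS else NA_real_
    p0 <- if (ES + EN > 0) EN / (ES + EN) else NA_real_
    pv <- if (!is.na(p0)) binom_two_tail(ON, ON + OS, p0) else NA_real_
    cls <- "neutral/ns"
    if (!is.na(pv) && !is.na(dnds_diff) && pv < alpha) {
      if (dnds_diff > 0) cls <- "positive"
      else if (dnds_diff < 0) cls <- "purifying"
    }
    res[[s]] <- data.frame(
      site = s,
      gene = if (!is.null(codon_aln$genes)) codon_aln$genes[s]
      else NA_character_,
      ES = ES, EN = EN, OS = OS, ON = ON,
      dN = dN, dS = dS, dn_minus_ds = dnds_diff,
      p_value = pv, classification = cls, n_ambiguous = n_amb,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize per-site selection results
#'
#' @param results Output of [slac()] (or any data.frame with columns
#'   dn_minus_ds, p_value, and optionally gene).
#' @param alpha Significance level (default 0.05).
#' @return list(counts = named vector c(positive_sig, purifying_sig,
#'   other), per_gene = data.frame of per-gene counts and percentages).
#' @export
classify_summary <- function(results, alpha = 0.05) {
  if (nrow(results) == 0L)
    return(list(counts = c(positive_sig = 0L, purifying_sig = 0L,
                           other = 0L),
                per_gene = data.frame(gene = character(),
                                      n_sites = integer(),
                                      positive_sig = integer(),
                                      purifying_sig = integer(),
                                      pct_purifying = numeric(),
                                      stringsAsFactors = FALSE)))
  sig <- !is.na(results$p_value) & results$p_value < alpha
  pos <- sig & !is.na(results$dn_minus_ds) & results$dn_minus_ds > 0
  pur <- sig & !is.na(results$dn_minus_ds) & results$dn_minus_ds < 0
  counts <- c(positive_sig = sum(pos), purifying_sig = sum(pur),
              other = nrow(results) - sum(pos) - sum(pur))
  gene <- if ("gene" %in% colnames(results)) results$gene
  else rep(NA_character_, nrow(results))
  gene[is.na(gene)] <- "(all)"
  per_gene <- do.call(rbind, lapply(split(seq_len(nrow(results)), gene),
    function(idx) data.frame(
      gene = gene[idx[1L]], n_sites = length(idx),
      positive_sig = sum(pos[idx]), purifying_sig = sum(pur[idx]),
      pct_purifying = round_half_up(100 * sum(pur[idx]) / length(idx), 2),
      stringsAsFactors = FALSE)))
  rownames(per_gene) <- NULL
  list(counts = counts, per_gene = per_gene)
}

## ---------------------------------------------------------------------------
## fel_lite: per-site two-rate likelihood-ratio test
## ---------------------------------------------------------------------------

## Off-diagonal adjacency matrices over the sense codons: Qs (synonymous
## single-nt changes) and Qn (nonsynonymous), equal exchangeabilities.
codon_model_matrices <- function(code_id = "2") {
  key <- paste0("M", code_id)
  hit <- path_cache[[key]]
  if (!is.null(hit)) return(hit)
  sense <- sense_codons(code_id)
  gc <- genetic_code(code_id)
  ns <- length(sense)
  Qs <- matrix(0, ns, ns, dimnames = list(sense, sense))
  Qn <- Qs
  chars <- strsplit(sense, "", fixed = TRUE)
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    nd <- sum(chars[[i]] != chars[[j]])
    if (nd != 1L) next
    if (gc[sense[i]] == gc[sense[j]]) {
      Qs[i, j] <- Qs[j, i] <- 1
    } else {
      Qn[i, j] <- Qn[j, i] <- 1
    }
  }
  out <- list(Qs = Qs, Qn = Qn, sense = sense)
  path_cache[[key]] <- out
  out
}

## Felsenstein pruning log-likelihood of one codon column given
## per-branch probability matrices.
prune_loglik <- function(ts, tree, Plist, tipstate, ns) {
  ntip <- ts$ntip
  L <- matrix(0, nrow = ntip + tree$Nnode, ncol = ns)
  for (i in seq_len(ntip)) {
    if (is.na(tipstate[i])) L[i, ] <- 1
    else L[i, tipstate[i]] <- 1
  }
  child_edge <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2L])
  for (v in ts$postorder) {
    kids <- ts$children[[v]]
    if (length(kids) == 0L) next
    vec <- rep(1, ns)
    for (k in kids)
      vec <- vec * as.vector(Plist[[child_edge[k]]] %*% L[k, ])
    L[v, ] <- vec
  }
  lik <- mean(L[ts$root, ])     # uniform root frequencies
  if (lik <= 0) -1e10 else log(lik)
}

#' Per-site two-rate likelihood selection test
#'
#' For each codon site a two-rate MG94-style model (equal nucleotide
#' exchangeabilities, uniform codon frequencies) is fitted by maximum
#' likelihood with the tree's branch lengths held fixed: `alpha_rate`
#' scales synonymous and `beta_rate` nonsynonymous single-nucleotide
#' codon changes. The null constrains beta = alpha; the alternative
#' frees beta. The likelihood-ratio p-value uses chi-squared with 1 df,
#' halved.
#'
#' @inheritParams slac
#' @return data.frame per site: site, gene, alpha_rate, beta_rate,
#'   lrt, p_value, converged, classification (at level `alpha` by the
#'   sign of beta - alpha).
#' @export
fel_lite <- function(codon_aln, tree, alpha = 0.05) {
  stopifnot(inherits(codon_aln, "codon_aln"))
  taxa <- codon_aln_taxa(codon_aln)
  if (!setequal(taxa, tree$tip.label))
    stop("tree and alignment taxa differ")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  mm <- codon_model_matrices(codon_aln$code_id)
  ns <- length(mm$sense)
  ts <- tree_structure(tree)
  elen <- pmax(tree$edge.length, 1e-9)
  ## eigen-decomposition depends only on omega = beta/alpha: the
  ## generator is alpha * (Qs + omega * Qn) with diagonal closure
  eig_cache <- new.env(parent = emptyenv())
  get_eig <- function(omega) {
    key <- sprintf("%.12g", omega)
    hit <- eig_cache[[key]]
    if (!is.null(hit)) return(hit)
    M <- mm$Qs + omega * mm$Qn
    diag(M) <- -rowSums(M)
    e <- eigen(M, symmetric = TRUE)
    eig_cache[[key]] <- e
    e
  }
  plist_for <- function(alpha_rate, omega) {
    e <- get_eig(omega)
    lapply(elen, function(t) {
      P <- e$vectors %*% (exp(e$values * alpha_rate * t) * t(e$vectors))
      P[P < 0] <- 0
      P
    })
  }
  tip_idx_all <- matrix(match(codon_aln$codons[tree$tip.label, ,
                                               drop = FALSE], mm$sense),
                        nrow = length(taxa))
  n_sites <- ncol(codon_aln$codons)
  out <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    tipstate <- tip_idx_all[, s]
    site_ll <- function(alpha_rate, omega)
      prune_loglik(ts, tree, plist_for(alpha_rate, omega), tipstate, ns)
    converged <- TRUE
    ## invariant site shortcut: rates 0, no test
    obs <- unique(tipstate[!is.na(tipstate)])
    if (length(obs) <= 1L) {
      out[[s]] <- data.frame(site = s,
                             gene = if (!is.null(codon_aln$genes))
                               codon_aln$genes[s] else NA_character_,
                             alpha_rate = 0, beta_rate = 0, lrt = 0,
                             p_value = 1, converged = TRUE,
                             classification = "neutral/ns",
                             stringsAsFactors = FALSE)
      next
    }
    fit <- tryCatch({
      null <- stats::optimize(function(r) -site_ll(exp(r), 1),
                              interval = c(-8, 4), tol = 1e-4)
      ## alternative: optimize (log alpha, log omega)
      alt <- stats::optim(c(null$minimum, 0),
                          function(p) -site_ll(exp(p[1L]), exp(p[2L])),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-6, maxit = 200))
      list(null = null, alt = alt)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      out[[s]] <- data.frame(site = s,
                             gene = if (!is.null(codon_aln$genes))
                               codon_aln$genes[s] else NA_character_,
                             alpha_rate = NA_real_, beta_rate = NA_real_,
                             lrt = NA_real_, p_value = NA_real_,
                             converged = FALSE,
                             classification = "neutral/ns",
                             stringsAsFactors = FALSE)
      next
    }
    ll0 <- -fit$null$objective
    ll1 <- -fit$alt$value
    lrt <- max(0, 2 * (ll1 - ll0))
    pv <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    a_hat <- exp(fit$alt$par[1L])
    b_hat <- a_hat * exp(fit$alt$par[2L])
    cls <- "neutral/ns"
    if (pv < alpha) cls <- if (b_hat > a_hat) "positive" else "purifying"
    out[[s]] <- data.frame(site = s,
                           gene = if (!is.null(codon_aln$genes))
                             codon_aln$genes[s] else NA_character_,
                           alpha_rate = a_hat, beta_rate = b_hat,
                           lrt = lrt, p_value = pv,
                           converged = fit$alt$convergence == 0,
                           classification = cls,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
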