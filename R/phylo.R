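## ---------------------------------------------------------------------------
## Distance-based phylogenetics: p/JC69/K2P distances with pairwise or
## complete gap deletion, Saitou-Nei neighbor joining with deterministic
## tie-breaking, nonparametric bootstrap support, and topology utilities
## (bipartitions, monophyly, Robinson-Foulds distance).
## ---------------------------------------------------------------------------

#' Pairwise distance matrix of an alignment
#'
#' @param aln A `mito_aln`.
#' @param model "p" (proportion of differing sites), "JC69"
#'   (d = -3/4 log(1 - 4p/3)) or "K2P" (transition/transversion
#'   two-parameter distance).
#' @param gap_deletion "pairwise" (default): sites with a gap/N in
#'   either member of a pair are dropped for that pair; "complete":
#'   sites with any gap/N are dropped for all pairs.
#' @return Symmetric numeric matrix with taxon dimnames. Saturated
#'   pairs (log argument <= 0) raise an error naming the pair.
#' @export
distance_matrix <- function(aln, model = c("p", "JC69", "K2P"),
                            gap_deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  gap_deletion <- match.arg(gap_deletion)
  m <- aln_matrix(aln)
  valid <- matrix(m %in% BASES, nrow = nrow(m))
  if (gap_deletion == "complete") {
    keep <- apply(valid, 2L, all)
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- nrow(m)
  taxa <- rownames(m)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  pur <- c("A", "G")
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok))
      stop("no comparable sites between ", taxa[i], " and ", taxa[j])
    a <- m[i, ok]; b <- m[j, ok]
    p <- mean(a != b)
    d <- switch(model,
      p = p,
      JC69 = {
        arg <- 1 - 4 * p / 3
        if (arg <= 0)
          stop("saturated pair ", taxa[i], "/", taxa[j],
               " (p = ", signif(p, 4), ")")
        -0.75 * log(arg)
      },
      K2P = {
        ts <- mean(a != b & (a %in% pur) == (b %in% pur))
        tv <- p - ts
        a1 <- 1 - 2 * ts - tv
        a2 <- 1 - 2 * tv
        if (a1 <= 0 || a2 <= 0)
          stop("saturated pair ", taxa[i], "/", taxa[j])
        -0.5 * log(a1) - 0.25 * log(a2)
      })
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining. Ties in the Q criterion are broken by
#' the lowest (row, column) index pair in the current matrix order, so
#' the output is deterministic. Negative branch lengths are clamped to
#' zero with a warning.
#'
#' @param D Symmetric distance matrix with unique taxon dimnames,
#'   >= 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) ||
      !isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("D must be a symmetric matrix")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels) || anyDuplicated(labels))
    stop("D must have unique taxon dimnames")
  node <- labels   # current newick fragment per active row
  clamped <- FALSE
  len <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    nn <- nrow(D)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ## lowest index pair among minima (row-major upper triangle)
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (i in seq_len(nn - 1L)) for (j in (i + 1L):nn)
      if (Q[i, j] < qmin - 1e-12) { qmin <- Q[i, j]; best <- c(i, j) }
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- D[i, j] - li
    li <- len(li); lj <- len(lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- paste0("(", node[i], ":", fmt(li), ",",
                     node[j], ":", fmt(lj), ")")
    keep <- setdiff(seq_len(nn), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node <- c(node[keep], merged)
    dimnames(D) <- list(NULL, NULL)
  }
  l1 <- len((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- len((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- len((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  if (clamped) warning("negative branch length(s) clamped to 0")
  nwk <- paste0("(", node[1], ":", fmt(l1), ",", node[2], ":", fmt(l2),
                ",", node[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

## Canonical keys for the bipartitions of an unrooted tree. Each side is
## canonicalized to the side NOT containing the alphabetically first
## taxon. With `trivial = FALSE` only internal (nontrivial) bipartitions
## are returned; names give the tree's internal node numbers.
tree_bipartitions <- function(tree, trivial = FALSE) {
  taxa <- sort(tree$tip.label)
  ref <- taxa[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character(0)
  nodes <- integer(0)
  ntip <- length(tree$tip.label)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (ref %in% side) side <- setdiff(labs, side)
    sz <- length(side)
    if (!trivial && (sz < 2L || sz > ntip - 2L)) next
    if (sz == 0L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, ntip + k)
  }
  ## on a rooted tree the two sides of the root edge describe the same
  ## bipartition; keep the first occurrence
  keep <- !duplicated(keys)
  stats::setNames(keys[keep], nodes[keep])
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; the
#' support of each internal bipartition of the point-estimate tree is
#' the percentage of replicate NJ trees containing it. Supports are
#' attached as internal node labels. Bipartitions on zero-length
#' internal edges of the point tree are uninformative and get NA.
#'
#' @param aln A `mito_aln`.
#' @param model Distance model (see [distance_matrix()]).
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed for reproducible resampling.
#' @return The point-estimate `phylo` tree with `node.label` holding
#'   integer percentage supports ("" for the root/uninformative edges).
#' @export
bootstrap_support <- function(aln, model = "JC69", n_reps = 100L,
                              seed = NULL) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  point <- suppressWarnings(nj_tree(distance_matrix(aln, model)))
  bp <- tree_bipartitions(point)
  counts <- stats::setNames(numeric(length(bp)), bp)
  m <- aln_matrix(aln)
  L <- ncol(m)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rs <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    ra <- mito_alignment(rs)
    rt <- tryCatch(
      suppressWarnings(nj_tree(distance_matrix(ra, model))),
      error = function(e) NULL)
    if (is.null(rt)) next
    hit <- tree_bipartitions(rt)
    counts[bp %in% hit] <- counts[bp %in% hit] + 1
  }
  support <- round(100 * counts / n_reps)
  ## zero-length internal edges are uninformative
  ntip <- length(point$tip.label)
  child_edge <- match(as.integer(names(bp)), point$edge[, 2L])
  informative <- !is.na(child_edge) &
    point$edge.length[child_edge] > 1e-12
  node.label <- rep("", point$Nnode)
  idx <- as.integer(names(bp)) - ntip
  node.label[idx] <- ifelse(informative, as.character(support), "")
  point$node.label <- node.label
  point
}

#' Is a taxon subset monophyletic (unrooted sense)?
#'
#' TRUE when the subset forms one side of some edge bipartition of the
#' tree (for subsets of size 1 or n-1 this is trivially true).
#'
#' @param tree An `ape::phylo`.
#' @param taxa Character vector of tip labels.
#' @return Logical flag.
#' @export
is_monophyletic <- function(tree, taxa) {
  if (!all(taxa %in% tree$tip.label))
    stop("taxa not in tree: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  n <- length(tree$tip.label)
  sz <- length(unique(taxa))
  if (sz %in% c(0L, 1L, n - 1L, n)) return(TRUE)
  ref <- sort(tree$tip.label)[1L]
  side <- unique(taxa)
  if (ref %in% side) side <- setdiff(tree$tip.label, side)
  key <- paste(sort(side), collapse = "|")
  key %in% tree_bipartitions(tree)
}

#' Bootstrap support of the edge defining a clade
#'
#' Looks up the internal-node label (as attached by
#' [bootstrap_support()]) of the edge whose bipartition separates
#' `taxa` from the rest of the tree.
#'
#' @param tree A `phylo` with node labels holding supports.
#' @param taxa Tip labels of the clade.
#' @return Numeric support, or NA when the clade is not an edge of the
#'   tree or its edge carries no support value.
#' @export
clade_support <- function(tree, taxa) {
  bp <- tree_bipartitions(tree)
  ref <- sort(tree$tip.label)[1L]
  side <- unique(taxa)
  if (ref %in% side) side <- setdiff(tree$tip.label, side)
  key <- paste(sort(side), collapse = "|")
  hit <- which(bp == key)
  if (length(hit) == 0L || is.null(tree$node.label)) return(NA_real_)
  node <- as.integer(names(bp)[hit[1L]])
  lab <- tree$node.label[node - length(tree$tip.label)]
  if (is.na(lab) || lab == "") NA_real_ else as.numeric(lab)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the internal (nontrivial) bipartition sets.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  sum(!b1 %in% b2) + sum(!b2 %in% b1)
}
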