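DNA_BASES <- c("A", "C", "G", "T")

## JC69 transition probability matrix for branch length t (subs/site)
jc_pmat <- function(t) {
  e <- exp(-4 * t / 3)
  same <- 0.25 + 0.75 * e
  diff <- 0.25 - 0.25 * e
  m <- matrix(diff, 4L, 4L)
  diag(m) <- same
  m
}

#' Evolve sequences along a gene tree under JC69
#'
#' Simulates an ungapped alignment of `window_len` sites, one row per taxon,
#' by dropping a uniform root state and applying Jukes-Cantor substitution
#' along each branch. Branch lengths in coalescent units are converted to
#' expected substitutions per site as `length * theta / 2` (`theta` is the
#' population-scaled mutation rate per site, `4 N mu`; one coalescent unit is
#' `2N` generations).
#'
#' @param tree an [ape::phylo] (or the `tree` element of an
#'   [sample_gene_tree] result) with branch lengths in coalescent units, or
#'   already in substitutions/site if `theta = NA`.
#' @param window_len number of sites.
#' @param theta population-scaled mutation rate per site (default 0.01);
#'   `NA` means branch lengths are already substitutions/site.
#' @return character matrix (`A/C/G/T`), rows named by taxa.
#' @export
evolve_sequences <- function(tree, window_len, theta = 0.01) {
  if (inherits(tree, "msc_gene_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"), window_len >= 1)
  if (!is.na(theta) && theta < 0) stop("theta must be non-negative")
  scale <- if (is.na(theta)) 1 else theta / 2
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  seqs <- matrix(0L, nrow = nn, ncol = window_len)
  root <- n + 1L
  seqs[root, ] <- sample.int(4L, window_len, replace = TRUE)
  ## preorder: parents before children
  ord <- reorder_edges_preorder(tree)
  for (e in ord) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    t <- tree$edge.length[e] * scale
    x <- seqs[p, ]
    if (t > 0) {
      redraw <- stats::runif(window_len) < (1 - exp(-4 * t / 3))
      if (any(redraw)) x[redraw] <- sample.int(4L, sum(redraw), replace = TRUE)
    }
    seqs[ch, ] <- x
  }
  out <- matrix(DNA_BASES[seqs[seq_len(n), , drop = FALSE]], nrow = n)
  rownames(out) <- tree$tip.label
  out
}

## edge indices ordered parents-before-children
reorder_edges_preorder <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  ord <- integer(0)
  stack <- which(tree$edge[, 1L] == root)
  while (length(stack)) {
    e <- stack[1L]; stack <- stack[-1L]
    ord <- c(ord, e)
    ch <- tree$edge[e, 2L]
    if (ch > n) stack <- c(which(tree$edge[, 1L] == ch), stack)
  }
  ord
}

#' Site-pattern probabilities of a tree under JC69 (Felsenstein pruning)
#'
#' Computes the probability of every one of the `4^n` joint base patterns at
#' the tips of a rooted tree, by the pruning algorithm with a uniform root
#' distribution. Patterns are indexed with the first tip varying fastest:
#' `index = 1 + sum_i (b_i - 1) * 4^(i-1)` with `b_i` the base (A=1..T=4) of
#' the i-th tip in `tip_order`.
#'
#' @param tree rooted [ape::phylo] with branch lengths in substitutions/site.
#' @param tip_order character vector giving the tip order defining the
#'   pattern index (default: `tree$tip.label`).
#' @return numeric vector of length `4^n` summing to 1.
#' @export
tree_pattern_probs <- function(tree, tip_order = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length < 0)) stop("malformed tree: negative branch length")
  n <- length(tree$tip.label)
  P <- 4L^n
  pos <- match(tree$tip.label, tip_order)
  if (any(is.na(pos))) stop("tip_order must contain all tips")
  nn <- n + tree$Nnode
  L <- vector("list", nn)
  for (i in seq_len(n)) L[[i]] <- tip_conditional(n, pos[i])
  ord <- rev(reorder_edges_preorder(tree))  # children before parents
  for (e in ord) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    contrib <- jc_pmat(tree$edge.length[e]) %*% L[[ch]]
    L[[p]] <- if (is.null(L[[p]])) contrib else L[[p]] * contrib
  }
  as.vector(colSums(L[[n + 1L]]) / 4)
}

## leaf conditional-likelihood matrices (4 x 4^n indicator matrices) are
## identical across calls for a given (n, position), so they are memoized
.tip_cond_cache <- new.env(parent = emptyenv())

tip_conditional <- function(n, pos) {
  key <- paste0(n, ".", pos)
  m <- .tip_cond_cache[[key]]
  if (is.null(m)) {
    P <- 4L^n
    b <- ((seq_len(P) - 1L) %/% 4L^(pos - 1L)) %% 4L + 1L
    m <- matrix(0, 4L, P)
    m[cbind(b, seq_len(P))] <- 1
    .tip_cond_cache[[key]] <- m
  }
  m
}

## integer pattern indices (1-based) for the columns of an alignment,
## NA for columns containing non-ACGT symbols
pattern_index <- function(aln, tip_order) {
  stopifnot(all(tip_order %in% rownames(aln)))
  m <- aln[tip_order, , drop = FALSE]
  code <- matrix(match(toupper(m), DNA_BASES), nrow = nrow(m))
  idx <- rep(1L, ncol(m))
  for (i in seq_len(nrow(m))) idx <- idx + (code[i, ] - 1L) * 4L^(i - 1L)
  idx
}
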