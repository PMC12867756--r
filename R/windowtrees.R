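#' Jukes-Cantor distance correction
#'
#' Converts an observed mismatch fraction `p` (computed over ungapped
#' columns) into an expected number of substitutions per site,
#' `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param p mismatch fraction(s), `0 <= p < 0.75`.
#' @return corrected distance(s); `d >= p`, `d = 0` iff `p = 0`.
#' @export
jc_distance <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75)) stop("saturation: mismatch fraction >= 0.75 cannot be JC-corrected")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise JC distance matrix from an alignment
#'
#' Mismatch fractions use pairwise deletion: for each taxon pair only
#' columns where both carry an unambiguous A/C/G/T base are compared.
#'
#' @param aln character matrix, rows = taxa.
#' @return symmetric distance matrix (substitutions/site).
#' @export
aln_jc_matrix <- function(aln) {
  n <- nrow(aln)
  valid <- matrix(toupper(aln) %in% DNA_BASES, nrow = n)
  m <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  up <- toupper(aln)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok)) stop("no comparable ungapped columns for pair ",
                       rownames(aln)[i], "/", rownames(aln)[j])
    p <- mean(up[i, ok] != up[j, ok])
    m[i, j] <- m[j, i] <- jc_distance(p)
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (via ape), with negative branch-length
#' estimates clamped to zero; the number of clamped branches is recorded in
#' the `"clamped"` attribute.
#'
#' @param D symmetric non-negative distance matrix, >= 3 taxa.
#' @return unrooted [ape::phylo].
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Classify a rooted window tree into Tree1 / Tree2 / Tree3
#'
#' After rooting on the outgroup, the window is labelled by which two of the
#' three focal clades (F = focal group, S = sister genus, G = congeneric
#' group) are sisters: `Tree1 = (S,(F,G))`, `Tree2 = ((F,S),G)`,
#' `Tree3 = (F,(S,G))`. A window is `"unresolved"` when some focal clade is
#' not monophyletic or no pair forms a clade.
#'
#' @param tree [ape::phylo], rooted or unrooted, containing the outgroup.
#' @param outgroup outgroup tip label (may be a vector).
#' @param focal_sets named list with elements `F`, `S`, `G`, each a character
#'   vector of tip labels.
#' @return `"Tree1"`, `"Tree2"`, `"Tree3"` or `"unresolved"`.
#' @export
root_and_classify <- function(tree, outgroup, focal_sets) {
  stopifnot(all(c("F", "S", "G") %in% names(focal_sets)))
  if (!all(outgroup %in% tree$tip.label)) stop("outgroup missing from tree")
  tr <- tryCatch(ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
                 error = function(e) NULL)
  if (is.null(tr)) return("unresolved")
  sets <- focal_sets[c("F", "S", "G")]
  ## taxa outside the three focal clades carry no information about the
  ## triplet topology and are pruned along with the outgroup
  tr <- ape::drop.tip(tr, setdiff(tr$tip.label, unlist(sets)))
  for (s in sets)
    if (length(s) > 1L && !ape::is.monophyletic(tr, s)) return("unresolved")
  pairs <- list(Tree1 = c(sets$F, sets$G), Tree2 = c(sets$F, sets$S),
                Tree3 = c(sets$S, sets$G))
  hit <- vapply(pairs, function(p) {
    length(p) == length(tr$tip.label) || ape::is.monophyletic(tr, p)
  }, TRUE)
  ## with all three clades present, exactly one pair can be monophyletic
  if (sum(hit) != 1L) return("unresolved")
  names(pairs)[hit]
}

#' Bootstrap support for a window's assigned topology
#'
#' Resamples alignment columns (gap- or ambiguity-containing columns are
#' excluded wholly before resampling), rebuilds an NJ+JC tree for each
#' replicate and reports the fraction of replicates reproducing the given
#' topology class.
#'
#' @param aln character matrix.
#' @param topology the class assigned to the original window tree.
#' @param outgroup,focal_sets as in [root_and_classify].
#' @param B number of bootstrap replicates (default 100).
#' @return support in `[0, 1]`; 0 (with attribute `flagged = TRUE`) if the
#'   alignment has no variable ungapped columns.
#' @export
bootstrap_support <- function(aln, topology, outgroup, focal_sets, B = 100L) {
  stopifnot(B >= 1)
  clean <- aln[, colSums(!matrix(toupper(aln) %in% DNA_BASES, nrow = nrow(aln))) == 0,
               drop = FALSE]
  variable <- ncol(clean) > 0 &&
    any(apply(clean, 2L, function(col) length(unique(col)) > 1L))
  if (!variable) {
    out <- 0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  hits <- 0L
  for (b in seq_len(B)) {
    rep_aln <- clean[, sample.int(ncol(clean), ncol(clean), replace = TRUE),
                     drop = FALSE]
    cls <- tryCatch(
      root_and_classify(nj_tree(aln_jc_matrix(rep_aln)), outgroup, focal_sets),
      error = function(e) "unresolved")
    if (identical(cls, topology)) hits <- hits + 1L
  }
  hits / B
}

#' Build and classify gene trees for a set of window alignments
#'
#' The per-window pipeline: JC distances (pairwise deletion), neighbor
#' joining, rooting on the outgroup, topology classification, and bootstrap
#' support of the assigned topology.
#'
#' @param alignments list of character matrices (one per window).
#' @param outgroup outgroup tip label.
#' @param focal_sets named list (`F`, `S`, `G`) of tip labels.
#' @param B bootstrap replicates per window (default 100).
#' @param window_ids optional ids (default `window_%06d`).
#' @return list with `records` (data.frame: window, topology, support) and
#'   `trees` (list of [ape::phylo]).
#' @export
window_trees <- function(alignments, outgroup, focal_sets, B = 100L,
                         window_ids = NULL) {
  nw <- length(alignments)
  ids <- window_ids %||% sprintf("window_%06d", seq_len(nw))
  topo <- character(nw); supp <- numeric(nw)
  trees <- vector("list", nw)
  for (w in seq_len(nw)) {
    tr <- tryCatch(nj_tree(aln_jc_matrix(alignments[[w]])),
                   error = function(e) NULL)
    if (is.null(tr)) { topo[w] <- "unresolved"; supp[w] <- 0; next }
    trees[[w]] <- tr
    topo[w] <- root_and_classify(tr, outgroup, focal_sets)
    supp[w] <- if (topo[w] == "unresolved") 0 else
      bootstrap_support(alignments[[w]], topo[w], outgroup, focal_sets, B = B)
  }
  list(records = data.frame(window = ids, topology = topo, support = supp,
                            stringsAsFactors = FALSE),
       trees = trees)
}

#' Internal branch length of the focal triplet in a window tree
#'
#' For a window tree classified as `Tree1`/`Tree2`/`Tree3`, returns the
#' length of the internal branch separating the sister pair of focal clades
#' from the third -- the quantity modelled by the branch-length mixture test.
#' Computed after rooting on the outgroup as the path length between the
#' sister-pair MRCA and the MRCA of all three focal clades.
#'
#' @param tree [ape::phylo] containing outgroup and focal taxa.
#' @param outgroup outgroup tip label(s).
#' @param focal_sets named list (`F`, `S`, `G`) of tip labels.
#' @return branch length in the tree's units, or `NA` if the window is
#'   unresolved.
#' @export
focal_internal_branch <- function(tree, outgroup, focal_sets) {
  cls <- root_and_classify(tree, outgroup, focal_sets)
  if (cls == "unresolved") return(NA_real_)
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  tr <- ape::drop.tip(tr, setdiff(tr$tip.label, unlist(focal_sets)))
  pair <- switch(cls,
                 Tree1 = c(focal_sets$F, focal_sets$G),
                 Tree2 = c(focal_sets$F, focal_sets$S),
                 Tree3 = c(focal_sets$S, focal_sets$G))
  depth <- ape::node.depth.edgelength(tr)
  m_pair <- ape::getMRCA(tr, pair)
  m_all <- ape::getMRCA(tr, unlist(focal_sets))
  depth[m_pair] - depth[m_all]
}

#' Topology-frequency summary with pairwise two-proportion tests
#'
#' Windows below the support threshold and unresolved windows are excluded;
#' proportions are over the retained classified windows. Tree1-vs-Tree2 and
#' Tree1-vs-Tree3 differences are tested with two-sided two-proportion
#' z-tests.
#'
#' @param records data.frame with columns `topology`, `support` (as from
#'   [window_trees]).
#' @param min_support retention threshold on bootstrap support
#'   (default 0.25; windows with support `< min_support` are dropped).
#' @return list with `counts`, `proportions`, `n_retained`, `n_unresolved`,
#'   and `tests` (named p-values).
#' @export
topology_frequencies <- function(records, min_support = 0.25) {
  keep <- records$support >= min_support & records$topology != "unresolved"
  n_unres <- sum(records$topology == "unresolved")
  if (!any(keep)) stop("no windows pass the support filter")
  counts <- table(factor(records$topology[keep],
                         levels = c("Tree1", "Tree2", "Tree3")))
  n <- sum(counts)
  props <- as.numeric(counts) / n
  names(props) <- names(counts)
  zp <- function(a, b) {
    stats::prop.test(c(counts[[a]], counts[[b]]), c(n, n),
                     correct = FALSE)$p.value
  }
  tests <- c(Tree1_vs_Tree2 = zp("Tree1", "Tree2"),
             Tree1_vs_Tree3 = zp("Tree1", "Tree3"))
  list(counts = as.vector(counts), proportions = props, n_retained = n,
       n_unresolved = n_unres, tests = tests)
}
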