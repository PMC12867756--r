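## Shared fixtures and independent oracles used across test files.

## study-shaped networks -----------------------------------------------------

## 3-taxon triplet with internal branch T (coalescent units)
triplet_net <- function(T = 0.5184) {
  species_network(sprintf("((A:1,B:1):%g,C:%g);", T, 1 + T), outgroup = "C")
}

## 5 ingroup lineages + outgroup, mirroring the langur study design:
## F = focal group, S = sister genus, G1/G2/G3 = congeneric groups
study_net <- function(pulses = NULL, t_fg = 1, t_int = 0.8) {
  nwk <- sprintf(
    "(((((G2:%g,G3:%g):%g,G1:%g):%g,F:%g):%g,S:%g):%g,O:%g);",
    t_fg, t_fg, t_int, t_fg + t_int,
    t_int, t_fg + 2 * t_int, t_int, t_fg + 3 * t_int,
    2, t_fg + 3 * t_int + 2)
  species_network(nwk, outgroup = "O", pulses = pulses)
}

## symmetric 5-taxon D_FOIL tree ((P1,P2),(P3,P4),O)
dfoil_net <- function(pulses = NULL) {
  species_network("(((P1:1,P2:1):2,(P3:2,P4:2):1):3,O:6);",
                  outgroup = "O", pulses = pulses)
}

## independent oracles --------------------------------------------------------

## brute-force JC pattern probabilities: direct sum over all internal-node
## state assignments (independent of the pruning implementation)
brute_pattern_probs <- function(tree, tip_order = tree$tip.label) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  n_int <- tree$Nnode
  internal <- (n + 1L):nn
  pmats <- lapply(seq_len(nrow(tree$edge)), function(e) {
    t <- tree$edge.length[e]
    e4 <- exp(-4 * t / 3)
    m <- matrix(0.25 - 0.25 * e4, 4, 4); diag(m) <- 0.25 + 0.75 * e4
    m
  })
  P <- 4^n
  probs <- numeric(P)
  states <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  pos <- match(tree$tip.label, tip_order)
  for (p in seq_len(P)) {
    tipstate <- integer(nn)
    for (i in seq_len(n)) tipstate[i] <- ((p - 1) %/% 4^(pos[i] - 1)) %% 4 + 1
    tot <- 0
    for (r in seq_len(nrow(states))) {
      st <- tipstate
      st[internal] <- states[r, ]
      pr <- 0.25
      for (e in seq_len(nrow(tree$edge)))
        pr <- pr * pmats[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      tot <- tot + pr
    }
    probs[p] <- tot
  }
  probs
}

## brute-force HMM log-likelihood by enumerating every state path
brute_hmm_loglik <- function(idx, params) {
  L <- length(idx)
  E <- unname(params$emission)
  A <- unname(params$transition)
  pi <- unname(as.numeric(params$pi))
  paths <- as.matrix(expand.grid(rep(list(1:4), L)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    pr <- pi[st[1]] * E[st[1], idx[1]]
    if (L > 1) for (t in 2:L)
      pr <- pr * A[st[t - 1], st[t]] * E[st[t], idx[t]]
    tot <- tot + pr
  }
  log(tot)
}

## quartet topologies of a tree via an independent route (ape::keep.tip)
oracle_quartet_score <- function(candidate, gene_trees) {
  taxa <- sort(candidate$tip.label)
  qs <- utils::combn(taxa, 4)
  score <- 0
  for (g in gene_trees) {
    for (q in seq_len(ncol(qs))) {
      sub_c <- ape::unroot(ape::keep.tip(candidate, qs[, q]))
      sub_g <- ape::unroot(ape::keep.tip(g, qs[, q]))
      if (ape::dist.topo(sub_c, sub_g) == 0) score <- score + 1
    }
  }
  score
}

## multinomial topology counts from the analytic MSC mixture
rmix_counts <- function(n, gamma, T1, T2) {
  m1 <- exp(-T1) / 3; m2 <- exp(-T2) / 3
  p <- gamma * c(1 - 2 * m1, m1, m1) + (1 - gamma) * c(m2, 1 - 2 * m2, m2)
  as.vector(stats::rmultinom(1, n, p))
}

## aggregate site-pattern counts for a 4- or 5-taxon configuration by
## sampling gene trees and multinomial sites from their JC pattern law
simulate_pattern_counts <- function(net, taxa, n_trees, sites_per_tree,
                                    theta = 0.02) {
  k <- length(taxa)
  counts <- integer(4^k)
  for (i in seq_len(n_trees)) {
    g <- sample_gene_tree(net)
    tr <- g$tree
    tr$edge.length <- tr$edge.length * theta / 2
    pr <- tree_pattern_probs(tr, tip_order = taxa)
    counts <- counts + as.integer(stats::rmultinom(1, sites_per_tree, pr))
  }
  counts
}

## indices of the 4^4 joint-base patterns (order P1, P2, P3, O) that are
## biallelic ABBA / BABA sites under outgroup polarization
local({
  idx <- seq_len(256L)
  b <- sapply(1:4, function(i) ((idx - 1L) %/% 4L^(i - 1L)) %% 4L)
  d <- b[, 1:3] != b[, 4L]
  der <- ifelse(d[, 1L], b[, 1L], ifelse(d[, 2L], b[, 2L], b[, 3L]))
  bi <- (!d[, 1L] | b[, 1L] == der) & (!d[, 2L] | b[, 2L] == der) &
        (!d[, 3L] | b[, 3L] == der)
  ABBA_IDX <<- which(bi & !d[, 1L] & d[, 2L] & d[, 3L])
  BABA_IDX <<- which(bi & d[, 1L] & !d[, 2L] & d[, 3L])
})

## collapse full 4^5 joint-base pattern counts into the 16 outgroup-polarized
## derived/ancestral classes used by the D_FOIL statistics (biallelic only)
cnt16_from_full <- function(counts, taxa) {
  stopifnot(length(counts) == 1024L, length(taxa) == 5L)
  idx <- seq_len(1024L)
  b <- sapply(1:5, function(i) ((idx - 1L) %/% 4L^(i - 1L)) %% 4L)
  d <- b[, 1:4] != b[, 5L]
  der <- ifelse(d[, 1L], b[, 1L], ifelse(d[, 2L], b[, 2L],
         ifelse(d[, 3L], b[, 3L], b[, 4L])))
  bi <- (!d[, 1L] | b[, 1L] == der) & (!d[, 2L] | b[, 2L] == der) &
        (!d[, 3L] | b[, 3L] == der) & (!d[, 4L] | b[, 4L] == der)
  lab <- c("A", "B")
  pat <- paste0(lab[d[, 1L] + 1L], lab[d[, 2L] + 1L],
                lab[d[, 3L] + 1L], lab[d[, 4L] + 1L])
  cls <- ifelse(bi, pat, NA)
  out <- tapply(counts, cls, sum)
  full <- stats::setNames(numeric(16), sort(unique(pat)))
  full[names(out)] <- out
  round(full)
}

## expand pattern counts into a (small) alignment matrix, one column per site
counts_to_alignment <- function(counts, taxa) {
  idx <- rep(seq_along(counts), counts)
  k <- length(taxa)
  aln <- matrix("", k, length(idx), dimnames = list(taxa, NULL))
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(k))
    aln[i, ] <- bases[((idx - 1) %/% 4^(i - 1)) %% 4 + 1]
  aln
}
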