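#' Sample a gene tree from the multispecies coalescent on a species network
#'
#' Simulates one gene genealogy backwards in time. Within each species branch,
#' `k` lineages coalesce at rate `k(k-1)/2` per coalescent unit, divided by
#' the branch's relative population size. At each internal node of the
#' species tree, surviving lineages merge into the parent branch. At an
#' introgression pulse, every lineage currently in the recipient branch jumps
#' to the donor branch independently with probability `gamma` (pulses at the
#' same time as a node are applied first).
#'
#' @param net a [species_network].
#' @param focal optional character vector of three taxa `(A, B, C)` with
#'   species topology `((A,B),C)`; if given, the returned object carries the
#'   genealogy truth class for that triplet (see [classify_genealogy]).
#' @return a list of class `"msc_gene_tree"` with elements `tree` (an
#'   ultrametric [ape::phylo] in coalescent units), `coal_times` (named
#'   pairwise TMRCA matrix), and, when `focal` is given, `class`
#'   (`"type0"|"type1"|"type2"|"type3"`).
#' @seealso [msc_topology_probs] for the analytic topology distribution.
#' @export
sample_gene_tree <- function(net, focal = NULL) {
  stopifnot(inherits(net, "species_network"))
  n <- length(net$taxa)

  ## event list: internal node times + pulse times, ascending; pulses first on ties
  ev_time <- net$times[(n + 1L):(n + net$tree$Nnode)]
  ev_type <- rep(1L, net$tree$Nnode)
  ev_idx <- (n + 1L):(n + net$tree$Nnode)
  if (!is.null(net$pulses)) {
    ev_time <- c(ev_time, net$pulses$time)
    ev_type <- c(ev_type, rep(0L, nrow(net$pulses)))
    ev_idx <- c(ev_idx, seq_len(nrow(net$pulses)))
  }
  o <- order(ev_time, ev_type)
  ev_time <- ev_time[o]; ev_type <- ev_type[o]; ev_idx <- ev_idx[o]
  nn <- n + net$tree$Nnode

  ## lineage state
  branch <- seq_len(n)            # current species branch per active lineage
  lin_node <- seq_len(n)          # node id in the gene tree being built
  lin_time <- numeric(n)          # time at the bottom of each lineage
  n_active <- n
  merges <- matrix(0, nrow = n - 1L, ncol = 3L)  # child1 node, child2 node, time
  n_merge <- 0L
  next_node <- 2L * n - 1L        # internal gene-tree ids assigned downward; root ends at n+1
  node_time <- numeric(2L * n - 1L)

  pop <- unname(net$pop_sizes)
  introgressed <- FALSE
  origin <- "none"
  t_now <- 0
  do_coalesce <- function(t_end) {
    repeat {
      if (n_active <= 1L) return(invisible(NULL))
      k <- tabulate(branch[seq_len(n_active)], nn)
      b <- which(k > 1L)
      if (!length(b)) { t_now <<- t_end; return(invisible(NULL)) }
      rate <- k[b] * (k[b] - 1) / 2 / pop[b]
      R <- sum(rate)
      dt <- stats::rexp(1L, R)
      if (t_now + dt >= t_end) { t_now <<- t_end; return(invisible(NULL)) }
      t_now <<- t_now + dt
      bsel <- if (length(b) == 1L) b else b[sample.int(length(b), 1L, prob = rate)]
      in_b <- which(branch[seq_len(n_active)] == bsel)
      pair <- in_b[sample.int(length(in_b), 2L)]
      i <- pair[1L]; j <- pair[2L]
      n_merge <<- n_merge + 1L
      merges[n_merge, ] <<- c(lin_node[i], lin_node[j], t_now)
      new_id <- next_node; next_node <<- next_node - 1L
      node_time[new_id] <<- t_now
      lin_node[i] <<- new_id; lin_time[i] <<- t_now
      ## drop lineage j
      keep <- setdiff(seq_len(n_active), j)
      branch[seq_along(keep)] <<- branch[keep]
      lin_node[seq_along(keep)] <<- lin_node[keep]
      lin_time[seq_along(keep)] <<- lin_time[keep]
      n_active <<- n_active - 1L
    }
  }

  for (e in seq_along(ev_time)) {
    do_coalesce(ev_time[e])
    if (n_active <= 1L) break
    act <- seq_len(n_active)
    if (ev_type[e] == 1L) {
      v <- ev_idx[e]
      branch[act][branch[act] %in% net$children[[v]]] <- v
    } else {
      i <- ev_idx[e]
      hit <- branch[act] == net$pulses$rv[i] & stats::runif(n_active) < net$pulses$gamma[i]
      if (any(hit)) {
        branch[act][hit] <- net$pulses$dv[i]
        introgressed <- TRUE
        origin <- net$pulses$donor[i]
      }
    }
  }
  ## root population
  if (n_active > 1L) do_coalesce(Inf)

  ## assemble phylo (merge ids were assigned from 2n-1 downward, so the root is n+1)
  edge <- matrix(0L, nrow = 2L * n - 2L, ncol = 2L)
  elen <- numeric(2L * n - 2L)
  r <- 0L
  for (m in seq_len(n - 1L)) {
    pid <- 2L * n - m
    for (ch in merges[m, 1:2]) {
      r <- r + 1L
      edge[r, ] <- c(pid, ch)
      elen[r] <- node_time[pid] - node_time[ch]
    }
  }
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = net$taxa, Nnode = n - 1L),
                    class = "phylo")

  ct <- pairwise_coal_times(edge, node_time, n, net$taxa)
  out <- list(tree = tree, coal_times = ct,
              introgressed = introgressed, origin = origin)
  if (!is.null(focal)) out$class <- classify_genealogy(ct, net, focal)
  class(out) <- "msc_gene_tree"
  out
}

## pairwise TMRCA matrix from the merge structure
pairwise_coal_times <- function(edge, node_time, n, taxa) {
  ## climb from each tip recording ancestor sets
  parent <- integer(2L * n - 1L)
  parent[edge[, 2L]] <- edge[, 1L]
  anc <- vector("list", n)
  for (i in seq_len(n)) {
    path <- integer(0); v <- i
    while (v != n + 1L) { v <- parent[v]; path <- c(path, v) }
    anc[[i]] <- path
  }
  ct <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m <- intersect(anc[[i]], anc[[j]])[1L]  # paths are ordered tipward->root
    ct[i, j] <- ct[j, i] <- node_time[m]
  }
  ct
}

#' Truth class of a simulated genealogy for a focal triplet
#'
#' For focal taxa `(A, B, C)` with species topology `((A,B),C)` the four
#' truth classes follow the coalescent-HMM convention: `type0` - A and B
#' coalesce inside their own ancestral branch (before the deeper split);
#' `type1` - topology `((A,B),C)` but the A-B coalescence is older than the
#' deeper split (deep coalescence, concordant topology); `type2` - discordant
#' topology `((A,C),B)`; `type3` - discordant topology `((B,C),A)`.
#'
#' @param coal_times pairwise TMRCA matrix (as in [sample_gene_tree] output).
#' @param net the [species_network] the genealogy was simulated from.
#' @param focal character vector `(A, B, C)`.
#' @return one of `"type0"`, `"type1"`, `"type2"`, `"type3"`.
#' @export
classify_genealogy <- function(coal_times, net, focal) {
  stopifnot(length(focal) == 3L, all(focal %in% net$taxa))
  a <- focal[1L]; b <- focal[2L]; c_ <- focal[3L]
  t_ab <- coal_times[a, b]; t_ac <- coal_times[a, c_]; t_bc <- coal_times[b, c_]
  deep <- net$times[resolve_branch(net, paste(sort(focal), collapse = "+"))]
  if (t_ab <= t_ac && t_ab <= t_bc) {
    if (t_ab < deep) "type0" else "type1"
  } else if (t_ac < t_bc) "type2" else "type3"
}

#' Draw internal branch lengths from the ILS / ILS+introgression mixture
#'
#' Generator for the two-component model used by the branch-length mixture
#' test: with probability `1 - p_intro` a length is drawn from
#' `Exp(rate 1/lambda)` (coalescent-only discordance), otherwise from
#' `C + Exp(rate 1/lambda)` (introgressed loci, whose internal branch is
#' elongated by the shift `C`).
#'
#' @param n number of draws.
#' @param p_intro mixing weight of the shifted component, in `[0, 1]`.
#' @param lambda mean of the exponential component (> 0).
#' @param C non-negative shift of the introgression component.
#' @return numeric vector of `n` non-negative branch lengths.
#' @export
sample_triplet_branch_lengths <- function(n, p_intro, lambda, C) {
  if (p_intro < 0 || p_intro > 1) stop("p_intro must lie in [0, 1]")
  if (lambda <= 0) stop("lambda must be positive")
  if (C < 0) stop("C must be non-negative")
  x <- stats::rexp(n, rate = 1 / lambda)
  x + C * (stats::runif(n) < p_intro)
}

#' @export
print.msc_gene_tree <- function(x, ...) {
  cat("MSC gene tree:", ape::write.tree(x$tree), "\n")
  if (!is.null(x$class)) cat("  genealogy class:", x$class, "\n")
  invisible(x)
}
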