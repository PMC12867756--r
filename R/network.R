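#' Species network: a dated species tree with optional introgression
#'
#' Constructs the demographic model used by the multispecies coalescent (MSC)
#' simulator: a rooted, ultrametric species tree whose branch lengths are in
#' coalescent units (time scaled by 2N generations of the root population),
#' optionally decorated with unidirectional introgression pulses and/or a
#' hybrid-origin tip. Per-branch relative population sizes rescale the
#' coalescent rate on that branch.
#'
#' Branches are identified by the tip set of the clade they subtend, written
#' as the sorted tip labels joined with `"+"` (a single label for a terminal
#' branch). A pulse `(time, donor, recipient, gamma)` means that, forward in
#' time, a fraction `gamma` of the recipient population was replaced by
#' migrants from the donor branch at `time`; tracing a lineage backwards it
#' therefore jumps from the recipient branch into the donor branch with
#' probability `gamma`.
#'
#' A hybrid tip `(taxon, parent1, parent2, gamma)` declares that the taxon's
#' lineage, upon reaching its attachment node, derives from `parent1` with
#' probability `gamma` and from `parent2` otherwise. In the backbone tree the
#' hybrid must be attached as sister to (part of) the `parent1` clade; the
#' constructor converts the `parent2` contribution into an equivalent pulse.
#'
#' @param tree an [ape::phylo] object (or Newick string), rooted and
#'   ultrametric, branch lengths in coalescent units.
#' @param outgroup tip label of the outgroup, which must attach at the root.
#' @param pop_sizes named numeric vector of relative population sizes keyed
#'   by branch id; unnamed branches default to 1.
#' @param pulses `data.frame` with columns `time`, `donor`, `recipient`,
#'   `gamma`, or `NULL`.
#' @param hybrid optional `list(taxon, parent1, parent2, gamma)`.
#' @return an object of class `"species_network"`.
#' @examples
#' net <- species_network("(((F:1,G:1):0.5184,S:1.5184):2,O:3.5184);",
#'                        outgroup = "O")
#' net
#' @export
species_network <- function(tree, outgroup, pop_sizes = NULL, pulses = NULL,
                            hybrid = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object or Newick string")
  if (is.null(tree$edge.length)) stop("species tree needs branch lengths (coalescent units)")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be binary")
  if (!outgroup %in% tree$tip.label) stop("outgroup not among tip labels")

  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)           # distance from root
  times <- max(depth) - depth                         # 0 at tips, increasing rootward
  if (any(abs(times[seq_len(n)]) > 1e-8))
    stop("species tree must be ultrametric (all tips at time 0)")
  times[seq_len(n)] <- 0

  root <- n + 1L
  parent <- integer(n + tree$Nnode); parent[root] <- NA_integer_
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]

  ## outgroup attaches at the root
  og <- match(outgroup, tree$tip.label)
  if (parent[og] != root) stop("outgroup must attach directly at the root")

  ## internal node times strictly increase rootward
  for (v in seq_len(n + tree$Nnode)) {
    if (v != root && !is.na(parent[v]) && times[parent[v]] <= times[v] - 1e-12 && v > n)
      stop("node times must strictly increase root-ward")
  }

  clades <- clade_ids(tree)
  ps <- rep(1, n + tree$Nnode)
  names(ps) <- clades
  if (!is.null(pop_sizes)) {
    bad <- setdiff(names(pop_sizes), clades)
    if (length(bad)) stop("unknown branch id(s): ", paste(bad, collapse = ", "))
    if (any(pop_sizes <= 0)) stop("population sizes must be positive")
    ps[names(pop_sizes)] <- pop_sizes
  }

  net <- structure(list(tree = tree, taxa = tree$tip.label, outgroup = outgroup,
                        times = times, parent = parent, root = root,
                        clades = clades, pop_sizes = ps,
                        pulses = NULL, hybrid = hybrid),
                   class = "species_network")

  if (!is.null(hybrid)) {
    stopifnot(is.list(hybrid),
              all(c("taxon", "parent1", "parent2", "gamma") %in% names(hybrid)))
    if (hybrid$gamma < 0 || hybrid$gamma > 1) stop("hybrid gamma must lie in [0, 1]")
    hn <- resolve_branch(net, hybrid$taxon)
    t_h <- net$times[net$parent[hn]]
    ## parent1 contribution is the backbone attachment; parent2 enters as a pulse
    pulses <- rbind(pulses,
                    data.frame(time = t_h, donor = hybrid$parent2,
                               recipient = hybrid$taxon,
                               gamma = 1 - hybrid$gamma))
  }
  if (!is.null(pulses)) {
    stopifnot(all(c("time", "donor", "recipient", "gamma") %in% names(pulses)))
    if (any(pulses$gamma < 0 | pulses$gamma > 1)) stop("pulse gamma must lie in [0, 1]")
    for (i in seq_len(nrow(pulses))) {
      dv <- resolve_branch(net, pulses$donor[i])
      rv <- resolve_branch(net, pulses$recipient[i])
      for (v in c(dv, rv)) {
        lo <- net$times[v]
        hi <- if (v == net$root) Inf else net$times[net$parent[v]]
        if (pulses$time[i] < lo - 1e-12 || pulses$time[i] > hi + 1e-12)
          stop("pulse time ", pulses$time[i], " outside the lifespan of branch ",
               net$clades[v])
      }
    }
    pulses$dv <- vapply(pulses$donor, function(s) resolve_branch(net, s), 0L)
    pulses$rv <- vapply(pulses$recipient, function(s) resolve_branch(net, s), 0L)
    net$pulses <- pulses
  }
  ## children lookup, used by the simulator's event loop
  nn <- n + tree$Nnode
  net$children <- lapply(seq_len(nn), function(v) tree$edge[tree$edge[, 1L] == v, 2L])
  net
}

## branch id (sorted tip labels joined by "+") for every node of a phylo
clade_ids <- function(tree) {
  n <- length(tree$tip.label)
  ids <- character(n + tree$Nnode)
  ids[seq_len(n)] <- tree$tip.label
  for (v in (n + 1L):(n + tree$Nnode)) {
    tips <- tree$tip.label[unlist(tips_below(tree, v))]
    ids[v] <- paste(sort(tips), collapse = "+")
  }
  ids
}

## tip indices below node v
tips_below <- function(tree, v) {
  n <- length(tree$tip.label)
  if (v <= n) return(v)
  kids <- tree$edge[tree$edge[, 1L] == v, 2L]
  unlist(lapply(kids, tips_below, tree = tree))
}

## resolve a branch spec ("A" or "A+B+C") to a node index
resolve_branch <- function(net, spec) {
  parts <- sort(strsplit(spec, "+", fixed = TRUE)[[1L]])
  key <- paste(parts, collapse = "+")
  v <- match(key, net$clades)
  if (is.na(v)) stop("no branch with clade {", key, "} in the species tree")
  v
}

#' @export
print.species_network <- function(x, ...) {
  cat("Species network on", length(x$taxa), "taxa (outgroup:", x$outgroup, ")\n")
  cat("  tree:", ape::write.tree(x$tree), "\n")
  if (!is.null(x$pulses)) {
    cat("  introgression pulses:\n")
    for (i in seq_len(nrow(x$pulses)))
      cat(sprintf("    t=%.4g  %s -> %s  gamma=%.3g\n", x$pulses$time[i],
                  x$pulses$donor[i], x$pulses$recipient[i], x$pulses$gamma[i]))
  }
  if (!is.null(x$hybrid))
    cat(sprintf("  hybrid tip %s = %s (gamma=%.3g) x %s\n", x$hybrid$taxon,
                x$hybrid$parent1, x$hybrid$gamma, x$hybrid$parent2))
  invisible(x)
}

#' Rooted triplet topology probabilities under the multispecies coalescent
#'
#' For a species triplet `((A,B),C)` whose internal branch (between the A-B
#' split and the deeper split) lasts `T` coalescent units, the probability
#' that a gene tree is concordant with the species tree is
#' `1 - (2/3) exp(-T)`; each of the two discordant rooted topologies has
#' probability `exp(-T)/3`.
#'
#' @param T internal branch length in coalescent units (scalar or vector),
#'   `T >= 0`.
#' @return matrix with columns `concordant`, `minor1`, `minor2`; rows sum
#'   to 1 and `minor1 == minor2`.
#' @examples
#' msc_topology_probs(0.5184)
#' @export
msc_topology_probs <- function(T) {
  if (any(is.na(T)) || any(T < 0)) stop("T must be non-negative")
  m <- exp(-T) / 3
  cbind(concordant = 1 - 2 * m, minor1 = m, minor2 = m)
}

#' Invert a minor-topology proportion to a coalescent internal branch length
#'
#' Under the MSC each discordant rooted triplet topology has probability
#' `exp(-T)/3`, so the average minor proportion `p` inverts to
#' `T = -log(3 p)`. Values of `p` above 1/3 cannot arise from the MSC on a
#' tree (anomaly-zone / estimation noise); a warning is issued and `T = 0`
#' returned. `p = 0` maps to `Inf` with a warning.
#'
#' @param p_minor_avg average proportion of the two discordant topologies,
#'   in `(0, 1/3]`.
#' @return internal branch length in coalescent units.
#' @examples
#' triplet_T_hat(0.1985)   # ~0.5184
#' @export
triplet_T_hat <- function(p_minor_avg) {
  if (any(p_minor_avg < 0) || any(p_minor_avg > 1)) stop("p_minor_avg must be in [0, 1]")
  out <- -log(3 * p_minor_avg)
  if (any(p_minor_avg == 0)) {
    warning("minor proportion 0: internal branch effectively infinite")
  }
  high <- p_minor_avg > 1 / 3
  if (any(high)) {
    warning("minor proportion exceeds 1/3 (not attainable under the MSC); returning T = 0")
    out[high] <- 0
  }
  out
}
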