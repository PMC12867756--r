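#' Exact quartet-agreement species tree
#'
#' Scores every candidate unrooted topology on the shared leaf set by the
#' total number of induced quartets over all gene trees that agree with it,
#' and returns the maximiser -- an exact version of the quartet criterion
#' optimised heuristically by summary coalescent species-tree methods,
#' feasible at small taxon counts (<= 8 taxa).
#'
#' @param gene_trees list of [ape::phylo] sharing one leaf set.
#' @param taxa optional leaf set (default: tips of the first tree).
#' @return list with `tree` (the best topology; when tied, the first of the
#'   tied set), `score`, `ties` (list of all tied topologies) and
#'   `ambiguous` (`TRUE` if more than one topology attains the maximum).
#' @export
exact_quartet_species_tree <- function(gene_trees, taxa = NULL) {
  stopifnot(length(gene_trees) >= 1L)
  taxa <- sort(taxa %||% gene_trees[[1L]]$tip.label)
  n <- length(taxa)
  if (n > 8L) stop("exact search limited to 8 taxa")
  if (n < 4L) stop("need at least 4 taxa")
  for (g in gene_trees)
    if (!setequal(g$tip.label, taxa)) stop("gene trees must share one leaf set")

  quartets <- utils::combn(n, 4L)
  nq <- ncol(quartets)
  ## resolution of each quartet in a tree: 1 = (12|34), 2 = (13|24), 3 = (14|23)
  resolutions <- function(tree) {
    tr <- tree; tr$edge.length <- rep(1, nrow(tr$edge))
    D <- stats::cophenetic(tr)[taxa, taxa]
    r <- integer(nq)
    for (q in seq_len(nq)) {
      i <- quartets[, q]
      s <- c(D[i[1L], i[2L]] + D[i[3L], i[4L]],
             D[i[1L], i[3L]] + D[i[2L], i[4L]],
             D[i[1L], i[4L]] + D[i[2L], i[3L]])
      m <- which(s == min(s))
      r[q] <- if (length(m) == 1L) m else 0L   # 0 = unresolved
    }
    r
  }

  counts <- matrix(0L, nq, 3L)
  for (g in gene_trees) {
    r <- resolutions(g)
    ok <- r > 0L
    idx <- cbind(which(ok), r[ok])
    counts[idx] <- counts[idx] + 1L
  }

  cands <- ape::read.tree(text = paste0(all_unrooted_newicks(taxa), collapse = ""))
  if (inherits(cands, "phylo")) cands <- list(cands)
  scores <- vapply(cands, function(ct) {
    r <- resolutions(ct)
    sum(counts[cbind(seq_len(nq), pmax(r, 1L))][r > 0L])
  }, 0)
  best <- max(scores)
  ties <- which(scores == best)
  list(tree = cands[[ties[1L]]], score = best,
       ties = cands[ties], ambiguous = length(ties) > 1L)
}

## Newick strings of all unrooted binary topologies on the given taxa
## (stepwise addition: each new taxon inserted into every edge)
all_unrooted_newicks <- function(taxa) {
  n <- length(taxa)
  ## represent trees as rooted-binary structures via nested lists over first 3 taxa
  trees <- list(list(taxa[1L], taxa[2L], taxa[3L]))  # unrooted star on 3
  add_tip <- function(tr, tip) {
    ## insert tip on each edge; tr is a nested list with 3 children at top
    res <- list()
    insert_all <- function(node, path) {
      if (is.character(node)) {
        res[[length(res) + 1L]] <<- replace_at(tr, path, list(node, tip))
        return(invisible(NULL))
      }
      for (k in seq_along(node)) insert_all(node[[k]], c(path, k))
      if (length(path) > 0L)  # internal edge above this node
        res[[length(res) + 1L]] <<- replace_at(tr, path, list(node, tip))
      invisible(NULL)
    }
    insert_all(tr, integer(0))
    res
  }
  replace_at <- function(tr, path, value) {
    if (length(path) == 0L) return(value)
    tr[[path[1L]]] <- replace_at(tr[[path[1L]]], path[-1L], value)
    tr
  }
  for (tip in taxa[-(1:3)]) trees <- unlist(lapply(trees, add_tip, tip = tip),
                                            recursive = FALSE)
  to_newick <- function(node) {
    if (is.character(node)) return(node)
    paste0("(", paste(vapply(node, to_newick, ""), collapse = ","), ")")
  }
  vapply(trees, function(tr) paste0(to_newick(tr), ";"), "")
}

#' Two-part test of the hybrid-speciation prediction
#'
#' Under homoploid hybrid speciation the focal lineage should cluster with
#' each putative parent in equal proportions of the genome, and each
#' parental pairing should outnumber the non-parental one. The hypothesis is
#' rejected if (a) the two parental-topology counts differ (two-sided
#' two-proportion test) or (b) the rarer parental proportion does not
#' significantly exceed the non-parental proportion (one-sided test).
#'
#' @param counts named or ordered vector of window counts for
#'   `(Tree1, Tree2, Tree3)`.
#' @param parental the two topology labels pairing the focal clade with each
#'   putative parent (default `c("Tree1", "Tree2")`).
#' @param alpha significance level for both sub-tests (default 0.05).
#' @return list with `decision` (`"consistent-with-hybrid"` or
#'   `"rejected"`), `p_equal`, `p_dominance`.
#' @export
hybrid_speciation_test <- function(counts, parental = c("Tree1", "Tree2"),
                                   alpha = 0.05) {
  labs <- c("Tree1", "Tree2", "Tree3")
  if (is.null(names(counts))) names(counts) <- labs
  if (sum(counts) == 0) stop("zero total count")
  stopifnot(all(parental %in% labs), length(parental) == 2L)
  nonpar <- setdiff(labs, parental)
  n <- sum(counts)
  p_eq <- stats::prop.test(c(counts[[parental[1L]]], counts[[parental[2L]]]),
                           c(n, n), correct = FALSE)$p.value
  weak <- parental[which.min(c(counts[[parental[1L]]], counts[[parental[2L]]]))]
  p_dom <- stats::prop.test(c(counts[[weak]], counts[[nonpar]]), c(n, n),
                            alternative = "greater", correct = FALSE)$p.value
  rejected <- (p_eq < alpha) || (p_dom >= alpha)
  list(decision = if (rejected) "rejected" else "consistent-with-hybrid",
       p_equal = p_eq, p_dominance = p_dom)
}

#' Maximum-likelihood inheritance probability from triplet topology counts
#'
#' Fits the one-reticulation mixture
#' `P(topo) = gamma * P_MSC(topo | parent1 tree, T1) + (1 - gamma) * P_MSC(topo | parent2 tree, T2)`
#' to the multinomial counts of the three rooted triplet topologies, where
#' `P_MSC` is the standard MSC triplet distribution ([msc_topology_probs]).
#' With a single triplet's counts (2 degrees of freedom) the 3-parameter
#' model is not identifiable, so by default the two parental internal branch
#' lengths are constrained equal (`T1 = T2`), which makes the model exactly
#' identified; `equal_T = FALSE` fits all three parameters and flags the fit
#' as non-identifiable.
#'
#' @param counts vector of 3 topology counts, ordered
#'   `(parent1 topology, parent2 topology, third topology)`.
#' @param equal_T constrain `T1 = T2` (default `TRUE`).
#' @param conf_level profile-likelihood confidence level for gamma.
#' @return object of class `"gamma_fit"`: `gamma`, `T1`, `T2`, `loglik`,
#'   `ci`, `identifiable`, `profile`.
#' @export
gamma_triplet_ml <- function(counts, equal_T = TRUE, conf_level = 0.95) {
  stopifnot(length(counts) == 3L, all(counts >= 0), sum(counts) > 0)
  counts <- as.numeric(counts)
  probs <- function(g, T1, T2) {
    m1 <- exp(-T1) / 3; m2 <- exp(-T2) / 3
    p <- g * c(1 - 2 * m1, m1, m1) + (1 - g) * c(m2, 1 - 2 * m2, m2)
    pmax(p, 1e-300)
  }
  ll <- function(g, T1, T2) sum(counts * log(probs(g, T1, T2)))
  obj <- function(par) {  # par = (logit g, log T1 [, log T2])
    g <- stats::plogis(par[1L]); T1 <- exp(par[2L])
    T2 <- if (equal_T) T1 else exp(par[3L])
    -ll(g, T1, T2)
  }
  init <- if (equal_T) c(0, log(0.5)) else c(0, log(0.5), log(0.5))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  g_hat <- stats::plogis(fit$par[1L])
  T1 <- exp(fit$par[2L]); T2 <- if (equal_T) T1 else exp(fit$par[3L])

  ## profile likelihood over gamma
  grid <- seq(0, 1, by = 0.005)
  prof <- vapply(grid, function(g) {
    o <- stats::optimize(function(lt) -ll(g, exp(lt), exp(lt)), c(-8, 4))
    if (!equal_T) {
      o2 <- stats::optim(c(log(T1 + 1e-6), log(T2 + 1e-6)),
                         function(p) -ll(g, exp(p[1L]), exp(p[2L])),
                         method = "Nelder-Mead")
      o <- list(objective = min(o$objective, o2$value))
    }
    -o$objective
  }, 0)
  llmax <- max(prof, ll(g_hat, T1, T2))
  cut <- llmax - stats::qchisq(conf_level, 1L) / 2
  inside <- grid[prof >= cut]
  ci <- if (length(inside)) range(inside) else c(NA_real_, NA_real_)

  structure(list(gamma = g_hat, T1 = T1, T2 = T2, loglik = ll(g_hat, T1, T2),
                 ci = ci, conf_level = conf_level,
                 identifiable = equal_T, counts = counts,
                 profile = data.frame(gamma = grid, loglik = prof)),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat("Triplet-frequency inheritance probability (ML)\n")
  cat(sprintf("  gamma = %.4f  [%.0f%% profile CI %.4f, %.4f]\n", x$gamma,
              100 * x$conf_level, x$ci[1L], x$ci[2L]))
  cat(sprintf("  T1 = %.4f, T2 = %.4f coalescent units; loglik = %.3f\n",
              x$T1, x$T2, x$loglik))
  if (!x$identifiable)
    cat("  warning: unconstrained (T1, T2) fit is not identifiable from one triplet\n")
  invisible(x)
}

#' @export
logLik.gamma_fit <- function(object, ...) {
  structure(object$loglik, df = if (object$identifiable) 2L else 3L,
            class = "logLik")
}

#' @export
coef.gamma_fit <- function(object, ...) {
  c(gamma = object$gamma, T1 = object$T1, T2 = object$T2)
}
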