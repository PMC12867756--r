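#' Parameters of the four-state coalescent HMM
#'
#' Hidden states are local genealogies of a four-taxon alignment
#' `((A,B),C,O)`: `type0` -- A,B coalesce inside their own ancestral branch;
#' `type1` -- concordant topology but deep coalescence in the ancestral
#' population; `type2` -- discordant `((A,C),B)`; `type3` -- discordant
#' `((B,C),A)`. ILS states are type2 and type3; type1 is deep coalescence
#' without topology change and is reported separately.
#'
#' Each state is represented by one fixed genealogy with point coalescent
#' times: mid-branch for type0 (`(tau1 + tau2)/2`), and ancestral means for
#' type1-3 (first coalescence `tau2 + theta_anc/3`, second after a further
#' `theta_anc`). Emissions are JC69 site-pattern probabilities of these
#' genealogies (Felsenstein pruning). The transition matrix is
#' `A = (1 - s) I + s 1 pi'`: with probability `s` per site the genealogy is
#' redrawn from the stationary distribution `pi` -- a single switch-rate
#' surrogate for recombination. `pi` must satisfy `pi[type2] == pi[type3]`
#' (the two discordant genealogies are exchangeable under the MSC).
#'
#' @param tau1,tau2 species divergence times of the (A,B) and (A,B,C) splits
#'   in expected substitutions/site, `0 < tau1 < tau2`.
#' @param theta_anc mean pairwise coalescent waiting time in the ancestral
#'   populations, substitutions/site.
#' @param s per-site genealogy switch probability, in `(0, 1)`.
#' @param pi stationary distribution over `(type0, type1, type2, type3)`.
#' @param tau3 outgroup divergence time (default `tau2 + 3 * theta_anc`).
#' @param taxa the four taxon labels, in order `(A, B, C, O)`.
#' @return object of class `"coalhmm_params"`: state trees, emission matrix
#'   (4 x 256), transition matrix, and the inputs.
#' @export
coalhmm_params <- function(tau1, tau2, theta_anc, s, pi,
                           tau3 = tau2 + 3 * theta_anc,
                           taxa = c("A", "B", "C", "O")) {
  stopifnot(tau1 > 0, tau2 > tau1, theta_anc > 0, tau3 > tau2,
            s > 0, s < 1, length(pi) == 4L, all(pi > 0), length(taxa) == 4L)
  pi <- pi / sum(pi)
  if (abs(pi[3L] - pi[4L]) > 1e-8)
    stop("pi[type2] must equal pi[type3]")
  t_first <- tau2 + theta_anc / 3
  t_second <- t_first + theta_anc
  t_root <- tau3 + theta_anc / 2
  if (t_second >= t_root) stop("outgroup time too small for the state genealogies")
  trees <- list(
    type0 = state_tree(taxa, c(1L, 2L), (tau1 + tau2) / 2, tau2 + theta_anc / 2, t_root),
    type1 = state_tree(taxa, c(1L, 2L), t_first, t_second, t_root),
    type2 = state_tree(taxa, c(1L, 3L), t_first, t_second, t_root),
    type3 = state_tree(taxa, c(2L, 3L), t_first, t_second, t_root))
  E <- t(vapply(trees, tree_pattern_probs, numeric(256L), tip_order = taxa))
  A <- (1 - s) * diag(4L) + s * matrix(pi, 4L, 4L, byrow = TRUE)
  dimnames(A) <- list(names(trees), names(trees))
  structure(list(tau1 = tau1, tau2 = tau2, theta_anc = theta_anc, tau3 = tau3,
                 s = s, pi = stats::setNames(pi, names(trees)), taxa = taxa,
                 trees = trees, emission = E, transition = A),
            class = "coalhmm_params")
}

## rooted 4-leaf genealogy: leaves `pair` coalesce at t1, joined by the
## remaining ingroup leaf at t2, outgroup at t_root
state_tree <- function(taxa, pair, t1, t2, t_root) {
  third <- setdiff(1:3, pair)
  nwk <- sprintf("(((%s:%g,%s:%g):%g,%s:%g):%g,%s:%g);",
                 taxa[pair[1L]], t1, taxa[pair[2L]], t1, t2 - t1,
                 taxa[third], t2, t_root - t2, taxa[4L], t_root)
  ape::read.tree(text = nwk)
}

#' @export
print.coalhmm_params <- function(x, ...) {
  cat("Coalescent HMM (4 states) over taxa", paste(x$taxa, collapse = ", "), "\n")
  cat(sprintf("  tau1 = %g, tau2 = %g, theta_anc = %g (subs/site)\n",
              x$tau1, x$tau2, x$theta_anc))
  cat(sprintf("  switch rate s = %g; pi = (%s)\n", x$s,
              paste(sprintf("%.3f", x$pi), collapse = ", ")))
  invisible(x)
}

#' Forward-backward posterior decoding
#'
#' Scaled forward-backward over the sites of a four-taxon alignment (or a
#' precomputed pattern-index vector). Columns with gaps or ambiguity codes
#' are treated as missing (emission 1 under every state).
#'
#' @param x character alignment matrix with the params' taxa as rows, or an
#'   integer vector of 1-based pattern indices (`NA` = missing).
#' @param params a [coalhmm_params].
#' @return list with `posterior` (L x 4 matrix, rows summing to 1),
#'   `loglik`, and `states` (column names).
#' @export
forward_backward <- function(x, params) {
  stopifnot(inherits(params, "coalhmm_params"))
  idx <- if (is.matrix(x)) pattern_index(x, params$taxa) else as.integer(x)
  L <- length(idx)
  if (L == 0L) stop("empty input")
  E <- params$emission
  e <- matrix(1, 4L, L)
  ok <- !is.na(idx)
  e[, ok] <- E[, idx[ok]]
  s <- params$s; pi <- as.numeric(params$pi)
  alpha <- matrix(0, 4L, L); cvec <- numeric(L)
  a <- pi * e[, 1L]
  cvec[1L] <- sum(a); alpha[, 1L] <- a / cvec[1L]
  if (L > 1L) for (t in 2L:L) {
    ap <- alpha[, t - 1L]
    a <- e[, t] * ((1 - s) * ap + s * pi)   # sum(ap) == 1 after scaling
    cvec[t] <- sum(a)
    alpha[, t] <- a / cvec[t]
  }
  beta <- matrix(0, 4L, L)
  beta[, L] <- 1
  if (L > 1L) for (t in (L - 1L):1L) {
    bn <- beta[, t + 1L] * e[, t + 1L]
    ## A %*% bn for A = (1-s)I + s 1 pi'
    beta[, t] <- ((1 - s) * bn + s * sum(pi * bn)) / cvec[t + 1L]
  }
  post <- t(alpha * beta)
  post <- post / rowSums(post)
  colnames(post) <- names(params$pi)
  list(posterior = post, loglik = sum(log(cvec)), states = names(params$pi))
}

#' Fit switch rate and stationary distribution by Baum-Welch
#'
#' Expectation-maximisation for `s` and `pi` with the state genealogies
#' (emissions) held at the values implied by the initial parameters,
#' optionally profiled over a coarse grid of branch-length scale factors.
#' The M-step maximises the expected complete-data log-likelihood
#' numerically under the constrained transition structure
#' `A = (1-s)I + s 1 pi'` with `pi[type2] = pi[type3]`; the observed
#' log-likelihood is non-decreasing across iterations.
#'
#' @param x alignment matrix or pattern-index vector.
#' @param init a [coalhmm_params] providing initial values and genealogies.
#' @param scale_grid numeric vector of scale factors applied to
#'   `(tau1, tau2, theta_anc, tau3)`; the best-likelihood scale is kept
#'   (default 1: no profiling).
#' @param max_iter,tol EM stopping rule (default 200 iterations, dLL < 1e-6).
#' @return object of class `"coalhmm_fit"`: fitted `params`, `loglik`,
#'   `trace`, `converged`, `scale`.
#' @export
fit_hmm_em <- function(x, init, scale_grid = 1, max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(init, "coalhmm_params"))
  idx <- if (is.matrix(x)) pattern_index(x, init$taxa) else as.integer(x)
  if (length(idx) < 1000L) stop("alignment too short to fit the HMM (need >= 1000 sites)")
  ok <- !is.na(idx)
  if (length(unique(idx[ok])) <= 1L)
    stop("degenerate alignment (constant or empty); no fit")
  best <- NULL
  for (m in scale_grid) {
    p <- coalhmm_params(init$tau1 * m, init$tau2 * m, init$theta_anc * m,
                        init$s, as.numeric(init$pi), tau3 = init$tau3 * m,
                        taxa = init$taxa)
    f <- baum_welch_spi(idx, p, max_iter, tol)
    if (is.null(best) || f$loglik > best$loglik) { best <- f; best$scale <- m }
  }
  class(best) <- "coalhmm_fit"
  best
}

baum_welch_spi <- function(idx, params, max_iter, tol) {
  L <- length(idx)
  E <- params$emission
  e <- matrix(1, 4L, L)
  ok <- !is.na(idx)
  e[, ok] <- E[, idx[ok]]
  s <- params$s; pi <- as.numeric(params$pi)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## forward-backward with current (s, pi)
    alpha <- matrix(0, 4L, L); cvec <- numeric(L)
    a <- pi * e[, 1L]; cvec[1L] <- sum(a); alpha[, 1L] <- a / cvec[1L]
    for (t in 2L:L) {
      ap <- alpha[, t - 1L]
      a <- e[, t] * ((1 - s) * ap + s * pi)
      cvec[t] <- sum(a); alpha[, t] <- a / cvec[t]
    }
    beta <- matrix(0, 4L, L); beta[, L] <- 1
    Amat <- (1 - s) * diag(4L) + s * matrix(pi, 4L, 4L, byrow = TRUE)
    for (t in (L - 1L):1L) {
      bn <- beta[, t + 1L] * e[, t + 1L]
      beta[, t] <- ((1 - s) * bn + s * sum(pi * bn)) / cvec[t + 1L]
    }
    ## expected transition counts: xi_t(i,j) ~ alpha_i(t) A_ij bn_j(t+1)/c_{t+1}
    BNc <- beta * e
    BNc <- sweep(BNc, 2L, cvec, "/")
    X <- (alpha[, -L, drop = FALSE] %*% t(BNc[, -1L, drop = FALSE])) * Amat
    ll <- sum(log(cvec))
    trace <- c(trace, ll)
    g1 <- alpha[, 1L] * beta[, 1L]; g1 <- g1 / sum(g1)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    ## M-step: numeric maximisation of Q over (logit s, pi with pi3 = pi4)
    qfun <- function(par) {
      ss <- stats::plogis(par[1L])
      w <- exp(c(par[2L], par[3L], par[4L], par[4L]))
      pp <- w / sum(w)
      Am <- (1 - ss) * diag(4L) + ss * matrix(pp, 4L, 4L, byrow = TRUE)
      -(sum(X * log(Am)) + sum(g1 * log(pp)))
    }
    par0 <- c(stats::qlogis(s), log(pi[1L]), log(pi[2L]), log(pi[3L]))
    op <- stats::optim(par0, qfun, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
    s <- stats::plogis(op$par[1L])
    w <- exp(c(op$par[2L], op$par[3L], op$par[4L], op$par[4L]))
    pi <- w / sum(w)
  }
  params_out <- coalhmm_params(params$tau1, params$tau2, params$theta_anc,
                               s, pi, tau3 = params$tau3, taxa = params$taxa)
  list(params = params_out, loglik = ll, trace = trace,
       converged = converged, iterations = length(trace))
}

#' @export
print.coalhmm_fit <- function(x, ...) {
  cat(sprintf("Coalescent HMM fit: loglik = %.3f after %d EM iterations%s\n",
              x$loglik, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  print(x$params)
  invisible(x)
}

#' @export
logLik.coalhmm_fit <- function(object, ...) {
  structure(object$loglik, df = 4L, class = "logLik")
}

#' Call ILS sites from HMM posteriors
#'
#' A site is ILS when the posterior mass of the two topology-discordant
#' genealogies (type2 + type3) exceeds the threshold.
#'
#' @param posterior L x 4 posterior matrix from [forward_backward].
#' @param threshold posterior threshold (default 0.5).
#' @return logical vector of length L.
#' @export
call_ils_sites <- function(posterior, threshold = 0.5) {
  stopifnot(ncol(posterior) == 4L)
  (posterior[, 3L] + posterior[, 4L]) > threshold
}

#' Merge called sites into segments
#'
#' Maximal runs of `TRUE` sites become half-open `[start, end)` intervals
#' (0-based); runs separated by at most `max_gap` uncalled sites are fused.
#'
#' @param calls logical vector.
#' @param max_gap maximum uncalled gap to bridge (default 0).
#' @param offset added to coordinates (e.g. window start).
#' @return data.frame with `start`, `end` (possibly 0 rows).
#' @export
merge_segments <- function(calls, max_gap = 0L, offset = 0L) {
  r <- rle(as.logical(calls))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  seg <- cbind(starts[r$values], ends[r$values])
  if (is.null(dim(seg)) || nrow(seg) == 0L)
    return(data.frame(start = integer(), end = integer()))
  if (max_gap > 0L && nrow(seg) > 1L) {
    out <- seg[1L, , drop = FALSE]
    for (i in 2L:nrow(seg)) {
      if (seg[i, 1L] - out[nrow(out), 2L] <= max_gap)
        out[nrow(out), 2L] <- seg[i, 2L]
      else out <- rbind(out, seg[i, ])
    }
    seg <- out
  }
  data.frame(start = seg[, 1L] + offset, end = seg[, 2L] + offset)
}

#' Segment-level ILS statistics
#'
#' Mean/median lengths of ILS and non-ILS segments, Welch's t test between
#' the two length samples, the genome fraction covered by ILS, and the
#' fraction of coding sequence covered by ILS.
#'
#' @param segments ILS segments (data.frame `start`, `end`, half-open).
#' @param non_ils_segments complementary segments, same format.
#' @param genome_len total genome length (bp, > 0).
#' @param cds_intervals optional CDS intervals (data.frame `start`, `end`).
#' @return list with `n`, `mean_len`, `median_len`, the same for non-ILS,
#'   `genome_fraction`, `coding_fraction` (NA without CDS), `welch_t`,
#'   `welch_p`.
#' @export
segment_stats <- function(segments, non_ils_segments, genome_len,
                          cds_intervals = NULL) {
  if (genome_len <= 0) stop("genome length must be positive")
  len_i <- segments$end - segments$start
  len_n <- non_ils_segments$end - non_ils_segments$start
  wt <- welch_guarded(len_i, len_n)
  coding <- NA_real_
  if (!is.null(cds_intervals) && nrow(cds_intervals)) {
    cds <- as.matrix(cds_intervals[, c("start", "end")])
    ov <- intervals_overlap_len(as.matrix(segments[, c("start", "end")]), cds)
    coding <- ov / sum(cds[, 2L] - cds[, 1L])
  }
  list(n = length(len_i), mean_len = mean(len_i), median_len = stats::median(len_i),
       n_non_ils = length(len_n), mean_len_non_ils = mean(len_n),
       median_len_non_ils = stats::median(len_n),
       genome_fraction = sum(len_i) / genome_len,
       coding_fraction = coding,
       welch_t = wt$statistic, welch_p = wt$p.value)
}

welch_guarded <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L ||
      (stats::sd(x) == 0 && stats::sd(y) == 0)) {
    eq <- length(x) && length(y) && mean(x) == mean(y)
    return(list(statistic = if (eq) 0 else NA_real_,
                p.value = if (eq) 1 else NA_real_))
  }
  t <- stats::t.test(x, y)
  list(statistic = unname(t$statistic), p.value = t$p.value)
}

#' Per-chromosome ILS density and the X-vs-autosome contrast
#'
#' Density is ILS bp per Mb per chromosome. The X is compared to the
#' autosome distribution with a one-sample Wilcoxon test (autosome
#' densities against the X density as location), and summarised by the
#' ratio of the X density to the median autosome density.
#'
#' @param segments data.frame `chrom`, `start`, `end`.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param chrom_class named character vector, `"autosome"` or `"X"`.
#' @return list with `density` (named, bp/Mb), `ratio_x_autosome`, `p`.
#' @export
chrom_aggregation <- function(segments, chrom_lengths, chrom_class) {
  stopifnot(all(names(chrom_lengths) %in% names(chrom_class)) ||
            all(names(chrom_class) %in% names(chrom_lengths)))
  if (!any(chrom_class == "X")) stop("no X chromosome in chrom_class")
  dens <- vapply(names(chrom_lengths), function(ch) {
    sel <- segments$chrom == ch
    sum(segments$end[sel] - segments$start[sel]) / chrom_lengths[[ch]] * 1e6
  }, 0)
  xch <- names(chrom_class)[chrom_class == "X"][1L]
  auto <- dens[names(chrom_class)[chrom_class == "autosome"]]
  if (all(dens == 0))
    return(list(density = dens, ratio_x_autosome = NA_real_, p = NA_real_,
                degenerate = TRUE))
  ratio <- dens[[xch]] / stats::median(auto)
  p <- if (all(abs(auto - dens[[xch]]) < 1e-12)) 1 else
    tryCatch(stats::wilcox.test(auto, mu = dens[[xch]], exact = FALSE)$p.value,
             error = function(e) NA_real_)
  list(density = dens, ratio_x_autosome = ratio, p = p, degenerate = FALSE)
}

#' Simulate a self-consistent genealogy mosaic from the HMM
#'
#' Draws a hidden state path from the HMM's own Markov chain and emits
#' site patterns from the per-state JC69 pattern distributions: the
#' site-level analogue of the window simulator, used to benchmark posterior
#' decoding. Tract lengths are geometric with mean `1/s` (up to the chance
#' of redrawing the same state).
#'
#' @param params a [coalhmm_params].
#' @param n_sites number of sites.
#' @param seed optional seed.
#' @return list with `aln` (4 x n character matrix) and `states` (integer
#'   vector, 1 = type0 .. 4 = type3).
#' @export
simulate_mosaic <- function(params, n_sites, seed = NULL) {
  run <- function() {
    s <- params$s; pi <- as.numeric(params$pi)
    redraw <- c(TRUE, stats::runif(n_sites - 1L) < s)
    ridx <- which(redraw)
    newstates <- sample.int(4L, length(ridx), replace = TRUE, prob = pi)
    states <- newstates[findInterval(seq_len(n_sites), ridx)]
    pat <- integer(n_sites)
    for (k in 1:4) {
      sel <- states == k
      if (any(sel))
        pat[sel] <- sample.int(256L, sum(sel), replace = TRUE,
                               prob = params$emission[k, ])
    }
    aln <- matrix("", 4L, n_sites, dimnames = list(params$taxa, NULL))
    for (i in 1:4)
      aln[i, ] <- DNA_BASES[((pat - 1L) %/% 4L^(i - 1L)) %% 4L + 1L]
    list(aln = aln, states = states)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
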