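#' ABBA / BABA site-pattern counts for a four-taxon alignment
#'
#' Counts biallelic site patterns in taxon order `(P1, P2, P3, O)` with the
#' outgroup allele taken as ancestral ("A"). An ABBA site has the derived
#' allele in P2 and P3; a BABA site has it in P1 and P3. Columns containing
#' gaps or ambiguity codes, more than two alleles, or an outgroup allele not
#' shared with the ingroup are excluded.
#'
#' @param aln character matrix with (at least) the four taxa as rows.
#' @param order character vector `(P1, P2, P3, O)`.
#' @return integer vector `c(ABBA = , BABA = )`.
#' @export
count_patterns_4taxon <- function(aln, order) {
  if (length(order) != 4L) stop("need exactly 4 taxa (P1, P2, P3, O)")
  if (!all(order %in% rownames(aln))) stop("taxa missing from alignment")
  m <- toupper(aln[order, , drop = FALSE])
  ok <- colSums(matrix(m %in% DNA_BASES, nrow = 4L)) == 4L
  m <- m[, ok, drop = FALSE]
  anc <- m[4L, ]
  d <- m[1:3, , drop = FALSE] != matrix(anc, 3L, ncol(m), byrow = TRUE)
  ## biallelic: every derived state must be one common allele
  der <- ifelse(d[1L, ], m[1L, ], ifelse(d[2L, ], m[2L, ], m[3L, ]))
  bi <- (!d[1L, ] | m[1L, ] == der) & (!d[2L, ] | m[2L, ] == der) &
    (!d[3L, ] | m[3L, ] == der)
  d <- d[, bi, drop = FALSE]
  abba <- sum(!d[1L, ] & d[2L, ] & d[3L, ])
  baba <- sum(d[1L, ] & !d[2L, ] & d[3L, ])
  c(ABBA = abba, BABA = baba)
}

#' The ABBA-BABA D statistic
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`; zero expected under incomplete
#' lineage sorting alone, non-zero under gene flow between P3 and one of
#' P1/P2.
#'
#' @param abba,baba non-negative counts.
#' @return D in `[-1, 1]`.
#' @export
d_stat <- function(abba, baba) {
  if (abba + baba == 0) stop("D undefined: no ABBA or BABA sites")
  (abba - baba) / (abba + baba)
}

#' Weighted block jackknife for the D statistic
#'
#' Computes the genome-wide D from total counts and its standard error by
#' the delete-one weighted block jackknife (Busing et al. 1999), with block
#' weights proportional to their informative-site counts. Significance uses
#' the conventional `|Z| > 3` rule.
#'
#' @param abba,baba per-block ABBA and BABA counts (length >= 2).
#' @param weights per-block weights (default `abba + baba`).
#' @return list with `D`, `SE`, `Z`, `significant`, `n_blocks`;
#'   `Z` is `Inf` (flagged) when the per-block D is constant.
#' @export
weighted_block_jackknife <- function(abba, baba, weights = NULL) {
  G <- length(abba)
  if (G < 2L) stop("need at least 2 blocks")
  stopifnot(length(baba) == G)
  m <- weights %||% (abba + baba)
  if (any(m <= 0)) stop("each block needs positive weight (informative sites)")
  n <- sum(m)
  D <- d_stat(sum(abba), sum(baba))
  Dj <- vapply(seq_len(G), function(j) d_stat(sum(abba[-j]), sum(baba[-j])), 0)
  h <- n / m
  theta_J <- G * D - sum((1 - m / n) * Dj)
  tau <- h * D - (h - 1) * Dj          # pseudovalues
  v <- sum((tau - theta_J)^2 / (h - 1)) / G
  SE <- sqrt(v)
  Z <- if (SE == 0) Inf * sign(D + (D == 0)) else D / SE
  list(D = D, SE = SE, Z = Z, significant = abs(Z) > 3,
       degenerate = SE == 0, n_blocks = G)
}

#' Permutation test for contiguity of flagged windows
#'
#' Tests whether flagged windows (e.g. windows with an introgression signal)
#' cluster along the genome. The statistic is the number of adjacent flagged
#' pairs; its null distribution comes from placing the same number of flags
#' uniformly at random.
#'
#' @param flagged integer indices of flagged windows.
#' @param n_windows total number of windows.
#' @param n_perm number of random placements (default 2000).
#' @return list with `observed` (adjacent pairs), `p` (fraction of
#'   placements with >= observed adjacency), `expected` (null mean).
#' @export
contiguity_test <- function(flagged, n_windows, n_perm = 2000L) {
  k <- length(flagged)
  if (k == 0L || k >= n_windows)
    stop("contiguity undefined: need 0 < n_flagged < n_windows")
  runs <- function(idx) sum(diff(sort(idx)) == 1L)
  obs <- runs(flagged)
  null <- vapply(seq_len(n_perm), function(i)
    runs(sample.int(n_windows, k)), 0L)
  list(observed = obs, p = mean(null >= obs), expected = mean(null))
}
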