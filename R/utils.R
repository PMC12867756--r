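#' Derive per-window random seeds from one master seed
#'
#' Windows are simulated on independent substreams so that results do not
#' depend on the order in which windows are generated. Substream seeds are
#' drawn once from the master seed and indexed by window number.
#'
#' @param master integer master seed.
#' @param n number of substreams.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(master, n) {
  if (n == 0L) return(integer(0))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master))
  sample.int(2147483646L, n, replace = TRUE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Run an expression under a fixed seed, restoring the RNG state afterwards
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

## total length of the intersection of two sets of disjoint sorted
## half-open intervals, given as 2-column matrices (start, end)
intervals_overlap_len <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1L], b[, 1L])
    e <- pmin(a[i, 2L], b[, 2L])
    tot <- tot + sum(pmax(0, e - s))
  }
  tot
}

`%||%` <- function(x, y) if (is.null(x)) y else x
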