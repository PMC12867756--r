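#' Fraction of a gene's coding sequence covered by ILS segments
#'
#' Coverage is the summed overlap between the (disjoint, sorted) segments
#' and the gene's CDS intervals, divided by the total CDS length; computed
#' in genome coordinates, strand-agnostic. Bases of a segment falling in
#' introns do not count.
#'
#' @param segments data.frame `start`, `end` (optionally `chrom`), 0-based
#'   half-open.
#' @param gene gene-model rows for one gene (columns `chrom`, `start`,
#'   `end`; one row per CDS interval).
#' @return fraction in `[0, 1]`.
#' @export
cds_coverage <- function(segments, gene) {
  cds_len <- sum(gene$end - gene$start)
  if (cds_len <= 0) stop("gene has zero CDS length")
  if (!nrow(segments)) return(0)
  seg <- segments
  if ("chrom" %in% names(seg) && "chrom" %in% names(gene))
    seg <- seg[seg$chrom %in% gene$chrom, , drop = FALSE]
  ov <- intervals_overlap_len(as.matrix(seg[, c("start", "end")]),
                              as.matrix(gene[, c("start", "end")]))
  ov / cds_len
}

#' Filter genes by ILS coverage of their coding sequence
#'
#' Retains genes whose CDS coverage strictly exceeds `min_frac` (a gene
#' covered exactly at the threshold is dropped), sorted by decreasing
#' coverage.
#'
#' @param coverages named numeric vector of per-gene CDS coverage fractions.
#' @param min_frac threshold (default 0.30).
#' @return data.frame `gene`, `coverage`, sorted by decreasing coverage.
#' @export
filter_ils_genes <- function(coverages, min_frac = 0.30) {
  keep <- coverages > min_frac
  out <- data.frame(gene = names(coverages)[keep],
                    coverage = unname(coverages[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$coverage), , drop = FALSE]
}

#' Compute per-gene ILS CDS coverage for a gene-model table
#'
#' @param segments ILS segments (`chrom`, `start`, `end`).
#' @param gene_models gene-model data.frame (`gene`, `chrom`, `start`, `end`).
#' @return named numeric vector of coverages, one per gene.
#' @export
gene_cds_coverages <- function(segments, gene_models) {
  genes <- unique(gene_models$gene)
  vapply(stats::setNames(genes, genes), function(g)
    cds_coverage(segments, gene_models[gene_models$gene == g, , drop = FALSE]), 0)
}

#' Scan a protein alignment for group-diagnostic shared residues
#'
#' Flags alignment columns where every taxon of the focal group (A union B,
#' e.g. the lineages sharing an ILS genotype) carries one residue and every
#' other taxon carries a single, different residue. Columns containing a
#' gap (`-`, `X`, `*`) in any taxon are skipped; the scan is symmetric in
#' the two group definitions.
#'
#' @param aln character matrix of aligned amino acids, rows = taxa.
#' @param group_ab taxa of the focal group.
#' @param others remaining taxa (must be disjoint from `group_ab`).
#' @return data.frame `column`, `residue_group`, `residue_other` (0 rows if
#'   nothing is diagnostic).
#' @export
shared_residue_scan <- function(aln, group_ab, others) {
  if (length(intersect(group_ab, others))) stop("groups must be disjoint")
  if (!length(group_ab) || !length(others)) stop("groups must be non-empty")
  if (!all(c(group_ab, others) %in% rownames(aln)))
    stop("group taxa missing from alignment")
  a <- toupper(aln[group_ab, , drop = FALSE])
  b <- toupper(aln[others, , drop = FALSE])
  bad <- c("-", "X", "*", ".", "?")
  gapfree <- colSums(matrix(a %in% bad, nrow = nrow(a))) == 0 &
             colSums(matrix(b %in% bad, nrow = nrow(b))) == 0
  fixed_a <- apply(a, 2L, function(col) length(unique(col)) == 1L)
  fixed_b <- apply(b, 2L, function(col) length(unique(col)) == 1L)
  ra <- a[1L, ]; rb <- b[1L, ]
  hit <- gapfree & fixed_a & fixed_b & ra != rb
  data.frame(column = which(hit), residue_group = ra[hit],
             residue_other = rb[hit], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Simulate a protein alignment with planted diagnostic columns
#'
#' Background columns share one residue across all taxa (with sparse random
#' noise in single taxa); at each planted column the focal group receives
#' one residue and all other taxa a different one -- the "shared genotype"
#' structure the residue scan is designed to recover.
#'
#' @param group_ab,others taxon labels of the two groups.
#' @param n_col alignment length.
#' @param planted integer columns to plant (default none).
#' @param noise per-cell probability of a private random substitution in
#'   non-planted columns (default 0.02).
#' @param seed optional seed.
#' @return character matrix of amino acids.
#' @export
simulate_protein_alignment <- function(group_ab, others, n_col,
                                       planted = integer(0), noise = 0.02,
                                       seed = NULL) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  taxa <- c(group_ab, others)
  run <- function() {
    base <- sample(aa, n_col, replace = TRUE)
    m <- matrix(rep(base, each = length(taxa)), nrow = length(taxa),
                dimnames = list(taxa, NULL))
    ## sparse private noise, never inside planted columns and never making a
    ## column fixed-different between the groups
    for (i in seq_along(taxa)) {
      hit <- which(stats::runif(n_col) < noise)
      hit <- setdiff(hit, planted)
      if (length(hit))
        m[i, hit] <- vapply(base[hit], function(b) sample(setdiff(aa, b), 1L), "")
    }
    for (cc in planted) {
      pairres <- sample(aa, 2L)
      m[group_ab, cc] <- pairres[1L]
      m[others, cc] <- pairres[2L]
    }
    m
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
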