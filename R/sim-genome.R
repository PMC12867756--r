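#' Configuration for a synthetic multilocus simulation
#'
#' Bundles the knobs of [simulate_genome]: total number of windows, window
#' length, population-scaled mutation rate, master seed, chromosome layout,
#' and optional gene models to embed. Identical configurations (including
#' the seed) produce bitwise-identical outputs.
#'
#' @param n_windows total number of non-overlapping windows.
#' @param window_len window length in bp (>= 1).
#' @param theta population-scaled mutation rate per site (default 0.01).
#' @param seed master random seed.
#' @param n_chrom number of synthetic chromosomes the windows are laid onto,
#'   end to end and as evenly as possible.
#' @param gene_models optional gene-model data.frame (columns
#'   `gene, chrom, strand, start, end`, 0-based half-open) to embed, e.g.
#'   from [random_gene_models].
#' @param focal three taxa `(A, B, C)` defining the genealogy truth class of
#'   each window (default: the first three non-outgroup taxa at simulation
#'   time).
#' @param suppress_ils_in_cds if `TRUE`, windows overlapping a CDS are
#'   resampled until their genealogy is topology-concordant (type0/type1), a
#'   crude emulation of purifying selection purging discordant tracts from
#'   coding sequence.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_windows, window_len = 1000L, theta = 0.01,
                       seed = 1L, n_chrom = 1L, gene_models = NULL,
                       focal = NULL, suppress_ils_in_cds = FALSE) {
  stopifnot(n_windows >= 0, window_len >= 1, theta >= 0, n_chrom >= 1)
  structure(list(n_windows = as.integer(n_windows),
                 window_len = as.integer(window_len), theta = theta,
                 seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 gene_models = gene_models, focal = focal,
                 suppress_ils_in_cds = isTRUE(suppress_ils_in_cds)),
            class = "sim_config")
}

#' Simulate a windowed multi-genome alignment with known truth
#'
#' Lays `n_windows` windows end to end on synthetic chromosomes, samples one
#' MSC gene tree per window from the species network (free recombination
#' between windows, none within), evolves JC69 sequences along it, and
#' returns -- and optionally writes -- per-window alignments, a truth BED
#' (genealogy class + introgression flag per window), gene-model GFF3,
#' Newick gene trees and a YAML manifest.
#'
#' Every window runs on its own seed substream derived from the master seed,
#' so outputs are reproducible and independent of generation order.
#'
#' @param config a [sim_config].
#' @param net a [species_network].
#' @param out_dir output directory, or `NULL` to keep everything in memory.
#' @return (invisibly, when writing) a list with `truth` (data.frame:
#'   window, chrom, start, end, class, introgressed, origin), `trees`
#'   (list of [ape::phylo]), `alignments` (list of character matrices),
#'   `gene_models`, and `files` when `out_dir` is given.
#' @export
simulate_genome <- function(config, net, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(net, "species_network"))
  nw <- config$n_windows
  focal <- config$focal %||%
    utils::head(c(setdiff(net$taxa, net$outgroup), net$outgroup), 3L)

  ## chromosome layout
  per <- rep(nw %/% config$n_chrom, config$n_chrom)
  if (nw %% config$n_chrom) per[seq_len(nw %% config$n_chrom)] <- per[1L] + 1L
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), per)
  widx <- unlist(lapply(per, seq_len))
  start <- (widx - 1L) * config$window_len
  end <- widx * config$window_len

  ## which windows overlap a CDS (for the purifying-selection switch)
  in_cds <- rep(FALSE, nw)
  gm <- config$gene_models
  if (!is.null(gm) && nw > 0L) {
    for (i in seq_len(nrow(gm))) {
      hit <- chrom == gm$chrom[i] & start < gm$end[i] & end > gm$start[i]
      in_cds <- in_cds | hit
    }
  }

  seeds <- derive_seeds(config$seed, nw)
  trees <- vector("list", nw)
  alns <- vector("list", nw)
  cls <- character(nw); intro <- logical(nw); orig <- character(nw)
  for (w in seq_len(nw)) {
    g <- with_seed(seeds[w], {
      gt <- sample_gene_tree(net, focal = focal)
      if (config$suppress_ils_in_cds && in_cds[w]) {
        tries <- 0L
        while (!gt$class %in% c("type0", "type1") && tries < 200L) {
          gt <- sample_gene_tree(net, focal = focal)
          tries <- tries + 1L
        }
      }
      aln <- evolve_sequences(gt$tree, config$window_len, config$theta)
      list(gt = gt, aln = aln)
    })
    trees[[w]] <- g$gt$tree
    alns[[w]] <- g$aln
    cls[w] <- g$gt$class
    intro[w] <- isTRUE(g$gt$introgressed)
    orig[w] <- g$gt$origin %||% "none"
  }

  truth <- data.frame(window = sprintf("window_%06d", seq_len(nw)),
                      chrom = chrom, start = start, end = end,
                      class = cls, introgressed = intro, origin = orig,
                      stringsAsFactors = FALSE)
  if (nw == 0L)
    truth <- data.frame(window = character(), chrom = character(),
                        start = integer(), end = integer(), class = character(),
                        introgressed = logical(), origin = character())

  out <- list(truth = truth, trees = trees, alignments = alns,
              gene_models = gm, taxa = net$taxa, config = config)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "windows"), recursive = TRUE, showWarnings = FALSE)
    fa <- character(nw)
    for (w in seq_len(nw)) {
      fa[w] <- file.path(out_dir, "windows", paste0(truth$window[w], ".fa"))
      write_fasta(alns[[w]], fa[w])
    }
    bed <- file.path(out_dir, "truth.bed")
    write_bed(truth[, c("chrom", "start", "end", "class", "introgressed", "origin")], bed)
    gff <- file.path(out_dir, "genes.gff3")
    write_gff3(gm %||% data.frame(gene = character(), chrom = character(),
                                  strand = character(), start = integer(),
                                  end = integer()), gff)
    nwk <- file.path(out_dir, "gene_trees.nwk")
    writeLines(vapply(seq_len(nw), function(w)
      paste0(ape::write.tree(trees[[w]]), " [", truth$window[w], "]"), ""), nwk)
    manifest <- file.path(out_dir, "manifest.yaml")
    yaml::write_yaml(list(
      n_windows = nw, window_len = config$window_len, theta = config$theta,
      seed = config$seed, n_chrom = config$n_chrom, taxa = net$taxa,
      outgroup = net$outgroup, files = list(truth = "truth.bed",
        genes = "genes.gff3", trees = "gene_trees.nwk", windows = "windows/")),
      manifest)
    out$files <- list(windows = fa, truth = bed, genes = gff,
                      trees = nwk, manifest = manifest)
  }
  invisible(out)
}

#' Random gene models on a synthetic genome
#'
#' Places `n_genes` genes uniformly at random (without overlap, best effort)
#' on the given chromosome lengths, each with 1-3 CDS exons.
#'
#' @param n_genes number of genes.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param seed random seed.
#' @param exon_len,intron_len typical exon / intron sizes (bp).
#' @return gene-model data.frame (`gene, chrom, strand, start, end`).
#' @export
random_gene_models <- function(n_genes, chrom_lengths, seed = 1L,
                               exon_len = 300L, intron_len = 500L) {
  with_seed(seed, {
    rows <- list()
    occupied <- lapply(chrom_lengths, function(...) matrix(0, 0, 2))
    for (g in seq_len(n_genes)) {
      for (try in 1:50) {
        ci <- sample.int(length(chrom_lengths), 1L,
                         prob = as.numeric(chrom_lengths))
        nex <- sample.int(3L, 1L)
        span <- nex * exon_len + (nex - 1L) * intron_len
        if (span >= chrom_lengths[ci]) next
        s <- sample.int(chrom_lengths[ci] - span, 1L) - 1L
        occ <- occupied[[ci]]
        if (nrow(occ) && any(pmax(occ[, 1L], s) < pmin(occ[, 2L], s + span))) next
        occupied[[ci]] <- rbind(occ, c(s, s + span))
        starts <- s + (seq_len(nex) - 1L) * (exon_len + intron_len)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = sprintf("gene%03d", g), chrom = names(chrom_lengths)[ci],
          strand = sample(c("+", "-"), 1L), start = starts,
          end = starts + exon_len, stringsAsFactors = FALSE)
        break
      }
    }
    if (!length(rows))
      return(data.frame(gene = character(), chrom = character(),
                        strand = character(), start = integer(), end = integer()))
    do.call(rbind, rows)
  })
}
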