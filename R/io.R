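#' Read / write alignment FASTA
#'
#' Thin wrappers around ape's FASTA support returning plain uppercase
#' character matrices (rows = taxa), the alignment container used throughout
#' this package.
#'
#' @param path file path.
#' @param type `"DNA"` or `"AA"`.
#' @return `read_fasta`: character matrix with taxa as row names.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- ape::read.FASTA(path, type = type)
  m <- toupper(as.character(as.matrix(x)))
  rownames(m) <- names(x)
  m
}

#' @param aln character matrix, rows named by taxa.
#' @rdname read_fasta
#' @export
write_fasta <- function(aln, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  obj <- if (type == "DNA") ape::as.DNAbin(aln) else ape::as.AAbin(aln)
  ape::write.FASTA(obj, path)
  invisible(path)
}

#' Read / write BED intervals (0-based half-open)
#'
#' The truth track written by [simulate_genome] uses columns
#' `chrom, start, end, name, score, origin`; plain 3+ column BED files are
#' accepted on input.
#'
#' @param x data.frame whose first three columns are chrom, start, end.
#' @param path file path.
#' @export
write_bed <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param col_names names to give the columns read.
#' @export
read_bed <- function(path, col_names = NULL) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "origin")
  nm <- col_names %||% base[seq_len(min(ncol(x), length(base)))]
  names(x)[seq_along(nm)] <- nm
  x
}

#' Write / read gene models as GFF3
#'
#' Gene models are held as a data.frame with one row per CDS interval and
#' columns `gene, chrom, strand, start, end` (0-based half-open genome
#' coordinates). On disk the standard GFF3 1-based closed convention is
#' used; each gene gets a `gene` feature spanning its CDS plus the `CDS`
#' features themselves.
#'
#' @param genes gene-model data.frame (see Details).
#' @param path file path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    for (g in unique(genes$gene)) {
      gg <- genes[genes$gene == g, , drop = FALSE]
      writeLines(paste(gg$chrom[1L], "ilsrad", "gene", min(gg$start) + 1L,
                       max(gg$end), ".", gg$strand[1L], ".",
                       paste0("ID=", g), sep = "\t"), con)
      for (i in seq_len(nrow(gg)))
        writeLines(paste(gg$chrom[i], "ilsrad", "CDS", gg$start[i] + 1L,
                         gg$end[i], ".", gg$strand[i], "0",
                         paste0("ID=", g, ".cds", i, ";Parent=", g),
                         sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, function(r) r[3L] == "CDS", TRUE)]
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, "=([^;]+)"), attrs))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
  }
  data.frame(
    gene = vapply(f, function(r) {
      p <- attr_field(r[9L], "Parent")
      if (is.na(p)) attr_field(r[9L], "ID") else p
    }, ""),
    chrom = vapply(f, `[`, "", 1L),
    strand = vapply(f, `[`, "", 7L),
    start = vapply(f, function(r) as.integer(r[4L]) - 1L, 0L),
    end = vapply(f, function(r) as.integer(r[5L]), 0L))
}
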