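#' Genome assembly object
#'
#' A light container for one genome's contigs: sequences (plain uppercase
#' character vector named by contig), per-contig mean read coverage, and the
#' genome label. Coordinates throughout the package are 1-based inclusive.
#'
#' @param genome genome label (single string).
#' @param seqs named character vector of contig sequences.
#' @param coverage named numeric vector of per-contig mean depths; names must
#'   match `names(seqs)`.
#' @return a `genome_assembly` object.
#' @export
genome_assembly <- function(genome, seqs, coverage = NULL) {
  if (inherits(seqs, "XStringSet")) seqs <- as.character(seqs)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) abort("contig ids must be unique")
  seqs <- toupper(seqs)
  bad <- stringr::str_locate(seqs, "[^ACGTN]")[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf("non-ACGTN character in contig '%s' at position %d",
                  names(seqs)[i], bad[i]))
  }
  if (is.null(coverage)) coverage <- setNames(rep(NA_real_, length(seqs)), names(seqs))
  if (!all(names(seqs) %in% names(coverage))) {
    abort("coverage must provide a value for every contig")
  }
  coverage <- coverage[names(seqs)]
  if (any(!is.na(coverage) & coverage < 0)) abort("coverage must be nonnegative")
  structure(list(genome = genome, seqs = seqs, coverage = coverage),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly>", x$genome, "-", length(x$seqs), "contigs,",
      sum(nchar(x$seqs)), "bp\n")
  invisible(x)
}

#' Contig summary of an assembly
#'
#' @param assembly a [genome_assembly()].
#' @return tibble with contig, length and coverage.
#' @export
contig_table <- function(assembly) {
  tibble(genome = assembly$genome,
         contig = names(assembly$seqs),
         length = nchar(assembly$seqs),
         coverage = unname(assembly$coverage))
}

#' Attach CDS and protein sequences to a gene table
#'
#' Extracts each gene's nucleotide sequence from its contig. Minus-strand
#' genes are stored reverse-complemented so every CDS is in reading frame;
#' the original strand is retained. Genes whose length is not a multiple of
#' three are flagged `partial` and excluded from codon-level analyses.
#'
#' @param assembly a [genome_assembly()].
#' @param genes tibble with columns genome, contig, gene_id, start, end,
#'   strand (`+`/`-`), product. Coordinates 1-based inclusive.
#' @return the gene tibble with `cds`, `protein` and `partial` columns.
#' @export
extract_genes <- function(assembly, genes) {
  stopifnot(all(c("contig", "gene_id", "start", "end", "strand") %in% names(genes)))
  missing <- setdiff(unique(genes$contig), names(assembly$seqs))
  if (length(missing)) {
    g <- genes$gene_id[genes$contig %in% missing][1]
    abort(sprintf("gene '%s' refers to contig '%s' absent from assembly '%s'",
                  g, genes$contig[genes$gene_id == g][1], assembly$genome))
  }
  clen <- nchar(assembly$seqs)[genes$contig]
  bad <- which(genes$start < 1 | genes$end > clen | genes$start > genes$end)
  if (length(bad)) {
    abort(sprintf("gene '%s' has coordinates outside contig '%s' (length %d)",
                  genes$gene_id[bad[1]], genes$contig[bad[1]], clen[bad[1]]))
  }
  cds <- substring(assembly$seqs[genes$contig], genes$start, genes$end)
  minus <- genes$strand == "-"
  if (any(minus)) cds[minus] <- revcomp(cds[minus])
  partial <- (nchar(cds) %% 3L) != 0L
  if ("partial" %in% names(genes)) partial <- partial | genes$partial
  genes$cds <- unname(cds)
  genes$partial <- partial
  genes$protein <- ifelse(partial, NA_character_,
                          vapply(cds, translate_cds, character(1), USE.NAMES = FALSE))
  genes
}

# named character vector of proteins (gene_id -> aa) for non-partial genes,
# trailing stop removed
proteome_of <- function(genes) {
  g <- genes[!genes$partial & !is.na(genes$protein), ]
  p <- sub("\\*$", "", g$protein)
  keep <- !grepl("*", p, fixed = TRUE) & nchar(p) > 0
  setNames(p[keep], g$gene_id[keep])
}
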