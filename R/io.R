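# Readers/writers for the on-disk formats: FASTA (Biostrings), FASTQ, gene
# and coverage TSVs, alignments, trees (ape), stage reports stamped with the
# configuration hash.

GENE_COLS <- c("genome", "contig", "gene_id", "start", "end", "strand", "product")

#' Read a genome bundle (assembly FASTA + coverage TSV + gene TSV)
#'
#' @param assembly_path FASTA of contigs.
#' @param coverage_path TSV with columns `contig`, `coverage` (mean depth).
#' @param genes_path TSV with columns genome, contig, gene_id, start, end,
#'   strand, product (1-based inclusive coordinates).
#' @param genome genome label; defaults to the gene table's genome.
#' @return list with `assembly` ([genome_assembly()]) and `genes` tibble
#'   carrying cds/protein/partial columns (see [extract_genes()]).
#' @export
read_genome_bundle <- function(assembly_path, coverage_path, genes_path,
                               genome = NULL) {
  seqs <- Biostrings::readDNAStringSet(assembly_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  cov <- readr::read_tsv(coverage_path, show_col_types = FALSE)
  stopifnot(all(c("contig", "coverage") %in% names(cov)))
  genes <- readr::read_tsv(genes_path, show_col_types = FALSE,
                           col_types = readr::cols(start = "i", end = "i"))
  stopifnot(all(GENE_COLS %in% names(genes)))
  if (is.null(genome)) genome <- genes$genome[1] %||% "genome"
  asm <- genome_assembly(genome, as.character(seqs),
                         setNames(cov$coverage, cov$contig))
  list(assembly = asm, genes = extract_genes(asm, genes))
}

#' Write a genome bundle to a directory
#'
#' Emits `<genome>.fasta`, `<genome>.coverage.tsv` and `<genome>.genes.tsv`.
#'
#' @param bundle list with `assembly` and `genes` as from [read_genome_bundle()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three paths.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- bundle$assembly$genome
  fa <- file.path(dir, paste0(g, ".fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$assembly$seqs), fa)
  covp <- file.path(dir, paste0(g, ".coverage.tsv"))
  readr::write_tsv(tibble(contig = names(bundle$assembly$seqs),
                          coverage = unname(bundle$assembly$coverage)), covp)
  gp <- file.path(dir, paste0(g, ".genes.tsv"))
  readr::write_tsv(bundle$genes[intersect(c(GENE_COLS, "partial"), names(bundle$genes))], gp)
  invisible(c(fa, covp, gp))
}

#' Read/write multiple sequence alignments as FASTA
#'
#' @param path FASTA file.
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  as_aln(setNames(as.character(x), sub("\\s.*$", "", names(x))))
}

#' @rdname read_alignment
#' @param aln named character vector (equal lengths).
#' @export
write_alignment <- function(aln, path) {
  aln <- as_aln(aln)
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln), path)
  invisible(path)
}

#' Write / read paired read sets as FASTQ
#'
#' Reads are stored as a long tibble (`read_id`, `mate`, `seq`). Qualities are
#' constant (error-free simulation); on reading they are dropped.
#'
#' @param reads tibble with read_id, mate (1/2), seq.
#' @param prefix file prefix; writes `<prefix>_1.fastq` / `<prefix>_2.fastq`.
#' @return invisibly the paths (write) or the tibble (read).
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- character(2)
  for (m in 1:2) {
    r <- reads[reads$mate == m, ]
    dss <- Biostrings::DNAStringSet(setNames(r$seq, r$read_id))
    qual <- Biostrings::BStringSet(strrep("I", nchar(r$seq)))
    p <- paste0(prefix, "_", m, ".fastq")
    Biostrings::writeQualityScaledXStringSet(
      Biostrings::QualityScaledDNAStringSet(dss, Biostrings::PhredQuality(qual)), p)
    paths[m] <- p
  }
  invisible(paths)
}

#' @rdname write_fastq_pair
#' @export
read_fastq_pair <- function(prefix) {
  out <- list()
  for (m in 1:2) {
    x <- Biostrings::readDNAStringSet(paste0(prefix, "_", m, ".fastq"), format = "fastq")
    out[[m]] <- tibble(read_id = sub("\\s.*$", "", names(x)), mate = m,
                       seq = unname(as.character(x)))
  }
  dplyr::arrange(bind_rows(out), .data$read_id, .data$mate)
}

#' Stage reports stamped with the configuration hash
#'
#' Reports are TSV files whose first line is a comment `#config_hash=<hash>`;
#' two runs under identical configurations and inputs produce byte-identical
#' reports.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param config a [pipeline_config()] (or any object to hash).
#' @export
write_stage_report <- function(df, path, config) {
  con <- file(path, open = "wb")
  writeLines(paste0("#config_hash=", config_hash(config)), con)
  close(con)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_stage_report
#' @return for the reader, the tibble with attribute `config_hash`.
#' @export
read_stage_report <- function(path) {
  first <- readLines(path, n = 1)
  hash <- sub("^#config_hash=", "", first)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  attr(df, "config_hash") <- hash
  df
}

#' Import a gene table from GFF3
#'
#' Thin adapter mapping GFF3 CDS features onto the package's fixed-column
#' gene table.
#'
#' @param path GFF3 file.
#' @param genome genome label to assign.
#' @return gene tibble (genome, contig, gene_id, start, end, strand, product).
#' @export
read_gff_genes <- function(path, genome = "genome") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 1L) == 9]
  m <- do.call(rbind, f)
  keep <- m[, 3] %in% c("CDS", "gene")
  m <- m[keep, , drop = FALSE]
  attr_field <- function(a, key) {
    v <- stringr::str_match(a, paste0(key, "=([^;]+)"))[, 2]
    v
  }
  ids <- attr_field(m[, 9], "ID")
  ids[is.na(ids)] <- paste0("gene", seq_len(sum(is.na(ids))))
  prod <- attr_field(m[, 9], "product")
  tibble(genome = genome, contig = m[, 1], gene_id = ids,
         start = as.integer(m[, 4]), end = as.integer(m[, 5]),
         strand = ifelse(m[, 7] == "-", "-", "+"),
         product = ifelse(is.na(prod), "hypothetical protein", prod))
}
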