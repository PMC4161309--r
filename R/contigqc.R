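# Contig quality control for single amplified genome assemblies: the three
# exclusion criteria (length, length+coverage+homology, bacterial homology),
# redundancy removal, and completeness estimation against a minimal
# essential gene set.

# does a contig have a translated-search hit vs a protein panel at E <= cutoff?
has_translated_hit <- function(contig_seq, panel, e_cutoff = 1e-5) {
  if (!length(panel)) return(NA)
  frames <- six_frames(contig_seq)
  frames <- frames[nchar(frames) >= 10]
  if (!length(frames)) return(FALSE)
  db_n <- sum(nchar(panel))
  for (p in panel) {
    sc <- protein_scores(frames, p)
    e <- ka_evalue(max(sc), max(nchar(frames)), db_n)
    if (e <= e_cutoff) return(TRUE)
  }
  FALSE
}

#' Apply the three contig-exclusion criteria
#'
#' A contig is removed if (i) it is shorter than 250 bp; (ii) it is shorter
#' than 500 bp and either its read coverage is below 5x or it has no
#' translated-search hit against the reference proteome (E <= 1e-5); or
#' (iii) it has no translated-search hit against the bacterial panel.
#' Rules are applied in that order and each contig gets exactly one reason.
#'
#' @param assembly a [genome_assembly()].
#' @param reference_proteome named character vector of reference proteins.
#' @param bacterial_panel named character vector of bacterial proteins
#'   (NULL or empty skips rule iii with a warning).
#' @param config a [pipeline_config()] (thresholds are fixed by convention;
#'   config supplies nothing here but is accepted for uniformity).
#' @param e_cutoff translated-search E-value gate.
#' @return tibble of contig verdicts: contig, length, coverage, retained,
#'   reason in {short, short_lowcov_nohit, no_bacterial_hit, pass}.
#' @export
filter_contigs <- function(assembly, reference_proteome, bacterial_panel,
                           config = pipeline_config(), e_cutoff = 1e-5) {
  ct <- contig_table(assembly)
  reason <- rep("pass", nrow(ct))
  skip_iii <- is.null(bacterial_panel) || !length(bacterial_panel)
  if (skip_iii) warn("empty bacterial panel: rule (iii) skipped")
  for (i in seq_len(nrow(ct))) {
    if (ct$length[i] < 250) {
      reason[i] <- "short"
      next
    }
    if (ct$length[i] < 500) {
      lowcov <- !is.na(ct$coverage[i]) && ct$coverage[i] < 5
      nohit <- !lowcov &&
        !isTRUE(has_translated_hit(assembly$seqs[[ct$contig[i]]],
                                   reference_proteome, e_cutoff))
      if (lowcov || nohit) {
        reason[i] <- "short_lowcov_nohit"
        next
      }
    }
    if (!skip_iii &&
        !isTRUE(has_translated_hit(assembly$seqs[[ct$contig[i]]],
                                   bacterial_panel, e_cutoff))) {
      reason[i] <- "no_bacterial_hit"
    }
  }
  tibble(contig = ct$contig, length = ct$length, coverage = ct$coverage,
         retained = reason == "pass", reason = reason)
}

#' Remove contigs identical to (or contained in) larger contigs
#'
#' A contig equal to, or an exact substring (either strand) of, a strictly
#' longer contig in the same assembly is removed with reason `redundant`.
#' Two identical contigs of equal length keep the lexicographically smaller
#' id.
#'
#' @param assembly a [genome_assembly()].
#' @return list with the filtered `assembly` and a `verdicts` tibble.
#' @export
remove_redundant_contigs <- function(assembly) {
  ids <- names(assembly$seqs)
  seqs <- assembly$seqs
  lens <- nchar(seqs)
  rcs <- revcomp(seqs)
  redundant <- rep(FALSE, length(ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      if (lens[j] > lens[i]) {
        if (grepl(seqs[i], seqs[j], fixed = TRUE) ||
            grepl(rcs[i], seqs[j], fixed = TRUE)) {
          redundant[i] <- TRUE
          break
        }
      } else if (lens[j] == lens[i] && ids[j] < ids[i]) {
        if (seqs[i] == seqs[j] || rcs[i] == seqs[j]) {
          redundant[i] <- TRUE
          break
        }
      }
    }
  }
  verdicts <- tibble(contig = ids, length = unname(lens),
                     retained = !redundant,
                     reason = ifelse(redundant, "redundant", "pass"))
  keep <- ids[!redundant]
  list(assembly = genome_assembly(assembly$genome, seqs[keep],
                                  assembly$coverage[keep]),
       verdicts = verdicts)
}

#' Estimate genome completeness against a minimal essential gene set
#'
#' An essential gene counts as present when its best local protein alignment
#' against the assembly's (possibly fragmentary) gene products reaches
#' `min_hit_identity` and covers at least `min_hit_coverage` of the
#' essential protein. Gene fragments are translated in all three forward
#' frames (truncation can shift the frame).
#'
#' @param genes gene tibble with `cds` (see [extract_genes()]).
#' @param essential_set named character vector of essential proteins.
#' @param min_hit_identity,min_hit_coverage gates (fractions).
#' @return tibble: genes_found, gene_set_size, fraction (percent, 1 decimal).
#' @export
estimate_completeness <- function(genes, essential_set,
                                  min_hit_identity = 0.5,
                                  min_hit_coverage = 0.5) {
  stopifnot(length(essential_set) > 0)
  frames <- unlist(lapply(genes$cds, three_frames))
  frames <- frames[nchar(frames) >= 10]
  found <- 0L
  for (p in essential_set) {
    sc <- protein_scores(frames, p)
    ord <- order(sc, decreasing = TRUE)
    hit <- FALSE
    for (i in head(ord, 3)) {
      al <- protein_local_align(frames[i], p)
      if (al$identity >= 100 * min_hit_identity && al$scov >= min_hit_coverage) {
        hit <- TRUE
        break
      }
    }
    if (hit) found <- found + 1L
  }
  tibble(genes_found = found,
         gene_set_size = length(essential_set),
         fraction = round(100 * found / length(essential_set), 1))
}
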