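# Removal of cross-library misassigned reads. Reads of one library are
# mapped (exact-seed, ungapped extension, small mismatch cap) against
# ultra-high-coverage regions of the other libraries; foreign-mapped reads
# whose pile-up depth within their own set is at or below the removal depth
# are discarded, while high-pile-up reads are kept only if they also align to
# their own assembly (conserved-region rescue).

#' Find ultra-high-coverage regions of an assembly
#'
#' Returns contigs whose mean read coverage exceeds `threshold` and that are
#' at least one read long; these are the likely sources of index-misassigned
#' reads in other libraries.
#'
#' @param assembly a [genome_assembly()].
#' @param threshold depth threshold (default 5000).
#' @param read_length minimum region length.
#' @return tibble: genome, contig, start, end, depth, seq.
#' @export
find_high_coverage_regions <- function(assembly, threshold = 5000,
                                       read_length = 76L) {
  ct <- contig_table(assembly)
  keep <- !is.na(ct$coverage) & ct$coverage > threshold & ct$length >= read_length
  tibble(genome = assembly$genome,
         contig = ct$contig[keep],
         start = 1L,
         end = ct$length[keep],
         depth = ct$coverage[keep],
         seq = unname(assembly$seqs[ct$contig[keep]]))
}

n_mismatch <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# Exact-seed (31-mer), ungapped-extension mapper. Seeds are taken at up to
# three positions per read and both strands are tried; a read maps if it lies
# fully within a target and matches with <= max_mismatches. Reports the best
# (fewest-mismatch) hit per read.
map_reads_ungapped <- function(reads, targets, max_mismatches = 2L) {
  if (!nrow(reads) || !length(targets)) {
    return(tibble(read_id = character(), mate = integer(), target = character(),
                  start = integer(), end = integer(), strand = character(),
                  mismatches = integer()))
  }
  tlen <- nchar(targets)
  rl <- max(nchar(reads$seq))
  k <- min(31L, min(nchar(reads$seq)))
  # k-mer index of targets (forward strand; reads are queried both ways)
  idx_t <- rep(seq_along(targets), pmax(0L, tlen - k + 1L))
  idx_p <- unlist(lapply(tlen, function(l) if (l >= k) seq_len(l - k + 1L) else integer(0)))
  kmers <- substring(targets[idx_t], idx_p, idx_p + k - 1L)
  first <- !duplicated(kmers)
  kmers <- kmers[first]; idx_t <- idx_t[first]; idx_p <- idx_p[first]

  seed_offsets <- unique(pmax(1L, c(1L, (rl - k) %/% 2L + 1L, rl - k + 1L)))
  queries <- bind_rows(
    tibble(qi = seq_len(nrow(reads)), strand = "+", qseq = reads$seq),
    tibble(qi = seq_len(nrow(reads)), strand = "-", qseq = revcomp(reads$seq))
  )
  best <- NULL
  mapped <- rep(FALSE, nrow(reads))
  for (off in seed_offsets) {
    todo <- which(!mapped[queries$qi])
    if (!length(todo)) break
    q <- queries[todo, ]
    ok <- nchar(q$qseq) >= off + k - 1L
    q <- q[ok, ]
    if (!nrow(q)) next
    hit <- match(substring(q$qseq, off, off + k - 1L), kmers)
    found <- which(!is.na(hit))
    if (!length(found)) next
    cand <- q[found, ]
    ti <- idx_t[hit[found]]
    st <- idx_p[hit[found]] - off + 1L
    en <- st + nchar(cand$qseq) - 1L
    inb <- st >= 1L & en <= tlen[ti]
    cand <- cand[inb, ]; ti <- ti[inb]; st <- st[inb]; en <- en[inb]
    if (!nrow(cand)) next
    mm <- mapply(function(s, t, a, b) n_mismatch(s, substring(targets[t], a, b)),
                 cand$qseq, ti, st, en, USE.NAMES = FALSE)
    pass <- mm <= max_mismatches
    if (!any(pass)) next
    res <- tibble(read_id = reads$read_id[cand$qi[pass]],
                  mate = reads$mate[cand$qi[pass]],
                  target = names(targets)[ti[pass]],
                  start = st[pass], end = en[pass],
                  strand = cand$strand[pass],
                  mismatches = as.integer(mm[pass]),
                  .qi = cand$qi[pass])
    res <- res[!duplicated(res$.qi), ]
    mapped[res$.qi] <- TRUE
    best <- bind_rows(best, res)
  }
  if (is.null(best)) {
    return(tibble(read_id = character(), mate = integer(), target = character(),
                  start = integer(), end = integer(), strand = character(),
                  mismatches = integer()))
  }
  best$.qi <- NULL
  best
}

#' Map a library's reads against another library's high-coverage regions
#'
#' Re-implementation of short-read mapping as exact 31-mer seeding with
#' ungapped extension and a mismatch cap. Each mapped read is annotated with
#' the average pile-up depth of reads *from the same set* over its footprint
#' (reads overlapping the footprint x read length / footprint length,
#' rounded to one decimal).
#'
#' @param reads tibble (read_id, mate, seq) of the library under scrutiny.
#' @param regions output of [find_high_coverage_regions()] for a *different*
#'   genome.
#' @param max_mismatches mismatch cap (default 2).
#' @return tibble of mapped reads with `pileup` column.
#' @export
cross_map_reads <- function(reads, regions, max_mismatches = 2L) {
  targets <- setNames(regions$seq, regions$contig)
  hits <- map_reads_ungapped(reads, targets, max_mismatches)
  if (!nrow(hits)) {
    hits$pileup <- numeric(0)
    hits$region_genome <- character(0)
    return(hits)
  }
  hits$pileup <- NA_real_
  for (ct in unique(hits$target)) {
    sel <- hits$target == ct
    len <- nchar(targets[[ct]])
    delta <- numeric(len + 1L)
    st <- hits$start[sel]; en <- hits$end[sel]
    for (i in seq_along(st)) {
      delta[st[i]] <- delta[st[i]] + 1
      delta[en[i] + 1L] <- delta[en[i] + 1L] - 1
    }
    depth <- cumsum(delta[seq_len(len)])
    cd <- cumsum(depth)
    tot <- cd[en] - c(0, cd)[st]
    hits$pileup[sel] <- round(tot / (en - st + 1L), 1)
  }
  hits$region_genome <- regions$genome[match(hits$target, regions$contig)]
  hits
}

#' Classify foreign-mapped reads and build a cleanup report
#'
#' Reads whose pile-up depth is at or below `depth_threshold` are removed.
#' Reads above the threshold are kept only if they align full-length,
#' ungapped, at `>= min_rescue_identity` to their own assembly (the
#' conserved-region rescue); otherwise they are removed too. Paired reads
#' are removed as pairs when either mate is classified misassigned.
#'
#' @param mapped output of [cross_map_reads()] (possibly row-bound over
#'   several foreign region sets).
#' @param reads the full read tibble of this library (read_id, mate, seq).
#' @param own_assembly this library's own [genome_assembly()].
#' @param depth_threshold removal depth (default 20).
#' @param min_rescue_identity rescue identity fraction (default 0.9).
#' @return a `cleanup_report`: list with `summary` tibble, `removed_ids`,
#'   `rescued_ids`, and the annotated `mapped` tibble.
#' @export
classify_and_remove <- function(mapped, reads, own_assembly,
                                depth_threshold = 20,
                                min_rescue_identity = 0.9) {
  mapped <- mapped[!duplicated(paste(mapped$read_id, mapped$mate)), ]
  low <- mapped$pileup <= depth_threshold
  rescue_cand <- mapped[!low, ]
  rescued <- character(0)
  if (nrow(rescue_cand)) {
    cand_reads <- dplyr::semi_join(reads, rescue_cand, by = c("read_id", "mate"))
    rl <- max(nchar(cand_reads$seq))
    allow <- floor((1 - min_rescue_identity) * rl)
    own_hits <- map_reads_ungapped(cand_reads, own_assembly$seqs,
                                   max_mismatches = allow)
    rescued <- unique(paste(own_hits$read_id, own_hits$mate))
  }
  key <- paste(mapped$read_id, mapped$mate)
  removed_mate <- key[low | !(key %in% rescued)]
  rescued <- setdiff(unique(paste(rescue_cand$read_id, rescue_cand$mate)),
                     removed_mate)
  # pair-level removal: a pair goes if either mate is removed
  removed_pairs <- unique(sub(" .*$", "", removed_mate))
  rescued_pairs <- setdiff(unique(sub(" .*$", "", rescued)), removed_pairs)
  all_pairs <- unique(reads$read_id)
  summary <- tibble(
    total_pairs = length(all_pairs),
    mapped_reads = nrow(mapped),
    removed_pairs = length(removed_pairs),
    rescued_pairs = length(rescued_pairs)
  )
  structure(list(summary = summary,
                 removed_ids = removed_pairs,
                 rescued_ids = rescued_pairs,
                 mapped = mapped),
            class = "cleanup_report")
}

#' @export
print.cleanup_report <- function(x, ...) {
  cat("<cleanup_report>", x$summary$removed_pairs, "of", x$summary$total_pairs,
      "pairs removed;", x$summary$rescued_pairs, "rescued\n")
  invisible(x)
}

#' Apply a cleanup report to a read set
#'
#' @param reads read tibble (read_id, mate, seq).
#' @param report a `cleanup_report`.
#' @return the read tibble without removed pairs.
#' @export
apply_cleanup <- function(reads, report) {
  reads[!(reads$read_id %in% report$removed_ids), ]
}

#' Run the full cleanup for one library against all others
#'
#' @param reads this library's reads (read_id, mate, seq).
#' @param own_assembly this library's assembly.
#' @param foreign_assemblies named list of the other libraries' assemblies.
#' @param config a [pipeline_config()].
#' @return a `cleanup_report`.
#' @export
clean_read_set <- function(reads, own_assembly, foreign_assemblies, config) {
  mapped <- purrr::map_dfr(foreign_assemblies, function(asm) {
    regions <- find_high_coverage_regions(asm, config$coverage_region_threshold,
                                          config$read_length %||% 76L)
    if (!nrow(regions)) return(tibble())
    cross_map_reads(reads, regions, config$mapper_max_mismatches)
  })
  if (!nrow(mapped)) {
    mapped <- tibble(read_id = character(), mate = integer(), target = character(),
                     start = integer(), end = integer(), strand = character(),
                     mismatches = integer(), pileup = numeric(),
                     region_genome = character())
  }
  classify_and_remove(mapped, reads, own_assembly,
                      depth_threshold = config$read_removal_depth,
                      min_rescue_identity = config$min_rescue_identity)
}
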