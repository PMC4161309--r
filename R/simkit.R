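# Synthetic strain genomes, read sets and truth ledgers. The simulator
# emulates the statistical structure the downstream analyses assume: strains
# diverging from a common ancestor with synonymous-site substitution at a
# controlled rate, nonsynonymous changes thinned by omega, homologous
# recombination tracts (including rRNA homogenization), random genome dropout
# mimicking incomplete MDA recovery, and cross-library read misassignment
# concentrated on ultra-high-coverage regions.

#' Simulation parameters
#'
#' @param ancestor_length ancestor genome length (nt).
#' @param gene_count number of protein-coding genes.
#' @param gene_length_mean mean CDS length (nt; rounded to codons).
#' @param n_strains number of strains to evolve.
#' @param divergence_times per-strain branch lengths, expected substitutions
#'   per site at synonymous sites (recycled to `n_strains`).
#' @param omega dN/dS used to thin nonsynonymous changes.
#' @param recomb_rate expected recombination tracts per genome per branch.
#' @param tract_length_mean mean tract length (nt, geometric).
#' @param rrna_homogenize if TRUE the rRNA-like locus is overwritten by donor
#'   tracts every branch so its pairwise divergence stays below 1%.
#' @param rrna_length length of the rRNA-like locus.
#' @param rrna_noise residual per-site noise applied to homogenized rRNA.
#' @param dropout_fraction fraction of each genome removed by simulated
#'   incomplete recovery, in `[0, 1)`.
#' @param dropout_interval_mean mean length of a dropped interval (nt).
#' @param coverage_mean baseline mean per-contig coverage.
#' @param coverage_lognormal_sigma log-sd of the per-contig coverage draw.
#' @param hotspot_count contigs boosted above the hotspot threshold.
#' @param hotspot_depth coverage assigned to hotspot contigs.
#' @param read_length,insert_size read geometry (default 76 nt paired reads,
#'   approx. 400 nt inserts).
#' @param misassignment_rate fraction of read pairs relabeled to another
#'   library, in `[0, 0.05]`.
#' @param error_rate optional uniform sequencing error rate (default 0).
#' @param origin_blur optional blur applied to hard 0/1 substitution origins.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(ancestor_length = 100000L,
                       gene_count = 60L,
                       gene_length_mean = 900L,
                       n_strains = 4L,
                       divergence_times = c(0.03, 0.03, 0.15, 1.0),
                       omega = 0.1,
                       recomb_rate = 2,
                       tract_length_mean = 500,
                       rrna_homogenize = TRUE,
                       rrna_length = 1500L,
                       rrna_noise = 0.004,
                       dropout_fraction = 0.35,
                       dropout_interval_mean = 2000,
                       coverage_mean = 30,
                       coverage_lognormal_sigma = 1,
                       hotspot_count = 2L,
                       hotspot_depth = 6000,
                       read_length = 76L,
                       insert_size = 400L,
                       misassignment_rate = 0.003,
                       error_rate = 0,
                       origin_blur = 0,
                       seed = NULL) {
  p <- as.list(environment())
  p$divergence_times <- rep_len(divergence_times, n_strains)
  if (any(p$divergence_times < 0)) abort("divergence_times must be >= 0")
  if (dropout_fraction < 0 || dropout_fraction >= 1) {
    abort("dropout_fraction must lie in [0, 1)")
  }
  if (misassignment_rate < 0 || misassignment_rate > 0.05) {
    abort("misassignment_rate must lie in [0, 0.05]")
  }
  if (omega < 0) abort("omega must be >= 0")
  structure(p, class = "sim_params")
}

#' Generate a random ancestor genome and gene table
#'
#' Places `gene_count` non-overlapping CDS (random strand, bodies of sense
#' codons so every gene translates without internal stops) plus one
#' rRNA-like locus on a single replicon.
#'
#' @param params a [sim_params()].
#' @return list with `assembly` ([genome_assembly()]) and `genes` tibble.
#' @export
generate_ancestor <- function(params) {
  if (!is.null(params$seed)) set.seed(params$seed)
  L <- params$ancestor_length
  ng <- params$gene_count
  lens <- pmax(150L, as.integer(round(rnorm(ng, params$gene_length_mean,
                                            0.15 * params$gene_length_mean) / 3) * 3))
  feat_lens <- c(lens, params$rrna_length)
  if (sum(feat_lens) + 2 * length(feat_lens) > L) {
    abort(paste0("cannot pack ", ng, " genes of mean length ",
                 params$gene_length_mean, " into ", L,
                 " nt; reduce gene_count or gene_length_mean"))
  }
  nf <- length(feat_lens)
  rrna_at <- sample.int(nf, 1)
  ord <- append(seq_len(ng), 0L, after = rrna_at - 1)  # 0 marks the rRNA slot
  lens_ord <- ifelse(ord == 0, params$rrna_length, lens[pmax(ord, 1)])
  slack <- L - sum(lens_ord)
  cuts <- sort(sample.int(slack - 1, nf))
  gaps <- diff(c(0, cuts))
  starts <- cumsum(gaps + dplyr::lag(lens_ord, default = 0))
  ends <- starts + lens_ord - 1
  chars <- sample(BASES, L, replace = TRUE)
  sense <- sense_codons()
  strand <- sample(c("+", "-"), nf, replace = TRUE, prob = c(0.5, 0.5))
  for (k in seq_len(nf)) {
    if (ord[k] == 0) next
    body <- paste(sample(sense, lens_ord[k] / 3, replace = TRUE), collapse = "")
    if (strand[k] == "-") body <- revcomp(body)
    chars[starts[k]:ends[k]] <- seq_chars(body)
  }
  genes <- tibble(
    genome = "ancestor", contig = "chr",
    gene_id = ifelse(ord == 0, "rrna_16S", sprintf("g%04d", ord)),
    start = as.integer(starts), end = as.integer(ends),
    strand = ifelse(ord == 0, "+", strand),
    product = ifelse(ord == 0, "16S_rRNA", "hypothetical protein")
  )
  asm <- genome_assembly("ancestor", c(chr = chars_seq(chars)),
                         c(chr = params$coverage_mean))
  list(assembly = asm, genes = extract_genes(asm, genes))
}

# integer map site -> gene row (0 intergenic, -1 rRNA/neutral feature)
site_gene_map <- function(L, genes) {
  m <- integer(L)
  for (i in seq_len(nrow(genes))) {
    m[genes$start[i]:genes$end[i]] <-
      if (genes$product[i] == "16S_rRNA") -1L else i
  }
  m
}

# Gillespie-style point-substitution engine. Candidate substitutions arrive
# at rate `d` per site with uniform proposals among the three alternative
# bases; proposals creating stop codons are rejected, nonsynonymous proposals
# are accepted with probability omega, synonymous and non-coding proposals
# always. Accepted synonymous substitutions per synonymous site then have
# expectation d, which is the quantity dS estimators target.
mutate_chars <- function(chars, d, omega, site_gene, genes, last_op = NULL) {
  L <- length(chars)
  if (is.null(last_op)) last_op <- integer(L)
  K <- rpois(1, L * d)
  if (K == 0) return(list(chars = chars, last_op = last_op))
  pos <- sample.int(L, K, replace = TRUE)
  gc_tab <- genetic_code()
  gs <- genes$start; ge <- genes$end; gstr <- genes$strand
  for (p in pos) {
    old <- chars[p]
    alt <- BASES[BASES != old]
    new <- alt[sample.int(3L, 1L)]
    g <- site_gene[p]
    if (g <= 0) {
      chars[p] <- new
      last_op[p] <- 1L
      next
    }
    if (gstr[g] == "+") {
      off <- p - gs[g]
      cpos <- gs[g] + (off %/% 3L) * 3L + 0:2
      codon <- chars[cpos]
      idx <- off %% 3L + 1L
      newcod <- codon
      newcod[idx] <- new
    } else {
      off <- ge[g] - p
      cpos <- ge[g] - ((off %/% 3L) * 3L + 0:2)
      codon <- unname(COMP[chars[cpos]])
      idx <- off %% 3L + 1L
      newcod <- codon
      newcod[idx] <- COMP[[new]]
    }
    aa_new <- gc_tab[[chars_seq(newcod)]]
    if (aa_new == "*") next
    aa_old <- gc_tab[[chars_seq(codon)]]
    if (aa_old == aa_new || runif(1) < omega) {
      chars[p] <- new
      last_op[p] <- 1L
    }
  }
  list(chars = chars, last_op = last_op)
}

#' Evolve strains from an ancestor
#'
#' Each strain evolves independently from the ancestor along its own branch
#' (star phylogeny) under the substitution engine, then receives homologous
#' recombination tracts copied from coexisting strains. With
#' `rrna_homogenize`, every strain's rRNA-like locus is overwritten by a
#' donor copy (recorded as a tract) plus small residual noise, so 16S
#' identity stays > 99% while genome-wide synonymous divergence is free to
#' saturate.
#'
#' @param ancestor output of [generate_ancestor()].
#' @param params a [sim_params()].
#' @return list with `strains` (named list of bundles: assembly + genes) and
#'   `ledger` (truth ledger: recomb_tracts, site_origins, dropout_intervals,
#'   misassigned_read_ids, true_tree).
#' @export
evolve_strains <- function(ancestor, params) {
  anc_chars <- seq_chars(ancestor$assembly$seqs[["chr"]])
  L <- length(anc_chars)
  genes <- ancestor$genes
  sg <- site_gene_map(L, genes)
  n <- params$n_strains
  ids <- paste0("s", seq_len(n))
  chars <- vector("list", n)
  ops <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- mutate_chars(anc_chars, params$divergence_times[i], params$omega, sg, genes)
    chars[[i]] <- ev$chars
    ops[[i]] <- ev$last_op
  }
  tracts <- list()
  if (n >= 2 && params$recomb_rate > 0) {
    for (i in seq_len(n)) {
      nt <- rpois(1, params$recomb_rate)
      for (k in seq_len(nt)) {
        donor <- sample(setdiff(seq_len(n), i), 1)
        len <- min(L, rgeom(1, 1 / params$tract_length_mean) + 1L)
        st <- sample.int(L - len + 1L, 1)
        en <- st + len - 1L
        rng <- st:en
        changed <- chars[[i]][rng] != chars[[donor]][rng]
        chars[[i]][rng] <- chars[[donor]][rng]
        ops[[i]][rng[changed]] <- 2L
        tracts[[length(tracts) + 1]] <-
          tibble(donor = ids[donor], recipient = ids[i], contig = "chr",
                 start = st, end = en, kind = "tract")
      }
    }
  }
  rr <- genes[genes$product == "16S_rRNA", ]
  if (params$rrna_homogenize && n >= 2 && nrow(rr) == 1) {
    rng <- rr$start:rr$end
    for (i in seq_len(n)[-1]) {
      changed <- chars[[i]][rng] != chars[[1]][rng]
      chars[[i]][rng] <- chars[[1]][rng]
      ops[[i]][rng[changed]] <- 2L
      tracts[[length(tracts) + 1]] <-
        tibble(donor = ids[1], recipient = ids[i], contig = "chr",
               start = rr$start, end = rr$end, kind = "rrna")
    }
    if (params$rrna_noise > 0) {
      for (i in seq_len(n)) {
        nmut <- rpois(1, length(rng) * params$rrna_noise)
        if (nmut == 0) next
        at <- sample(rng, min(nmut, length(rng)))
        for (p in at) {
          alt <- BASES[BASES != chars[[i]][p]]
          chars[[i]][p] <- alt[sample.int(3L, 1L)]
          ops[[i]][p] <- 1L
        }
      }
    }
  }
  origins <- purrr::map2_dfr(seq_len(n), ids, function(i, id) {
    diffpos <- which(chars[[i]] != anc_chars)
    if (!length(diffpos)) return(tibble())
    tibble(strain = id, contig = "chr", pos = diffpos,
           origin = as.numeric(ops[[i]][diffpos] == 2L))
  })
  if (params$origin_blur > 0 && nrow(origins)) {
    u <- runif(nrow(origins), 0, params$origin_blur)
    origins$origin <- abs(origins$origin - u)
  }
  strains <- setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    asm <- genome_assembly(ids[i], setNames(chars_seq(chars[[i]]), "chr"),
                           c(chr = params$coverage_mean))
    gt <- genes
    gt$genome <- ids[i]
    gt$gene_id <- paste0(ids[i], "_", gt$gene_id)  # globally unique ids
    strains[[ids[i]]] <- list(assembly = asm, genes = extract_genes(asm, gt))
  }
  ledger <- structure(list(
    recomb_tracts = if (length(tracts)) bind_rows(tracts) else
      tibble(donor = character(), recipient = character(), contig = character(),
             start = integer(), end = integer(), kind = character()),
    site_origins = origins,
    dropout_intervals = tibble(strain = character(), start = integer(), end = integer()),
    misassigned_read_ids = character(),
    true_tree = paste0("(", paste0(ids, ":", params$divergence_times, collapse = ","), ");")
  ), class = "truth_ledger")
  list(strains = strains, ledger = ledger)
}

#' Simulate incomplete genome recovery (MDA dropout)
#'
#' Removes uniformly placed intervals totaling `dropout_fraction` of the
#' genome; the remaining fragments become contigs with lognormal mean
#' coverage. A configurable number of contigs is boosted above the hotspot
#' threshold to emulate MDA amplification hotspots; hotspots are drawn from
#' the smallest contigs that can hold a read pair and never from the
#' rRNA-carrying contig, so hotspot truth labels stay unambiguous.
#'
#' @param bundle strain bundle (assembly + genes) with a single contig.
#' @param params a [sim_params()].
#' @return list with `assembly`, `genes`, `dropout` (intervals tibble) and
#'   `hotspots` (contig ids boosted).
#' @export
simulate_partial_recovery <- function(bundle, params) {
  seqv <- bundle$assembly$seqs
  stopifnot(length(seqv) == 1)
  chars <- seq_chars(seqv[[1]])
  L <- length(chars)
  id <- bundle$assembly$genome
  drop <- logical(L)
  target <- round(params$dropout_fraction * L)
  while (sum(drop) < target) {
    len <- min(L, max(50L, as.integer(rexp(1, 1 / params$dropout_interval_mean))))
    st <- sample.int(L - len + 1L, 1)
    rng <- st:(st + len - 1L)
    new_idx <- rng[!drop[rng]]
    need <- target - sum(drop)
    if (length(new_idx) > need) new_idx <- new_idx[seq_len(need)]
    drop[new_idx] <- TRUE
  }
  r <- rle(!drop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 100L
  fs <- starts[keep]; fe <- ends[keep]
  if (!length(fs)) abort("dropout removed the whole genome")
  cn <- sprintf("%s_c%03d", id, seq_along(fs))
  seqs <- setNames(substring(seqv[[1]], fs, fe), cn)
  cov <- rlnorm(length(fs),
                log(params$coverage_mean) - params$coverage_lognormal_sigma^2 / 2,
                params$coverage_lognormal_sigma)
  genes <- bundle$genes
  out_genes <- list()
  rrna_contig <- character(0)
  for (k in seq_along(fs)) {
    ov <- genes[genes$end >= fs[k] & genes$start <= fe[k], ]
    if (!nrow(ov)) next
    trunc <- ov$start < fs[k] | ov$end > fe[k]
    ov$partial <- trunc
    ns <- pmax(ov$start, fs[k]) - fs[k] + 1L
    ne <- pmin(ov$end, fe[k]) - fs[k] + 1L
    ov$start <- as.integer(ns); ov$end <- as.integer(ne)
    ov$contig <- cn[k]
    # any rRNA overlap (even truncated) disqualifies the contig as a hotspot:
    # homogenized rRNA fragments would make misassignment truth ambiguous
    if (any(ov$product == "16S_rRNA")) rrna_contig <- c(rrna_contig, cn[k])
    out_genes[[length(out_genes) + 1]] <- ov
  }
  genes2 <- if (length(out_genes)) bind_rows(out_genes) else genes[0, ]
  genes2 <- genes2[intersect(c(GENE_COLS, "partial"), names(genes2))]
  hot <- character(0)
  if (params$hotspot_count > 0) {
    elig <- cn[nchar(seqs) >= params$insert_size + 20 & !(cn %in% rrna_contig)]
    if (length(elig)) {
      elig <- elig[order(nchar(seqs[elig]))]
      hot <- head(elig, params$hotspot_count)
      cov[match(hot, cn)] <- params$hotspot_depth
    }
  }
  asm <- genome_assembly(id, seqs, setNames(cov, cn))
  dr <- rle(drop)
  de <- cumsum(dr$lengths); ds <- de - dr$lengths + 1L
  dropout <- tibble(strain = id, start = ds[dr$values], end = de[dr$values])
  list(assembly = asm, genes = extract_genes(asm, genes2),
       dropout = dropout, hotspots = hot)
}

#' Simulate multiplexed paired-end reads with index misassignment
#'
#' Generates error-free paired 76 nt reads (insert ~400 nt) per contig in
#' proportion to its assigned coverage. A fraction `misassignment_rate` of
#' each genome's read pairs is relabeled to another genome's read set; a
#' pair's hop probability is proportional to its source contig's depth
#' (normalised so the overall expected hopped fraction equals the rate), so
#' misassigned reads are drawn preferentially from hotspot contigs.
#'
#' @param bundles named list of strain bundles (assembly + genes).
#' @param params a [sim_params()].
#' @return list with `read_sets` (named list of tibbles: read_id, mate, seq)
#'   and `truth` (tibble: read_id, genome_true, assigned, contig, misassigned).
#' @export
simulate_reads <- function(bundles, params) {
  if (params$misassignment_rate > 0 && length(bundles) < 2) {
    abort("misassignment requires at least 2 genomes")
  }
  rl <- params$read_length
  pairs <- list()
  for (g in names(bundles)) {
    asm <- bundles[[g]]$assembly
    for (ct in names(asm$seqs)) {
      len <- nchar(asm$seqs[[ct]])
      if (len < rl) {
        warn(sprintf("contig %s (%d nt) shorter than read length; skipped", ct, len))
        next
      }
      cov <- asm$coverage[[ct]]
      np <- max(0L, as.integer(round(cov * len / (2 * rl))))
      if (np == 0) next
      ins <- min(params$insert_size, len)
      st <- sample.int(len - ins + 1L, np, replace = TRUE)
      m1 <- substring(asm$seqs[[ct]], st, st + rl - 1L)
      m2 <- revcomp(substring(asm$seqs[[ct]], st + ins - rl, st + ins - 1L))
      pairs[[length(pairs) + 1]] <- tibble(
        read_id = sprintf("%s:%s:%06d", g, ct, seq_len(np)),
        genome_true = g, contig = ct, start = st, depth = cov,
        mate1 = m1, mate2 = m2)
    }
  }
  pr <- bind_rows(pairs)
  if (params$error_rate > 0) {
    for (col in c("mate1", "mate2")) {
      nerr <- rbinom(nrow(pr), rl, params$error_rate)
      for (i in which(nerr > 0)) {
        ch <- seq_chars(pr[[col]][i])
        at <- sample.int(rl, nerr[i])
        for (p in at) ch[p] <- sample(BASES[BASES != ch[p]], 1)
        pr[[col]][i] <- chars_seq(ch)
      }
    }
  }
  pr$assigned <- pr$genome_true
  pr$misassigned <- FALSE
  if (params$misassignment_rate > 0) {
    wmean <- mean(pr$depth)
    phop <- pmin(1, params$misassignment_rate * pr$depth / wmean)
    hop <- runif(nrow(pr)) < phop
    if (any(hop)) {
      gs <- names(bundles)
      pr$assigned[hop] <- vapply(pr$genome_true[hop], function(g) {
        sample(setdiff(gs, g), 1)
      }, character(1))
      pr$misassigned <- hop
    }
  }
  read_sets <- lapply(split(pr, pr$assigned), function(d) {
    bind_rows(
      tibble(read_id = d$read_id, mate = 1L, seq = d$mate1),
      tibble(read_id = d$read_id, mate = 2L, seq = d$mate2)
    ) |> dplyr::arrange(.data$read_id, .data$mate)
  })
  list(read_sets = read_sets,
       truth = pr[c("read_id", "genome_true", "assigned", "contig", "misassigned")])
}

#' Simulate one pair of coding sequences at a given synonymous divergence
#'
#' Two descendants of a random ancestor CDS, each evolved along a branch of
#' `ds / 2` expected synonymous substitutions per synonymous site with
#' nonsynonymous thinning by `omega`.
#'
#' @param n_codons CDS length in codons.
#' @param ds total expected pairwise synonymous divergence.
#' @param omega dN/dS thinning probability.
#' @return named character vector of the two CDS.
#' @export
simulate_codon_pair <- function(n_codons, ds, omega = 0.1) {
  body <- paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
  chars <- seq_chars(body)
  L <- length(chars)
  genes <- tibble(start = 1L, end = L, strand = "+")
  sg <- rep(1L, L)
  a <- mutate_chars(chars, ds / 2, omega, sg, genes)$chars
  b <- mutate_chars(chars, ds / 2, omega, sg, genes)$chars
  c(a = chars_seq(a), b = chars_seq(b))
}

#' Simulate a three-sequence alignment with an optional conversion tract
#'
#' Two focal sequences at a controlled pairwise divergence plus a more
#' distant background sequence; optionally a tract of the second sequence is
#' overwritten with the first (a "global inner" gene-conversion event).
#' Neutral Jukes-Cantor evolution, no indels.
#'
#' @param len alignment length (nt).
#' @param pair_divergence expected substitutions/site separating the focal
#'   pair.
#' @param background_divergence branch length of the background sequence.
#' @param tract_length implanted tract length (nt).
#' @param tract if FALSE no tract is implanted (null alignment).
#' @return list with `aln` (named character vector s1/s2/s3) and
#'   `tract_start`/`tract_end` (NA when no tract).
#' @export
simulate_tract_alignment <- function(len = 1500L, pair_divergence = 0.1,
                                     background_divergence = 0.25,
                                     tract_length = 300L, tract = TRUE) {
  anc <- sample(BASES, len, replace = TRUE)
  genes <- tibble(start = integer(), end = integer(), strand = character())
  sg <- integer(len)
  s1 <- mutate_chars(anc, pair_divergence / 2, 1, sg, genes)$chars
  s2 <- mutate_chars(anc, pair_divergence / 2, 1, sg, genes)$chars
  s3 <- mutate_chars(anc, background_divergence, 1, sg, genes)$chars
  ts <- NA_integer_; te <- NA_integer_
  if (isTRUE(tract)) {
    ts <- sample.int(len - tract_length + 1L, 1)
    te <- ts + tract_length - 1L
    s2[ts:te] <- s1[ts:te]
  }
  list(aln = c(s1 = chars_seq(s1), s2 = chars_seq(s2), s3 = chars_seq(s3)),
       tract_start = ts, tract_end = te)
}

#' Write a simulation to disk
#'
#' One directory per simulation: per-strain FASTA + gene TSV + coverage TSV,
#' FASTQ read sets, truth-ledger TSVs and the true tree in newick.
#'
#' @param strains named list of strain bundles.
#' @param ledger truth ledger.
#' @param read_sets optional output of [simulate_reads()].
#' @param dir output directory.
#' @export
write_simulation <- function(strains, ledger, dir, read_sets = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(strains)) write_genome_bundle(strains[[g]], dir)
  readr::write_tsv(ledger$recomb_tracts, file.path(dir, "truth_tracts.tsv"))
  readr::write_tsv(ledger$site_origins, file.path(dir, "truth_origins.tsv"))
  readr::write_tsv(ledger$dropout_intervals, file.path(dir, "truth_dropout.tsv"))
  writeLines(ledger$true_tree, file.path(dir, "true_tree.nwk"))
  if (!is.null(read_sets)) {
    for (g in names(read_sets$read_sets)) {
      write_fastq_pair(read_sets$read_sets[[g]], file.path(dir, g))
    }
    readr::write_tsv(read_sets$truth, file.path(dir, "truth_reads.tsv"))
  }
  invisible(dir)
}
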