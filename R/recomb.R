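# Recombination detection: the Hudson-Kaplan lower bound on recombination
# events (four-gamete test), a gene-conversion fragment scan in the spirit
# of Sawyer's runs-of-agreement statistic with a permutation null, and the
# two r/m estimators from per-site substitution-origin probabilities.

# biallelic segregating sites of an alignment matrix: list of (column
# position, binary genotype vector); other sites are ignored
biallelic_sites <- function(m) {
  keep_base <- apply(m, 2, function(col) {
    u <- unique(col[col %in% BASES])
    length(u) == 2
  })
  pos <- which(keep_base)
  geno <- lapply(pos, function(j) {
    col <- m[, j]
    u <- sort(unique(col[col %in% BASES]))
    g <- ifelse(col == u[1], 0L, ifelse(col == u[2], 1L, NA_integer_))
    g
  })
  list(pos = pos, geno = geno)
}

four_gametes <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  length(unique(paste0(g1[ok], g2[ok]))) == 4
}

# incompatible (four-gamete) site pairs as intervals over site indices
incompatible_intervals <- function(m) {
  b <- biallelic_sites(m)
  ns <- length(b$pos)
  if (ns < 2) return(tibble(left = integer(), right = integer()))
  lefts <- integer(0); rights <- integer(0)
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      if (four_gametes(b$geno[[i]], b$geno[[j]])) {
        lefts <- c(lefts, i); rights <- c(rights, j)
      }
    }
  }
  tibble(left = lefts, right = rights)
}

#' Hudson-Kaplan minimum number of recombination events (Rm)
#'
#' Under the infinite-sites assumption, two biallelic sites displaying all
#' four gametes require at least one recombination event between them. Rm is
#' the size of a maximal set of non-overlapping incompatible site intervals
#' (intervals sharing only an endpoint do not overlap), obtained greedily by
#' earliest right endpoint, which is optimal for interval scheduling.
#'
#' @param aln character vector of aligned sequences (or matrix).
#' @return integer Rm (0 when fewer than 2 segregating sites).
#' @export
minimum_recombination_events <- function(aln) {
  m <- if (is.matrix(aln)) aln else aln_matrix(aln)
  iv <- incompatible_intervals(m)
  if (!nrow(iv)) return(0L)
  iv <- iv[order(iv$right, iv$left), ]
  rm_count <- 0L
  bound <- -Inf
  for (k in seq_len(nrow(iv))) {
    if (iv$left[k] >= bound) {
      rm_count <- rm_count + 1L
      bound <- iv$right[k]
    }
  }
  rm_count
}

# ---- gene-conversion fragment scan ------------------------------------------

# mismatch penalty per gscale: 0 ends a run outright; larger gscale values
# use smaller penalties, tolerating older (more mutated) conversion tracts
gscale_penalty <- function(gscale) {
  if (gscale == 0) Inf else 6 / gscale
}

# maximum-segment (Kadane) score and interval of +1/-penalty over a logical
# agreement vector
max_segment <- function(agree, penalty) {
  x <- ifelse(agree, 1, -penalty)
  best <- 0; cur <- 0
  bs <- be <- cs <- 0L
  for (i in seq_along(x)) {
    if (cur <= 0) {
      cur <- x[i]; cs <- i
    } else {
      cur <- cur + x[i]
    }
    if (cur > best) {
      best <- cur; bs <- cs; be <- i
    }
  }
  list(score = best, start = bs, end = be)
}

# permutation null of the max-segment score for n polymorphic sites of which
# m are mismatches, cached per (n, m, penalty, nperm)
# null matrix (permutations x penalties), cached per configuration; penalties
# share the same permuted mismatch placements. The null uses its own RNG
# stream derived from the configuration (the caller's RNG state is left
# untouched), so a cache hit is indistinguishable from recomputation and
# pipelines stay byte-deterministic.
max_segment_null <- function(n, m, penalties, nperm) {
  pens <- ifelse(is.finite(penalties), penalties, n + 1)
  key <- paste(n, m, paste(pens, collapse = ","), nperm, sep = "_")
  if (is.null(.sagevo$null_cache)) .sagevo$null_cache <- new.env(parent = emptyenv())
  hit <- .sagevo$null_cache[[key]]
  if (!is.null(hit)) return(hit)
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_seed) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed((n * 1000003 + m * 10007 + sum(round(pens * 97)) + nperm) %%
             .Machine$integer.max)
  best <- max_segment_null_cpp(n, m, pens, nperm)
  .sagevo$null_cache[[key]] <- best
  best
}

#' Detect global-inner gene-conversion fragments
#'
#' Restricts the alignment to polymorphic sites and, for every sequence
#' pair, scores runs of agreement (+1 per shared polymorphic-site match;
#' mismatch handling set by `gscale`: 0 ends the run at the first mismatch,
#' gscale 1 and 2 apply decreasing penalties so older, imperfect tracts can
#' still score). Significance is assessed by permutation of polymorphic-site
#' columns (the null depends only on the site and mismatch counts), with a
#' Bonferroni correction across pairs. Fragments with corrected p <=
#' `p_cutoff` are returned with nucleotide coordinates.
#'
#' @param aln character vector of >= 3 aligned sequences.
#' @param gscale_set subset of c(0, 1, 2).
#' @param p_cutoff corrected p-value cutoff (default 0.05).
#' @param permutations permutations for the null (default 10000).
#' @return tibble of fragments: seq_a, seq_b, gscale, start, end, length,
#'   n_sites, score, p_value.
#' @export
detect_gi_fragments <- function(aln, gscale_set = c(0L, 1L, 2L),
                                p_cutoff = 0.05, permutations = 10000L) {
  m <- aln_matrix(aln)
  if (nrow(m) < 3) abort("inner fragments need at least 3 sequences")
  poly <- which(apply(m, 2, function(col) {
    u <- unique(col[col %in% BASES])
    length(u) >= 2
  }))
  out <- tibble(seq_a = character(), seq_b = character(), gscale = integer(),
                start = integer(), end = integer(), length = integer(),
                n_sites = integer(), score = numeric(), p_value = numeric())
  if (!length(poly)) return(out)
  prs <- combn(nrow(m), 2)
  npairs <- ncol(prs)
  rows <- list()
  for (k in seq_len(npairs)) {
    i <- prs[1, k]; j <- prs[2, k]
    ok <- m[i, poly] %in% BASES & m[j, poly] %in% BASES
    sites <- poly[ok]
    agree <- m[i, sites] == m[j, sites]
    n <- length(agree)
    mm <- sum(!agree)
    if (n < 2) next
    pens <- vapply(gscale_set, gscale_penalty, numeric(1))
    nulls <- max_segment_null(n, mm, pens, permutations)
    for (gi in seq_along(gscale_set)) {
      g <- gscale_set[gi]
      pen <- pens[gi]
      obs <- max_segment(agree, if (is.finite(pen)) pen else n + 1)
      if (obs$score <= 0) next
      p <- (1 + sum(nulls[, gi] >= obs$score)) / (permutations + 1)
      p_corr <- min(1, p * npairs)
      if (p_corr <= p_cutoff) {
        rows[[length(rows) + 1]] <- tibble(
          seq_a = rownames(m)[i], seq_b = rownames(m)[j], gscale = as.integer(g),
          start = sites[obs$start], end = sites[obs$end],
          length = sites[obs$end] - sites[obs$start] + 1L,
          n_sites = obs$end - obs$start + 1L,
          score = obs$score, p_value = p_corr)
      }
    }
  }
  if (length(rows)) out <- bind_rows(out, bind_rows(rows))
  out
}

#' Summarise gene-conversion fragments per pair
#'
#' @param fragments tibble of fragments with a `gene_id` column (bind rows of
#'   per-gene [detect_gi_fragments()] output).
#' @param pair optional 2-vector restricting to one sequence pair.
#' @return tibble: seq_a, seq_b, n_genes (genes with >= 1 fragment, union
#'   over gscale), mean_length (NA when no fragments).
#' @export
summarize_fragments <- function(fragments, pair = NULL) {
  if (!is.null(pair)) {
    fragments <- fragments[(fragments$seq_a %in% pair) &
                             (fragments$seq_b %in% pair), ]
  }
  if (!nrow(fragments)) {
    pr <- if (!is.null(pair)) sort(pair) else c(NA_character_, NA_character_)
    return(tibble(seq_a = pr[1], seq_b = pr[2], n_genes = 0L,
                  mean_length = NA_real_))
  }
  fragments |>
    group_by(.data$seq_a, .data$seq_b) |>
    summarise(n_genes = dplyr::n_distinct(.data$gene_id),
              mean_length = mean(.data$length), .groups = "drop")
}

#' Ratio of recombination to mutation (r/m)
#'
#' Two estimators over per-site probabilities that a substitution arose by
#' recombination: `all_positions` sums the probabilities (r) against their
#' complements (m); `confident_only` counts sites with p >= 0.95 as
#' recombinant and p <= 0.05 as mutational, excluding the rest. The ratio is
#' `Inf` when m = 0 and r > 0, and 0 when r = 0.
#'
#' @param origins numeric vector of probabilities in `[0, 1]` (one per
#'   substituted site), or a truth-ledger `site_origins` tibble.
#' @param method "all_positions" or "confident_only".
#' @return numeric r/m ratio.
#' @export
r_over_m <- function(origins, method = c("all_positions", "confident_only")) {
  method <- match.arg(method)
  if (is.data.frame(origins)) origins <- origins$origin
  if (!length(origins)) abort("no substituted sites supplied")
  if (any(origins < 0 | origins > 1)) abort("origin probabilities must lie in [0, 1]")
  if (method == "all_positions") {
    r <- sum(origins)
    m <- sum(1 - origins)
  } else {
    r <- sum(origins >= 0.95)
    m <- sum(origins <= 0.05)
  }
  if (m == 0) {
    if (r == 0) return(0)
    return(Inf)
  }
  r / m
}
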