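# Ortholog inference: all-vs-all protein similarity, Markov clustering of
# the similarity graph, paralog resolution, remnant/genome-specific
# classification, and shared/accessory gene sets.

#' All-vs-all protein similarity search
#'
#' Striped local protein alignment (BLOSUM62) of every protein pair across
#' (and within) genomes; hits are gated at a Karlin-Altschul E-value and
#' annotated with percent identity over aligned columns and the aligned
#' footprint coverage of both sequences. Self-hits are excluded. Each
#' unordered pair appears once.
#'
#' @param proteomes named list (genome -> named character vector of
#'   proteins keyed by gene id). Gene ids must be globally unique.
#' @param e_cutoff E-value gate (default 1e-5).
#' @return tibble of similarity hits: query, subject, query_genome,
#'   subject_genome, identity (0-100), qcov, scov, score.
#' @export
all_vs_all_search <- function(proteomes, e_cutoff = 1e-5) {
  if (length(proteomes) < 2) abort("need at least 2 genomes")
  empty <- names(proteomes)[lengths(proteomes) == 0]
  if (length(empty)) {
    warn(paste("empty proteome(s):", paste(empty, collapse = ", ")))
    proteomes <- proteomes[lengths(proteomes) > 0]
  }
  genome <- rep(names(proteomes), lengths(proteomes))
  prots <- unlist(unname(proteomes))
  if (anyDuplicated(names(prots))) abort("gene ids must be globally unique")
  G <- length(prots)
  db_n <- sum(nchar(prots))
  rows <- list()
  for (j in seq(2, G)) {
    qs <- seq_len(j - 1)
    sc <- protein_scores(prots[qs], prots[[j]])
    e <- ka_evalue(sc, nchar(prots[qs]), db_n)
    for (i in qs[e <= e_cutoff]) {
      al <- protein_local_align(prots[[i]], prots[[j]])
      rows[[length(rows) + 1]] <- tibble(
        query = names(prots)[i], subject = names(prots)[j],
        query_genome = genome[i], subject_genome = genome[j],
        identity = al$identity, qcov = al$qcov, scov = al$scov,
        score = al$score)
    }
  }
  if (!length(rows)) {
    return(tibble(query = character(), subject = character(),
                  query_genome = character(), subject_genome = character(),
                  identity = numeric(), qcov = numeric(), scov = numeric(),
                  score = numeric()))
  }
  bind_rows(rows)
}

# Markov clustering (expansion 2, given inflation) on a weighted adjacency
# matrix; returns a list of member index vectors (singletons included here,
# dropped by the caller).
mcl_cluster <- function(adj, inflation, max_iter = 200, tol = 1e-8) {
  n <- nrow(adj)
  diag(adj) <- apply(adj, 2, max)  # self-loops stabilise the flow
  M <- sweep(adj, 2, colSums(adj), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < 1e-10] <- 0
    cs <- colSums(M2)
    M2 <- sweep(M2, 2, ifelse(cs == 0, 1, cs), "/")
    resid <- max(abs(M2 - M))
    M <- M2
    if (resid < tol) {
      g <- (M > 1e-6) | (t(M) > 1e-6)
      comp <- integer(n)
      cur <- 0L
      for (s in seq_len(n)) {
        if (comp[s] != 0) next
        cur <- cur + 1L
        queue <- s
        while (length(queue)) {
          v <- queue[[1]]; queue <- queue[-1]
          if (comp[v] != 0) next
          comp[v] <- cur
          queue <- c(queue, which(g[v, ] & comp == 0))
        }
      }
      return(split(seq_len(n), comp))
    }
  }
  abort(sprintf("MCL did not converge after %d iterations (residual %.2e)",
                max_iter, resid))
}

#' Cluster similarity hits into ortholog groups
#'
#' Hits are filtered (identity >= `min_identity`, both coverages >
#' `min_coverage`), assembled into an undirected score-weighted graph with
#' canonically sorted nodes, and clustered with the MCL algorithm
#' (expansion 2, configurable inflation). Singletons are not clusters.
#'
#' @param hits tibble from [all_vs_all_search()].
#' @param min_identity identity gate as a fraction (default 0.5 = 50%).
#' @param min_coverage coverage gate (both query and subject, default 0.5).
#' @param inflation MCL inflation (default 1.5).
#' @return an `ortholog_catalog`: list with `clusters` tibble (cluster,
#'   gene_id, genome, retained) and `genome_of` lookup.
#' @export
build_graph_and_cluster <- function(hits, min_identity = 0.5,
                                    min_coverage = 0.5, inflation = 1.5) {
  f <- hits[hits$identity >= 100 * min_identity &
              hits$qcov > min_coverage & hits$scov > min_coverage, ]
  genome_of <- c(setNames(hits$query_genome, hits$query),
                 setNames(hits$subject_genome, hits$subject))
  genome_of <- genome_of[!duplicated(names(genome_of))]
  if (!nrow(f)) {
    cat <- list(clusters = tibble(cluster = character(), gene_id = character(),
                                  genome = character(), retained = logical()),
                genome_of = genome_of)
    return(structure(cat, class = "ortholog_catalog"))
  }
  nodes <- sort(unique(c(f$query, f$subject)))
  n <- length(nodes)
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  qi <- match(f$query, nodes); si <- match(f$subject, nodes)
  for (k in seq_len(nrow(f))) {
    w <- max(adj[qi[k], si[k]], f$score[k])
    adj[qi[k], si[k]] <- w
    adj[si[k], qi[k]] <- w
  }
  comps <- mcl_cluster(adj, inflation)
  comps <- comps[lengths(comps) >= 2]
  clusters <- purrr::imap_dfr(comps, function(idx, nm) {
    tibble(cluster = sprintf("OG%04d", as.integer(nm)),
           gene_id = nodes[idx],
           genome = unname(genome_of[nodes[idx]]),
           retained = TRUE)
  })
  structure(list(clusters = clusters, genome_of = genome_of),
            class = "ortholog_catalog")
}

#' @export
print.ortholog_catalog <- function(x, ...) {
  cat("<ortholog_catalog>", length(unique(x$clusters$cluster)), "clusters,",
      sum(x$clusters$retained), "retained genes\n")
  invisible(x)
}

# symmetric identity lookup from a hits tibble
hit_identity <- function(hits, a, b) {
  m <- (hits$query == a & hits$subject == b) |
       (hits$query == b & hits$subject == a)
  if (any(m)) max(hits$identity[m]) else 0
}

#' Resolve within-cluster paralogs
#'
#' When a genome contributes more than one member to a cluster, the copy
#' with the highest mean identity to the members from other genomes is
#' retained; ties go to the lexicographically smaller gene id. Dropped
#' copies are flagged `retained = FALSE`.
#'
#' @param catalog an `ortholog_catalog`.
#' @param hits the similarity hits used to build it.
#' @return the catalog with paralogs resolved.
#' @export
resolve_paralogs <- function(catalog, hits) {
  cl <- catalog$clusters
  for (cid in unique(cl$cluster)) {
    members <- cl[cl$cluster == cid & cl$retained, ]
    dup_genomes <- unique(members$genome[duplicated(members$genome)])
    for (g in dup_genomes) {
      copies <- sort(members$gene_id[members$genome == g])
      others <- members$gene_id[members$genome != g]
      mid <- vapply(copies, function(cp) {
        if (!length(others)) return(0)
        mean(vapply(others, function(o) hit_identity(hits, cp, o), numeric(1)))
      }, numeric(1))
      keep <- copies[which.max(mid)]  # which.max takes the first (smallest id) on ties
      drop <- setdiff(copies, keep)
      cl$retained[cl$cluster == cid & cl$gene_id %in% drop] <- FALSE
    }
  }
  catalog$clusters <- cl
  catalog
}

#' Classify genes left out of every cluster
#'
#' Unclustered genes with any similarity hit are `remnant` (partial,
#' sub-threshold homology, typically an alignment covering < 50% of the
#' hit sequence); genes with no hit at the E-gate are
#' `genome_specific`. Clustered genes keep their classification.
#'
#' @param genes gene tibble (gene_id, genome, protein) for one species group.
#' @param hits similarity hits tibble.
#' @param catalog resolved `ortholog_catalog`.
#' @return tibble (gene_id, genome, class) covering every gene exactly once.
#' @export
classify_unclustered <- function(genes, hits, catalog) {
  cl <- catalog$clusters
  class <- setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
  class[cl$gene_id[cl$retained]] <- "clustered"
  class[cl$gene_id[!cl$retained]] <- "paralog_dropped"
  has_hit <- unique(c(hits$query, hits$subject))
  todo <- names(class)[is.na(class)]
  class[todo] <- ifelse(todo %in% has_hit, "remnant", "genome_specific")
  tibble(gene_id = genes$gene_id, genome = genes$genome,
         class = unname(class[genes$gene_id]))
}

#' Shared and accessory gene sets
#'
#' Computes the core (clusters with every genome present), per-subset shared
#' counts (Venn counts), the accessory pool (clusters and genes absent from
#' the reference genome), and per-genome unique gene counts after
#' subtracting remnants, dropped paralogs and small genes (< `min_aa`
#' residues, potential false positives).
#'
#' @param catalog resolved `ortholog_catalog`.
#' @param classifications output of [classify_unclustered()].
#' @param genes gene tibble with `protein` column.
#' @param genomes character vector of genomes considered.
#' @param reference reference genome id (must be in `genomes`).
#' @param min_aa small-gene cutoff in residues (default 50).
#' @return list: `core_count`, `venn` tibble (subset, n_clusters),
#'   `accessory` tibble of accessory genes, `unique_counts` tibble.
#' @export
shared_and_accessory_sets <- function(catalog, classifications, genes,
                                      genomes, reference, min_aa = 50) {
  if (!reference %in% genomes) abort(sprintf("reference '%s' not among genomes", reference))
  cl <- catalog$clusters[catalog$clusters$retained, ]
  cl <- cl[cl$genome %in% genomes, ]
  pres <- cl |> distinct(.data$cluster, .data$genome)
  subsets <- pres |>
    group_by(.data$cluster) |>
    summarise(subset = paste(sort(unique(.data$genome)), collapse = "+"),
              n_genomes = dplyr::n_distinct(.data$genome), .groups = "drop")
  core_count <- sum(subsets$n_genomes == length(genomes))
  venn <- subsets |> count(.data$subset, name = "n_clusters")
  with_ref <- unique(pres$cluster[pres$genome == reference])
  acc_clusters <- setdiff(unique(pres$cluster), with_ref)
  acc_cluster_genes <- cl$gene_id[cl$cluster %in% acc_clusters]
  spec_genes <- classifications$gene_id[
    classifications$class == "genome_specific" &
      classifications$genome != reference]
  accessory <- tibble(gene_id = c(acc_cluster_genes, spec_genes)) |>
    distinct() |>
    left_join(genes[c("gene_id", "genome")], by = "gene_id")
  aa_len <- setNames(nchar(sub("\\*$", "", genes$protein)), genes$gene_id)
  uniq <- classifications |>
    filter(.data$class == "genome_specific",
           .data$genome %in% genomes,
           !is.na(aa_len[.data$gene_id]),
           aa_len[.data$gene_id] >= min_aa) |>
    count(.data$genome, name = "n_unique")
  uniq <- left_join(tibble(genome = genomes), uniq, by = "genome") |>
    mutate(n_unique = dplyr::coalesce(.data$n_unique, 0L))
  list(core_count = core_count, venn = venn, accessory = accessory,
       unique_counts = uniq)
}
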