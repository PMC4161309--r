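make_proteomes <- function(n_strains = 3, n_genes = 12, d = 0.1, omega = 0.1,
                           seed = 8) {
  p <- sim_params(ancestor_length = 3000 * n_genes, gene_count = n_genes,
                  gene_length_mean = 750, n_strains = n_strains,
                  divergence_times = rep(d, n_strains), omega = omega,
                  recomb_rate = 0, rrna_homogenize = FALSE,
                  dropout_fraction = 0, seed = seed)
  ev <- evolve_strains(generate_ancestor(p), p)
  lapply(ev$strains, function(b) sagevo:::proteome_of(b$genes))
}

test_that("similarity hits report symmetric statistics and exact identities", {
  set.seed(21)
  prot <- make_proteomes(2, 6, d = 0)
  hits <- all_vs_all_search(prot)
  # identical proteomes: every cross-genome ortholog pair hits at 100/1/1
  cross <- hits[hits$query_genome != hits$subject_genome, ]
  same_gene <- sub("^s\\d+_", "", cross$query) == sub("^s\\d+_", "", cross$subject)
  expect_true(all(cross$identity[same_gene] == 100))
  expect_true(all(cross$qcov[same_gene] == 1))
  expect_true(all(cross$scov[same_gene] == 1))
  # protein vs its N-terminal half: subject fully covered, query about half
  half <- substr(prot[[1]][[1]], 1, nchar(prot[[1]][[1]]) %/% 2)
  two <- list(gA = setNames(prot[[1]][1], "full"), gB = c(half = half))
  h2 <- all_vs_all_search(two)
  expect_equal(h2$scov, 1, tolerance = 0.02)
  expect_equal(h2$qcov, 0.5, tolerance = 0.05)
  # empty proteome warns and contributes nothing
  expect_warning(h3 <- all_vs_all_search(list(a = prot[[1]], b = character(0),
                                              c = prot[[2]])),
                 "empty")
  expect_false("b" %in% c(h3$query_genome, h3$subject_genome))
})

test_that("MCL clustering matches a dense reference and respects graph structure", {
  # two disconnected triangles -> two clusters of 3
  nodes <- paste0("n", 1:6)
  mk_hits <- function(edges, w) {
    tibble::tibble(query = nodes[edges[, 1]], subject = nodes[edges[, 2]],
                   query_genome = paste0("g", edges[, 1]),
                   subject_genome = paste0("g", edges[, 2]),
                   identity = 90, qcov = 1, scov = 1, score = w)
  }
  tri <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  cat1 <- build_graph_and_cluster(mk_hits(tri, 100), inflation = 1.5)
  cl1 <- split(cat1$clusters$gene_id, cat1$clusters$cluster)
  expect_length(cl1, 2)
  expect_setequal(vapply(cl1, length, 1L), c(3L, 3L))
  # two cliques joined by one weak edge still split, agreeing with the
  # brute-force MCL iteration on the same 6-node matrix
  hits2 <- dplyr::bind_rows(mk_hits(tri, 100), mk_hits(rbind(c(3, 4)), 5))
  cat2 <- build_graph_and_cluster(hits2, inflation = 1.5)
  cl2 <- split(cat2$clusters$gene_id, cat2$clusters$cluster)
  adj <- matrix(0, 6, 6)
  for (k in seq_len(nrow(tri))) adj[tri[k, 1], tri[k, 2]] <- adj[tri[k, 2], tri[k, 1]] <- 100
  adj[3, 4] <- adj[4, 3] <- 5
  ref <- dense_mcl(adj, 1.5)
  ref_cl <- split(nodes, ref)
  expect_setequal(unname(lapply(cl2, sort)), unname(lapply(ref_cl, sort)))
  expect_length(cl2, 2)
  # empty hit list -> empty catalog
  cat0 <- build_graph_and_cluster(mk_hits(tri, 100)[0, ])
  expect_equal(nrow(cat0$clusters), 0)
})

test_that("simulated orthologs cluster perfectly below saturation", {
  set.seed(22)
  prot <- make_proteomes(3, 12, d = 0.1)
  hits <- all_vs_all_search(prot)
  catl <- resolve_paralogs(build_graph_and_cluster(hits), hits)
  cl <- catl$clusters
  expect_equal(dplyr::n_distinct(cl$cluster), 12)
  truth <- sub("^s\\d+_", "", cl$gene_id)
  # adjusted agreement with truth: every cluster maps to one ancestral gene
  expect_true(all(tapply(truth, cl$cluster, function(x) length(unique(x))) == 1))
})

test_that("paralog resolution keeps the most similar copy with a deterministic tie-break", {
  hits <- tibble::tibble(
    query = c("a1", "a2", "a1", "a2", "b1"),
    subject = c("b1", "b1", "a2", "c1", "c1"),
    query_genome = c("A", "A", "A", "A", "B"),
    subject_genome = c("B", "B", "A", "C", "C"),
    identity = c(92, 85, 88, 84, 90), qcov = 1, scov = 1, score = 200)
  catalog <- structure(list(
    clusters = tibble::tibble(
      cluster = "OG0001", gene_id = c("a1", "a2", "b1", "c1"),
      genome = c("A", "A", "B", "C"), retained = TRUE),
    genome_of = c(a1 = "A", a2 = "A", b1 = "B", c1 = "C")),
    class = "ortholog_catalog")
  res <- resolve_paralogs(catalog, hits)
  # a1: mean(92, 0) vs a2: mean(85, 84) -> a2 wins
  expect_true(res$clusters$retained[res$clusters$gene_id == "a2"])
  expect_false(res$clusters$retained[res$clusters$gene_id == "a1"])
  # exact tie keeps the lexicographically smaller id
  hits_tie <- dplyr::mutate(hits, identity = c(85, 85, 88, 84, 90))
  hits_tie$identity[hits_tie$query == "a2" & hits_tie$subject == "c1"] <- 85
  catalog2 <- catalog
  catalog2$clusters <- catalog2$clusters[catalog2$clusters$gene_id != "c1", ]
  res2 <- resolve_paralogs(catalog2, hits_tie)
  expect_true(res2$clusters$retained[res2$clusters$gene_id == "a1"])
  # no paralogs: catalog unchanged
  solo <- catalog
  solo$clusters <- solo$clusters[solo$clusters$gene_id != "a2", ]
  expect_identical(resolve_paralogs(solo, hits)$clusters, solo$clusters)
})

test_that("classification covers every gene exactly once and set algebra is exact", {
  genes <- tibble::tibble(
    gene_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    genome = c("A", "A", "B", "B", "C", "C"),
    protein = strrep("M", 100))
  hits <- tibble::tibble(
    query = c("a1", "a1", "b2"), subject = c("b1", "c1", "c2"),
    query_genome = c("A", "A", "B"), subject_genome = c("B", "C", "C"),
    identity = c(95, 95, 60), qcov = c(1, 1, 0.3), scov = c(1, 1, 0.3),
    score = c(300, 300, 40))
  catalog <- build_graph_and_cluster(hits)
  classif <- classify_unclustered(genes, hits, catalog)
  expect_equal(nrow(classif), nrow(genes))
  # a partial (sub-threshold) hit makes a remnant; no hit at all is specific
  expect_equal(classif$class[classif$gene_id == "b2"], "remnant")
  expect_equal(classif$class[classif$gene_id == "c2"], "remnant")
  expect_equal(classif$class[classif$gene_id == "a2"], "genome_specific")
  expect_true(all(classif$class[classif$gene_id %in% c("a1", "b1", "c1")] == "clustered"))
  # shared/accessory: cluster {a1,b1,c1} is core; a2 is genome-specific but
  # small genes (< 50 aa) are excluded from unique counts
  genes_small <- genes
  genes_small$protein[genes_small$gene_id == "a2"] <- strrep("M", 40)
  sets <- shared_and_accessory_sets(catalog, classif, genes_small,
                                    c("A", "B", "C"), reference = "A")
  expect_equal(sets$core_count, 1)
  expect_equal(sets$unique_counts$n_unique[sets$unique_counts$genome == "A"], 0)
  sets2 <- shared_and_accessory_sets(catalog, classif, genes,
                                     c("A", "B", "C"), reference = "A")
  expect_equal(sets2$unique_counts$n_unique[sets2$unique_counts$genome == "A"], 1)
  # remnants never count as unique
  expect_equal(sets2$unique_counts$n_unique[sets2$unique_counts$genome == "C"], 0)
  expect_error(shared_and_accessory_sets(catalog, classif, genes,
                                         c("A", "B", "C"), reference = "Z"),
               "reference")
})
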