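block_alignment <- function() {
  # 4 taxa with a clean AB|CD signal plus taxon-specific noise
  set.seed(61)
  base <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
  mk <- function(x, sites) {
    y <- base
    for (i in sites) y[i] <- setdiff(c("A", "C", "G", "T"), y[i])[1]
    paste(y, collapse = "")
  }
  shared_ab <- 1:60
  shared_cd <- 61:120
  c(A = mk(base, c(shared_ab, 200:205)),
    B = mk(base, c(shared_ab, 300:305)),
    C = mk(base, c(shared_cd, 400:405)),
    D = mk(base, c(shared_cd, 500:505)))
}

test_that("NJ recovers clear topologies with nonnegative branch lengths", {
  aln <- block_alignment()
  st <- build_tree(aln)
  expect_s3_class(st$tree, "phylo")
  expect_true(all(st$tree$edge.length >= 0))
  expect_true("A,B" %in% sagevo:::tree_splits(st$tree) ||
                "C,D" %in% sagevo:::tree_splits(st$tree))
  # 3 taxa: the unique unrooted topology, no internal splits
  st3 <- build_tree(aln[1:3])
  expect_length(sagevo:::tree_splits(st3$tree), 0)
  # saturation errors name the offending pair
  sat <- c(x = strrep("ACGT", 50), y = strrep("CAAA", 50), z = strrep("GTTC", 50))
  expect_error(build_tree(sat), "saturated")
})

test_that("NJ is consistent on clock-like simulated alignments", {
  set.seed(62)
  ok <- 0
  for (r in 1:15) {
    anc <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
    genes <- tibble::tibble(start = integer(), end = integer(), strand = character())
    sg <- integer(1000)
    mut <- function(x, d) sagevo:::mutate_chars(x, d, 1, sg, genes)$chars
    ab <- mut(anc, 0.1); cd <- mut(anc, 0.1)
    aln <- c(A = paste(mut(ab, 0.05), collapse = ""),
             B = paste(mut(ab, 0.05), collapse = ""),
             C = paste(mut(cd, 0.05), collapse = ""),
             D = paste(mut(cd, 0.05), collapse = ""))
    st <- build_tree(aln)
    # canonical form: the side not containing taxon A, i.e. "C,D" for AB|CD
    if ("C,D" %in% sagevo:::tree_splits(st$tree)) ok <- ok + 1
  }
  expect_gte(ok, 14)
})

test_that("bootstrap support is seeded, bounded, and saturates on clean signal", {
  aln <- block_alignment()
  set.seed(63)
  st <- bootstrap_support(aln, reps = 50)
  expect_true(all(st$splits$support >= 0 & st$splits$support <= 100))
  # congruent signal with no homoplasy: full support
  expect_true(all(st$splits$support >= 80))
  set.seed(63)
  st2 <- bootstrap_support(aln, reps = 50)
  expect_identical(st$splits, st2$splits)
  # a single replicate yields 0/100 supports
  set.seed(64)
  st1 <- bootstrap_support(aln, reps = 1)
  expect_true(all(st1$splits$support %in% c(0, 100)))
  # supports are invariant under leaf relabeling (permutation equivariance)
  perm <- aln[c("C", "D", "A", "B")]
  set.seed(63)
  stp <- bootstrap_support(perm, reps = 50)
  expect_setequal(stp$splits$split, st$splits$split)
})

test_that("topology concordance counts congruent and supported gene trees", {
  aln <- block_alignment()
  set.seed(65)
  ref <- bootstrap_support(aln, reps = 20)
  # four gene trees: three congruent, one conflicting (A with C)
  conflict <- aln[c("A", "C", "B", "D")]
  names(conflict) <- c("A", "B", "C", "D")  # relabel to swap the pairing
  gts <- list(build_tree(aln), build_tree(aln), build_tree(aln),
              build_tree(conflict))
  conc <- topology_concordance(gts, ref, support_threshold = 80)
  expect_equal(nrow(conc), 1)
  expect_equal(conc$n_eval, 4)
  expect_equal(conc$n_congruent, 3)
  expect_equal(conc$pct_congruent, 75)
  expect_lte(conc$n_supported, conc$n_congruent)
  # identical gene trees: 100% everywhere
  conc2 <- topology_concordance(list(build_tree(aln), build_tree(aln)), ref)
  expect_equal(conc2$pct_congruent, 100)
  # a gene tree missing taxa on one side is excluded from the denominator
  gt3 <- build_tree(aln[c("A", "B", "C")])
  conc3 <- topology_concordance(list(build_tree(aln), gt3), ref)
  expect_equal(conc3$n_eval, 1)
})

test_that("recombinant gene histories depress concordance at the affected split", {
  set.seed(66)
  p <- sim_params(ancestor_length = 40000, gene_count = 20, n_strains = 4,
                  divergence_times = c(0.05, 0.05, 0.05, 0.05), omega = 0.1,
                  recomb_rate = 0, rrna_homogenize = FALSE, dropout_fraction = 0)
  ev <- evolve_strains(generate_ancestor(p), p)
  tabs <- lapply(ev$strains, `[[`, "genes")
  cds_ids <- sub("^s1_", "", tabs$s1$gene_id[tabs$s1$product != "16S_rRNA"])
  gene_aln <- function(gid) {
    vapply(tabs, function(tt) tt$cds[sub("^s\\d+_", "", tt$gene_id) == gid],
           character(1))
  }
  alns <- lapply(cds_ids, gene_aln)
  concat <- vapply(names(tabs), function(g) {
    paste(vapply(alns, `[[`, character(1), g), collapse = "")
  }, character(1))
  ref <- build_tree(concat)
  gts_clean <- lapply(alns, build_tree)
  conc_clean <- topology_concordance(gts_clean, ref)
  # overwrite half of each of the first 10 genes in s2 with s4's copy
  alns_rec <- alns
  for (k in 1:10) {
    a <- alns_rec[[k]]
    half <- nchar(a[["s2"]]) %/% 2
    substr(a[["s2"]], 1, half) <- substr(a[["s4"]], 1, half)
    alns_rec[[k]] <- a
  }
  gts_rec <- lapply(alns_rec, function(a) tryCatch(build_tree(a), error = function(e) NULL))
  gts_rec <- Filter(Negate(is.null), gts_rec)
  conc_rec <- topology_concordance(gts_rec, ref)
  expect_lt(mean(conc_rec$pct_congruent), mean(conc_clean$pct_congruent) + 1e-9)
})
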