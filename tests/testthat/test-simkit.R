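test_that("ancestor generation packs genes, is seeded, and guards infeasible input", {
  p <- sim_params(ancestor_length = 50000, gene_count = 40, gene_length_mean = 900,
                  seed = 5)
  anc <- generate_ancestor(p)
  g <- anc$genes
  expect_equal(sum(g$product != "16S_rRNA"), 40)
  # non-overlapping features on both strands
  o <- order(g$start)
  expect_true(all(g$start[o][-1] > g$end[o][-length(o)]))
  expect_setequal(unique(g$strand[g$product != "16S_rRNA"]), c("+", "-"))
  # every CDS translates without internal stops
  prot <- g$protein[g$product != "16S_rRNA"]
  expect_false(any(grepl("\\*", prot)))
  # determinism under the seed
  anc2 <- generate_ancestor(p)
  expect_identical(anc2$assembly$seqs, anc$assembly$seqs)
  expect_equal(anc2$genes$start, anc$genes$start)
  # infeasible packing errors
  expect_error(generate_ancestor(sim_params(ancestor_length = 10000,
                                            gene_count = 40, seed = 1)),
               "gene_count|pack")
})

test_that("zero-branch evolution is the identity and omega = 0 freezes proteins", {
  p0 <- sim_params(ancestor_length = 20000, gene_count = 10, n_strains = 2,
                   divergence_times = c(0, 0), recomb_rate = 0,
                   rrna_homogenize = FALSE, seed = 2)
  anc <- generate_ancestor(p0)
  ev <- evolve_strains(anc, p0)
  expect_identical(ev$strains$s1$assembly$seqs[["chr"]],
                   anc$assembly$seqs[["chr"]])
  expect_equal(nrow(ev$ledger$site_origins), 0)
  expect_equal(nrow(ev$ledger$recomb_tracts), 0)

  pw <- sim_params(ancestor_length = 20000, gene_count = 10, n_strains = 2,
                   divergence_times = c(0.2, 0.2), omega = 0, recomb_rate = 0,
                   rrna_homogenize = FALSE, seed = 3)
  anc2 <- generate_ancestor(pw)
  ev2 <- evolve_strains(anc2, pw)
  cds <- anc2$genes$product != "16S_rRNA"
  expect_identical(ev2$strains$s1$genes$protein[cds],
                   ev2$strains$s2$genes$protein[cds])
})

test_that("without recombination every substitution origin is mutational (true r/m = 0)", {
  p <- sim_params(ancestor_length = 30000, gene_count = 15, n_strains = 3,
                  divergence_times = c(0.1, 0.1, 0.1), recomb_rate = 0,
                  rrna_homogenize = FALSE, seed = 9)
  ev <- evolve_strains(generate_ancestor(p), p)
  org <- ev$ledger$site_origins
  expect_gt(nrow(org), 0)
  expect_true(all(org$origin == 0))
  expect_equal(r_over_m(org), 0)
})

test_that("synonymous divergence is calibrated: JC at low divergence, exact chain at high", {
  ps_of <- function(aln) {
    cc <- sagevo:::comparable_codons(aln[[1]], aln[[2]])
    ss <- sagevo:::codon_syn_sites()
    dt <- sagevo:::codon_diff_tables()
    idx <- cbind(match(cc$a, colnames(dt$syn)), match(cc$b, colnames(dt$syn)))
    sum(dt$syn[idx]) / ((sum(ss[cc$a]) + sum(ss[cc$b])) / 2)
  }
  # invariant: mean dS estimates at summed divergence 0.05 and 0.2 within
  # 3 SE over >= 100 genes
  set.seed(31)
  for (d in c(0.05, 0.2)) {
    ds <- vapply(seq_len(100), function(i) {
      ng86_divergence(simulate_codon_pair(300, d, 0.1))$dS
    }, numeric(1))
    se <- sd(ds) / sqrt(length(ds))
    expect_lt(abs(mean(ds) - d), 3 * se)
  }
  # high divergence (0.3/branch): rRNA homogenized while CDS divergence is
  # free; mean synonymous p-distance matches the exact thinned-chain
  # expectation (matrix-exponential oracle) within 3 SE
  set.seed(77)
  p <- sim_params(ancestor_length = 80000, gene_count = 60, n_strains = 2,
                  divergence_times = c(0.3, 0.3), omega = 0.1, recomb_rate = 0,
                  rrna_homogenize = TRUE, dropout_fraction = 0)
  ev <- evolve_strains(generate_ancestor(p), p)
  g1 <- ev$strains$s1$genes; g2 <- ev$strains$s2$genes
  rr <- g1$product == "16S_rRNA"
  expect_gt(pairwise_identity(g1$cds[rr], g2$cds[rr]), 99)
  ps <- vapply(which(!rr), function(i) ps_of(c(a = g1$cds[i], b = g2$cds[i])),
               numeric(1))
  expt <- expected_syn_pdist(0.6, 0.1)
  se <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - expt), 3 * se)
  # and the four-state JC formula is the low-divergence limit of that oracle
  expect_lt(abs(expected_syn_pdist(0.05, 0.1) - 0.75 * (1 - exp(-4 * 0.05 / 3))),
            0.001)
})

test_that("partial recovery removes the configured fraction and boosts hotspots", {
  p <- sim_params(ancestor_length = 120000, gene_count = 50, n_strains = 1,
                  divergence_times = 0, dropout_fraction = 0.35,
                  hotspot_count = 2, hotspot_depth = 6000, seed = 6)
  anc <- generate_ancestor(p)
  ev <- evolve_strains(anc, p)
  set.seed(61)
  rec <- simulate_partial_recovery(ev$strains$s1, p)
  frac <- sum(nchar(rec$assembly$seqs)) / 120000
  expect_gte(frac, 0.60)
  expect_lte(frac, 0.70)
  expect_length(rec$hotspots, 2)
  expect_true(all(rec$assembly$coverage[rec$hotspots] == 6000))
  # hotspots recovered exactly by the region finder
  regions <- find_high_coverage_regions(rec$assembly, 5000)
  expect_setequal(regions$contig, rec$hotspots)
  # determinism
  set.seed(61)
  rec2 <- simulate_partial_recovery(ev$strains$s1, p)
  expect_identical(rec2$assembly$seqs, rec$assembly$seqs)
  # dropout 0 keeps a single contig but still draws lognormal coverage
  p0 <- sim_params(ancestor_length = 50000, gene_count = 20, n_strains = 1,
                   divergence_times = 0, dropout_fraction = 0,
                   hotspot_count = 0, seed = 6)
  ev0 <- evolve_strains(generate_ancestor(p0), p0)
  rec0 <- simulate_partial_recovery(ev0$strains$s1, p0)
  expect_length(rec0$assembly$seqs, 1)
  expect_true(is.finite(rec0$assembly$coverage[[1]]))
})

test_that("read simulation respects geometry, misassignment rate and truth ledger", {
  p <- sim_params(ancestor_length = 40000, gene_count = 15, n_strains = 2,
                  divergence_times = c(0.1, 0.1), dropout_fraction = 0.2,
                  dropout_interval_mean = 1000, coverage_mean = 10,
                  hotspot_count = 1, hotspot_depth = 5500,
                  misassignment_rate = 0.003, seed = 12)
  ev <- evolve_strains(generate_ancestor(p), p)
  rec <- lapply(ev$strains, simulate_partial_recovery, params = p)
  set.seed(13)
  rd <- simulate_reads(rec, p)
  reads <- rd$read_sets[[1]]
  expect_true(all(nchar(reads$seq) == 76))
  # every read maps back to its true genome with 0 mismatches
  tr <- rd$truth
  samp <- tr[sample.int(nrow(tr), 50), ]
  for (k in seq_len(nrow(samp))) {
    gsrc <- samp$genome_true[k]
    ctg <- rec[[gsrc]]$assembly$seqs[[samp$contig[k]]]
    rr <- rd$read_sets[[samp$assigned[k]]]
    m1 <- rr$seq[rr$read_id == samp$read_id[k] & rr$mate == 1]
    expect_true(grepl(m1, ctg, fixed = TRUE))
  }
  # misassignment count is plausible under the configured rate
  nm <- sum(tr$misassigned)
  expect_gt(nm, 0)
  lam <- 0.003 * nrow(tr)
  expect_lt(abs(nm - lam), 6 * sqrt(lam) + 10)
  # rate 0 leaves the ledger empty
  p0 <- sim_params(ancestor_length = 20000, gene_count = 8, n_strains = 2,
                   divergence_times = c(0.1, 0.1), dropout_fraction = 0,
                   hotspot_count = 0, misassignment_rate = 0, seed = 12)
  ev0 <- evolve_strains(generate_ancestor(p0), p0)
  rd0 <- simulate_reads(lapply(ev0$strains, function(b) b), p0)
  expect_false(any(rd0$truth$misassigned))
})

test_that("parameter validation guards the simulator", {
  expect_error(sim_params(dropout_fraction = 1), "dropout_fraction")
  expect_error(sim_params(misassignment_rate = 0.2), "misassignment_rate")
  expect_error(sim_params(divergence_times = -0.1), "divergence_times")
})
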