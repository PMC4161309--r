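# Shared experiment recipes for the acceptance-level checks. Problem sizes
# (genome length, gene count, read depths) are the package's desk-scale
# study conditions, documented in the methods vignette.

cleanup_experiment <- function(seed) {
  set.seed(seed)
  p <- sim_params(ancestor_length = 60000, gene_count = 30, gene_length_mean = 900,
                  n_strains = 2, divergence_times = c(0.35, 0.35), omega = 0.1,
                  recomb_rate = 0, rrna_homogenize = TRUE,
                  dropout_fraction = 0.35, dropout_interval_mean = 800,
                  coverage_mean = 20, coverage_lognormal_sigma = 0.7,
                  hotspot_count = 2, hotspot_depth = 6000,
                  misassignment_rate = 0.003)
  anc <- generate_ancestor(p)
  ev <- evolve_strains(anc, p)
  rec <- lapply(ev$strains, simulate_partial_recovery, params = p)
  rd <- simulate_reads(rec, p)
  cfg <- pipeline_config()
  removed <- character(0)
  for (g in names(rd$read_sets)) {
    rep_g <- clean_read_set(rd$read_sets[[g]], rec[[g]]$assembly,
                            lapply(rec[setdiff(names(rec), g)], `[[`, "assembly"),
                            cfg)
    removed <- c(removed, rep_g$removed_ids)
  }
  tr <- rd$truth
  mis <- tr$read_id[tr$misassigned]
  gen <- tr$read_id[!tr$misassigned]
  list(recall = mean(mis %in% removed),
       false_removal = mean(gen %in% removed),
       n_misassigned = length(mis), n_pairs = nrow(tr))
}

rrna_signature_experiment <- function(seed) {
  set.seed(seed)
  p <- sim_params(ancestor_length = 50000, gene_count = 30, gene_length_mean = 900,
                  n_strains = 2, divergence_times = c(0.8, 0.8), omega = 0.1,
                  recomb_rate = 0, rrna_homogenize = TRUE, dropout_fraction = 0)
  ev <- evolve_strains(generate_ancestor(p), p)
  g1 <- ev$strains$s1$genes
  g2 <- ev$strains$s2$genes
  rr <- g1$product == "16S_rRNA"
  id16s <- pairwise_identity(g1$cds[rr], g2$cds[rr])
  rows <- which(!rr & !g1$partial)
  alns <- lapply(rows, function(i) c(s1 = g1$cds[i], s2 = g2$cds[i]))
  names(alns) <- g1$gene_id[rows]
  conc <- concat_divergence(alns, pair = "s1-s2")
  list(identity_16s = id16s, concat_ds = conc$dS)
}
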