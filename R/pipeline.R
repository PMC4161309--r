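# End-to-end orchestration: chains cleanup, contig QC, ortholog clustering,
# divergence, ternary, recombination and phylogeny stages over a manifest of
# genome bundles, writing one TSV report per stage (stamped with the config
# hash) plus newick trees and a run log.

# pair two (or more) CDS into a codon alignment; equal-length CDS are taken
# as positionally aligned (the simulator produces no indels), otherwise the
# proteins are globally aligned and back-translated
codon_align_genes <- function(cds_vec) {
  lens <- nchar(cds_vec)
  if (length(unique(lens)) == 1) return(as_aln(cds_vec))
  if (length(cds_vec) != 2) return(NULL)
  prots <- vapply(cds_vec, function(x) sub("\\*$", "", translate_cds(x)), character(1))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prots[[1]]), Biostrings::AAString(prots[[2]]),
    type = "global", substitutionMatrix = protein_submat(),
    gapOpening = 11, gapExtension = 1)
  paln <- setNames(c(as.character(Biostrings::alignedPattern(al)),
                     as.character(Biostrings::alignedSubject(al))),
                   names(cds_vec))
  tryCatch(backtranslate(paln, cds_vec), error = function(e) NULL)
}

# single-copy ortholog CDS table: cluster x genome -> cds
single_copy_table <- function(catalog, gene_tables) {
  genes <- bind_rows(gene_tables)
  cl <- catalog$clusters[catalog$clusters$retained, ]
  left_join(cl, genes[c("gene_id", "cds", "partial", "product")], by = "gene_id") |>
    filter(!.data$partial)
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @param manifest list with components: `genomes` (named list of bundles:
#'   assembly + genes), optional `reads` (named list of read tibbles),
#'   `groups` (named character mapping genome -> species group; default one
#'   group), `reference` (named character mapping group -> reference genome
#'   id), optional `essential` (named list mapping group -> protein set for
#'   completeness), optional `origins` (site-origin probabilities tibble for
#'   r/m).
#' @param out_dir report directory (created).
#' @return invisibly, the output directory. Deterministic given
#'   `config$random_seed`.
#' @export
run_pipeline <- function(config, manifest, out_dir) {
  set.seed(config$random_seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(paste0("config_hash\t", config_hash(config)))
  say <- function(...) log_lines <<- c(log_lines, paste(..., sep = "\t"))
  for (f in setdiff(names(config), "gscale_set")) say("threshold", f, config[[f]])
  say("threshold", "gscale_set", paste(config$gscale_set, collapse = ","))

  genomes <- manifest$genomes
  ids <- names(genomes)
  groups <- manifest$groups %||% setNames(rep("group1", length(ids)), ids)
  refs <- manifest$reference %||%
    setNames(rep(ids[1], length(unique(groups))), unique(groups))

  ## stage: cleanup -----------------------------------------------------------
  if (!is.null(manifest$reads) && length(ids) >= 2) {
    rows <- list()
    for (g in intersect(ids, names(manifest$reads))) {
      rep_g <- clean_read_set(manifest$reads[[g]], genomes[[g]]$assembly,
                              lapply(genomes[setdiff(ids, g)], `[[`, "assembly"),
                              config)
      rows[[g]] <- mutate(rep_g$summary, genome = g, .before = 1)
      say("cleanup", g, paste0(rep_g$summary$removed_pairs, " pairs removed"))
    }
    write_stage_report(bind_rows(rows), file.path(out_dir, "cleanup.tsv"), config)
  } else if (!is.null(manifest$reads)) {
    say("cleanup", "skipped", "fewer than 2 genomes")
  }

  ## stage: contig QC ---------------------------------------------------------
  qc_rows <- list()
  for (g in ids) {
    grp <- groups[[g]]
    ref_prot <- proteome_of(genomes[[refs[[grp]]]]$genes)
    red <- remove_redundant_contigs(genomes[[g]]$assembly)
    v1 <- filter_contigs(red$assembly, ref_prot, ref_prot, config)
    v2 <- red$verdicts[!red$verdicts$retained, ]
    verdicts <- bind_rows(
      mutate(v1, genome = g, .before = 1),
      tibble(genome = g, contig = v2$contig, length = v2$length,
             coverage = NA_real_, retained = FALSE, reason = "redundant"))
    if (!is.null(manifest$essential) && !is.null(manifest$essential[[grp]])) {
      comp <- estimate_completeness(genomes[[g]]$genes, manifest$essential[[grp]],
                                    config$min_hit_identity, config$min_hit_coverage)
      say("completeness", g, comp$fraction)
    }
    qc_rows[[g]] <- verdicts
  }
  write_stage_report(bind_rows(qc_rows), file.path(out_dir, "contig_qc.tsv"), config)

  ## per-group comparative stages --------------------------------------------
  for (grp in unique(groups)) {
    gids <- ids[groups[ids] == grp]
    if (length(gids) < 2) {
      warn(sprintf("group %s has fewer than 2 genomes: divergence and recombination stages skipped", grp))
      say("group", grp, "skipped: fewer than 2 genomes")
      next
    }
    proteomes <- lapply(genomes[gids], function(b) proteome_of(b$genes))
    hits <- all_vs_all_search(proteomes)
    catalog <- build_graph_and_cluster(hits, config$min_hit_identity,
                                       config$min_hit_coverage, config$mcl_inflation)
    catalog <- resolve_paralogs(catalog, hits)
    genes_all <- bind_rows(lapply(genomes[gids], `[[`, "genes"))
    genes_cds <- genes_all[!genes_all$partial & genes_all$product != "16S_rRNA", ]
    classif <- classify_unclustered(genes_cds, hits, catalog)
    sets <- shared_and_accessory_sets(catalog, classif, genes_cds, gids,
                                      refs[[grp]])
    write_stage_report(classif, file.path(out_dir, paste0("orthologs_", grp, ".tsv")), config)
    write_stage_report(sets$venn, file.path(out_dir, paste0("venn_", grp, ".tsv")), config)
    say("orthologs", grp, paste0(sets$core_count, " core clusters"))

    sc <- single_copy_table(catalog, lapply(genomes[gids], `[[`, "genes"))
    div_rows <- list()
    concat_rows <- list()
    aln_cache <- list()
    for (pr in combn(gids, 2, simplify = FALSE)) {
      shared <- sc |> filter(.data$genome %in% pr) |>
        group_by(.data$cluster) |> filter(n() == 2) |> ungroup()
      if (!nrow(shared)) next
      pair_lab <- paste(sort(pr), collapse = "-")
      alns <- list()
      for (cid in unique(shared$cluster)) {
        rowsc <- shared[shared$cluster == cid, ]
        cdsv <- setNames(rowsc$cds, rowsc$genome)[pr]
        aln <- codon_align_genes(cdsv)
        if (is.null(aln)) next
        alns[[cid]] <- aln
        rec <- tryCatch(ng86_divergence(aln, pair = pair_lab, gene_id = cid,
                                        ds_cap = config$ds_cap),
                        error = function(e) NULL)
        if (!is.null(rec)) div_rows[[paste(pair_lab, cid)]] <- rec
      }
      aln_cache[[pair_lab]] <- alns
      if (length(alns)) {
        concat_rows[[pair_lab]] <- concat_divergence(alns, pair = pair_lab,
                                                     ds_cap = config$ds_cap)
      }
    }
    div <- bind_rows(div_rows)
    write_stage_report(bind_rows(div, bind_rows(concat_rows)),
                       file.path(out_dir, paste0("divergence_", grp, ".tsv")), config)

    # ternary analysis on the first three genomes (sorted) of the group
    if (length(gids) >= 3 && nrow(div)) {
      trio <- sort(gids)[1:3]
      prs <- combn(trio, 2, simplify = FALSE)
      labs <- vapply(prs, function(p) paste(sort(p), collapse = "-"), character(1))
      wide <- div |> filter(.data$pair %in% labs) |>
        select("pair", "gene_id", "dS") |>
        tidyr::pivot_wider(names_from = "pair", values_from = "dS") |>
        tidyr::drop_na()
      if (nrow(wide)) {
        tp <- ternary_analysis(wide, cap = config$ds_cap)
        write_stage_report(tp$points, file.path(out_dir, paste0("ternary_", grp, ".tsv")), config)
        say("ternary", grp, paste0("spread_mean=", signif(tp$spread_mean, 4),
                                   ";spread_median=", signif(tp$spread_median, 4)))
      }
    }

    # recombination: 16S four-gamete bound + per-gene GI fragments
    rec_rows <- list()
    rrna <- genes_all[genes_all$product == "16S_rRNA", ]
    if (nrow(rrna) >= 4 && length(unique(nchar(rrna$cds))) == 1) {
      rm_16s <- minimum_recombination_events(setNames(rrna$cds, rrna$genome))
      say("recomb", grp, paste0("Rm_16S=", rm_16s))
      rec_rows[["rm"]] <- tibble(seq_a = "16S", seq_b = "16S", gscale = NA_integer_,
                                 start = NA_integer_, end = NA_integer_,
                                 length = NA_integer_, n_sites = rm_16s,
                                 score = NA_real_, p_value = NA_real_,
                                 gene_id = "16S_Rm")
    }
    multi <- sc |> group_by(.data$cluster) |>
      filter(dplyr::n_distinct(.data$genome) >= 3,
             dplyr::n_distinct(nchar(.data$cds)) == 1) |> ungroup()
    for (cid in unique(multi$cluster)) {
      rowsc <- multi[multi$cluster == cid, ]
      fr <- detect_gi_fragments(setNames(rowsc$cds, rowsc$genome),
                                gscale_set = config$gscale_set,
                                p_cutoff = config$fragment_p_cutoff,
                                permutations = config$permutations)
      if (nrow(fr)) rec_rows[[cid]] <- mutate(fr, gene_id = cid)
    }
    write_stage_report(bind_rows(rec_rows),
                       file.path(out_dir, paste0("recombination_", grp, ".tsv")), config)

    if (!is.null(manifest$origins) && nrow(manifest$origins)) {
      rm_tab <- manifest$origins |> group_by(.data$strain) |>
        summarise(rm_all = r_over_m(.data$origin, "all_positions"),
                  rm_confident = r_over_m(.data$origin, "confident_only"),
                  .groups = "drop")
      write_stage_report(rm_tab, file.path(out_dir, paste0("rm_", grp, ".tsv")), config)
    }

    # phylogeny: concatenated NJ tree + bootstrap + gene-tree concordance
    if (length(gids) >= 4) {
      allg <- sc |> group_by(.data$cluster) |>
        filter(dplyr::n_distinct(.data$genome) == length(gids),
               dplyr::n_distinct(nchar(.data$cds)) == 1) |> ungroup()
      cids <- unique(allg$cluster)
      if (length(cids)) {
        mats <- lapply(cids, function(cid) {
          r <- allg[allg$cluster == cid, ]
          setNames(r$cds, r$genome)[gids]
        })
        concat <- vapply(gids, function(g) {
          paste(vapply(mats, `[[`, character(1), g), collapse = "")
        }, character(1))
        st <- tryCatch(bootstrap_support(concat, config$bootstrap_reps),
                       error = function(e) NULL)
        if (!is.null(st)) {
          ape::write.tree(st$tree, file.path(out_dir, paste0("tree_", grp, ".nwk")))
          gene_trees <- purrr::compact(lapply(mats, function(mv) {
            tryCatch(build_tree(mv), error = function(e) NULL)
          }))
          conc <- topology_concordance(gene_trees, st, config$support_threshold)
          write_stage_report(left_join(conc, st$splits, by = "split"),
                             file.path(out_dir, paste0("concordance_", grp, ".tsv")), config)
          say("phylo", grp, paste0(length(gene_trees), " gene trees"))
        }
      }
    }
  }

  writeLines(c("stage\tkey\tvalue", log_lines), file.path(out_dir, "run_log.tsv"))
  invisible(out_dir)
}
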