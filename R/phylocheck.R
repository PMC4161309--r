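# Distance-based phylogenetics: JC-corrected neighbor-joining trees,
# nonparametric bootstrap support, and counting single-gene trees concordant
# with the splits of a concatenated tree.

# pairwise JC distance matrix with pairwise deletion; errors on saturation
jc_distance_matrix <- function(m) {
  ns <- nrow(m)
  d <- matrix(0, ns, ns, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      ok <- m[i, ] %in% BASES & m[j, ] %in% BASES
      p <- mean(m[i, ok] != m[j, ok])
      if (p >= 0.75) {
        abort(sprintf("saturated distance (p = %.3f) between '%s' and '%s'",
                      p, rownames(m)[i], rownames(m)[j]))
      }
      d[i, j] <- d[j, i] <- unname(jc_correct(p))
    }
  }
  d
}

# clamp negative NJ branch lengths to zero, moving the deficit to the
# sibling edge of the same parent node
clamp_negative_edges <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == parent)
    sib <- setdiff(sib, e)
    if (length(sib)) {
      s <- sib[1]
      tree$edge.length[s] <- max(0, tree$edge.length[s] + deficit)
    }
  }
  tree
}

#' Build a neighbor-joining tree from an alignment
#'
#' JC-corrected pairwise distances (pairwise deletion) and NJ via
#' [ape::nj()]. Negative branch lengths are clamped to zero with the
#' deficit moved to the sibling edge. A saturated pair (p >= 3/4) is an
#' error naming the pair.
#'
#' @param aln character vector of >= 3 aligned sequences (or a matrix from
#'   `aln_matrix`).
#' @return a `supported_tree`: list with `tree` (phylo) and `splits` (NULL
#'   until bootstrapped).
#' @export
build_tree <- function(aln) {
  m <- if (is.matrix(aln)) aln else aln_matrix(aln)
  stopifnot(nrow(m) >= 3)
  d <- jc_distance_matrix(m)
  tree <- ape::nj(as.dist(d))
  tree <- clamp_negative_edges(tree)
  structure(list(tree = tree, splits = NULL), class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("<supported_tree>", length(x$tree$tip.label), "tips")
  if (!is.null(x$splits)) cat(";", nrow(x$splits), "splits with support")
  cat("\n")
  invisible(x)
}

# canonical string for each non-trivial split of an unrooted tree: the side
# not containing the alphabetically first taxon, sorted and joined by ","
tree_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  anchor <- labs[1]
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    side <- tree$tip.label[p]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2 && length(side) <= length(labs) - 2) {
      out <- c(out, paste(sort(side), collapse = ","))
    }
  }
  unique(out)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `reps` times, rebuilds the
#' tree, and reports for each internal split of the point-estimate tree the
#' percentage of replicate trees containing it. Deterministic for a fixed
#' RNG state.
#'
#' @param aln alignment (>= 4 sequences for internal splits).
#' @param reps bootstrap replicates (default 100).
#' @return a `supported_tree` with a `splits` tibble (split, support).
#' @export
bootstrap_support <- function(aln, reps = 100L) {
  m <- if (is.matrix(aln)) aln else aln_matrix(aln)
  point <- build_tree(m)
  sp <- tree_splits(point$tree)
  if (!length(sp)) {
    point$splits <- tibble(split = character(), support = numeric())
    return(point)
  }
  hits <- setNames(numeric(length(sp)), sp)
  done <- 0L
  for (r in seq_len(reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    bt <- tryCatch(build_tree(m[, cols, drop = FALSE]), error = function(e) NULL)
    if (is.null(bt)) next
    done <- done + 1L
    bs <- tree_splits(bt$tree)
    hits[sp %in% bs] <- hits[sp %in% bs] + 1
  }
  point$splits <- tibble(split = sp,
                         support = round(100 * hits / max(done, 1), 1))
  point
}

# split of a pruned tree, canonicalised on the common taxon set
restricted_splits <- function(tree, taxa) {
  keep <- intersect(tree$tip.label, taxa)
  if (length(keep) < 4) return(character(0))
  sub <- ape::keep.tip(tree, keep)
  tree_splits(sub)
}

canonical_split <- function(side, all_taxa) {
  anchor <- sort(all_taxa)[1]
  if (anchor %in% side) side <- setdiff(all_taxa, side)
  paste(sort(side), collapse = ",")
}

#' Count gene trees concordant with reference splits
#'
#' For each non-trivial split of the reference (concatenated) tree, counts
#' the gene trees whose topology, restricted to the taxa they share with
#' the split, contains it; gene trees that cannot display the split
#' (missing taxa leaving fewer than 2 taxa on either side) are excluded
#' from that split's denominator. Gene trees carrying bootstrap supports
#' are additionally tallied when their own support for the split reaches
#' `support_threshold`.
#'
#' @param gene_trees list of `supported_tree` (or phylo) objects.
#' @param reference_tree the concatenated `supported_tree` (or phylo).
#' @param support_threshold percent support counted as supported (default 80).
#' @return tibble: split, n_eval, n_congruent, pct_congruent, n_supported,
#'   pct_supported.
#' @export
topology_concordance <- function(gene_trees, reference_tree,
                                 support_threshold = 80) {
  ref <- if (inherits(reference_tree, "supported_tree")) reference_tree$tree else reference_tree
  ref_splits <- tree_splits(ref)
  all_taxa <- ref$tip.label
  res <- list()
  for (s in ref_splits) {
    side <- strsplit(s, ",", fixed = TRUE)[[1]]
    other <- setdiff(all_taxa, side)
    n_eval <- 0L; n_cong <- 0L; n_sup <- 0L
    for (gt in gene_trees) {
      tr <- if (inherits(gt, "supported_tree")) gt$tree else gt
      sup <- if (inherits(gt, "supported_tree")) gt$splits else NULL
      common <- intersect(tr$tip.label, all_taxa)
      s1 <- intersect(side, common)
      s2 <- intersect(other, common)
      if (length(s1) < 2 || length(s2) < 2) next
      gsplits <- restricted_splits(tr, common)
      if (!length(gsplits)) next
      n_eval <- n_eval + 1L
      target <- canonical_split(s1, common)
      if (target %in% gsplits) {
        n_cong <- n_cong + 1L
        if (!is.null(sup)) {
          # support is looked up on the gene tree's own (unpruned) splits
          full_target <- vapply(sup$split, function(x) {
            gs <- strsplit(x, ",", fixed = TRUE)[[1]]
            canonical_split(intersect(gs, common), common) == target ||
              canonical_split(setdiff(common, gs), common) == target
          }, logical(1))
          if (any(full_target) && max(sup$support[full_target]) >= support_threshold) {
            n_sup <- n_sup + 1L
          }
        }
      }
    }
    if (length(side) < 2 || length(other) < 2) {
      warn(sprintf("split %s has fewer than 2 taxa on a side; skipped", s))
      next
    }
    res[[length(res) + 1]] <- tibble(
      split = s, n_eval = n_eval, n_congruent = n_cong,
      pct_congruent = if (n_eval) round(100 * n_cong / n_eval, 1) else NA_real_,
      n_supported = n_sup,
      pct_supported = if (n_eval) round(100 * n_sup / n_eval, 1) else NA_real_)
  }
  bind_rows(res)
}
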