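# Divergence statistics: codon alignments, NG86 counting with Jukes-Cantor
# correction, 16S nucleotide diversity and pairwise identity, sliding-window
# divergence tracks, and the ternary relative-dS analysis.

#' Back-translate a protein alignment into a codon alignment
#'
#' Each aligned residue is replaced by its source codon; protein gaps become
#' triple nucleotide gaps. The degapped protein must equal the translation
#' of its CDS (trailing stops in the CDS are tolerated).
#'
#' @param protein_aln named character vector, aligned proteins.
#' @param cds named character vector of in-frame CDS, same names.
#' @return named character vector: the codon alignment (class
#'   `codon_alignment`).
#' @export
backtranslate <- function(protein_aln, cds) {
  protein_aln <- as_aln(protein_aln)
  stopifnot(all(names(protein_aln) %in% names(cds)))
  out <- vapply(names(protein_aln), function(nm) {
    aa <- seq_chars(protein_aln[[nm]])
    one <- toupper(cds[[nm]])
    codons <- split_codons(one)
    tr <- translate_codons(codons)
    if (length(tr) && tr[length(tr)] == "*") {
      codons <- codons[-length(codons)]
      tr <- tr[-length(tr)]
    }
    res <- aa[aa != "-"]
    if (length(res) != length(tr) || any(res != tr)) {
      bad <- which(res != tr[seq_along(res)])[1] %||% length(tr) + 1L
      abort(sprintf("CDS of '%s' does not translate to its aligned protein (residue %d)",
                    nm, bad))
    }
    filled <- character(length(aa))
    filled[aa == "-"] <- "---"
    filled[aa != "-"] <- codons
    paste(filled, collapse = "")
  }, character(1))
  structure(as_aln(out), class = c("codon_alignment", "character"))
}

# codon columns of a pairwise codon alignment, dropping columns with gaps,
# ambiguity or stop codons in either sequence (complete deletion per pair)
comparable_codons <- function(a, b) {
  ca <- split_codons(a)
  cb <- split_codons(b)
  sense <- sense_codons()
  ok <- ca %in% sense & cb %in% sense
  list(a = ca[ok], b = cb[ok])
}

divergence_record <- function(pair = NA_character_, gene_id = NA_character_,
                              dS, dN, estimator, saturated) {
  omega <- ifelse(is.finite(dS) & dS > 0, dN / dS, NA_real_)
  tibble(pair = pair, gene_id = gene_id, dS = dS, dN = dN, omega = omega,
         estimator = estimator, saturated = saturated)
}

#' Nei-Gojobori (1986) divergence with Jukes-Cantor correction
#'
#' Counts synonymous and nonsynonymous sites (averaged between the two
#' sequences) and differences (multi-step codons averaged over shortest
#' mutational paths avoiding stop codons), then applies the Jukes-Cantor
#' correction `d = -3/4 log(1 - 4p/3)` to the proportions. A synonymous
#' p-distance at or beyond 3/4 is saturated: dS is reported capped at
#' `ds_cap` with the `saturated` flag set.
#'
#' @param aln character vector of two aligned CDS (gaps `-`), or a
#'   `codon_alignment`.
#' @param pair,gene_id optional labels carried into the record.
#' @param ds_cap cap for saturated dS (default 3).
#' @return one-row divergence record tibble: pair, gene_id, dS, dN, omega,
#'   estimator = "NG86", saturated.
#' @export
ng86_divergence <- function(aln, pair = NA_character_, gene_id = NA_character_,
                            ds_cap = 3) {
  aln <- as_aln(aln)
  stopifnot(length(aln) == 2)
  cc <- comparable_codons(aln[[1]], aln[[2]])
  n <- length(cc$a)
  if (n < 10) abort(sprintf("only %d comparable codons (need >= 10)", n))
  ss <- codon_syn_sites()
  S <- (sum(ss[cc$a]) + sum(ss[cc$b])) / 2
  N <- 3 * n - S
  dt <- codon_diff_tables()
  idx <- cbind(match(cc$a, colnames(dt$syn)), match(cc$b, colnames(dt$syn)))
  Sd <- sum(dt$syn[idx])
  Nd <- sum(dt$non[idx])
  pS <- Sd / S
  pN <- Nd / N
  saturated <- pS >= 0.75
  dS <- if (saturated) ds_cap else unname(jc_correct(pS))
  dN <- if (pN >= 0.75) ds_cap else unname(jc_correct(pN))
  saturated <- saturated || dS >= 3
  divergence_record(pair, gene_id, dS, dN, "NG86", saturated)
}

#' Nucleotide diversity (pi) of a multiple alignment
#'
#' Average over all sequence pairs of the proportion of differing sites,
#' each pair compared over its ungapped, unambiguous columns.
#'
#' @param aln named character vector of >= 2 aligned sequences.
#' @return pi (numeric scalar).
#' @export
nucleotide_diversity <- function(aln) {
  m <- aln_matrix(aln)
  ns <- nrow(m)
  stopifnot(ns >= 2)
  ps <- c()
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      ok <- m[i, ] %in% BASES & m[j, ] %in% BASES
      if (!any(ok)) abort(sprintf("no comparable columns between '%s' and '%s'",
                                  rownames(m)[i], rownames(m)[j]))
      ps <- c(ps, mean(m[i, ok] != m[j, ok]))
    }
  }
  mean(ps)
}

#' Pairwise percent identity after global alignment
#'
#' Ends-free global alignment (overhangs unpenalised, mirroring the usual
#' treatment of 16S fragments of unequal length); identity is matches over
#' aligned columns excluding end gaps, reported to two decimals.
#'
#' @param a,b sequences (character scalars).
#' @return percent identity.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "overlap", gapOpening = 10, gapExtension = 0.5)
  pa <- as.character(Biostrings::alignedPattern(al))
  ps <- as.character(Biostrings::alignedSubject(al))
  va <- seq_chars(pa); vs <- seq_chars(ps)
  round(100 * sum(va == vs) / length(va), 2)
}

#' Sliding-window Jukes-Cantor divergence track
#'
#' Columns containing any gap are stripped first. Windows start at positions
#' 1, 1+step, 1+2*step, ... of the gap-stripped alignment; only full windows
#' are evaluated. Per window the mean pairwise p-distance is Jukes-Cantor
#' corrected; saturated windows (p >= 3/4) are reported as `NA`.
#'
#' @param aln character vector of >= 2 aligned sequences.
#' @param window window size in nt (default 200).
#' @param step step size in nt (default 50).
#' @return tibble: start, end, midpoint, p, divergence.
#' @export
sliding_window_divergence <- function(aln, window = 200L, step = 50L) {
  m <- aln_matrix(aln)
  keep <- colSums(m == "-") == 0
  m <- m[, keep, drop = FALSE]
  len <- ncol(m)
  if (len < window) abort(sprintf("gap-stripped alignment (%d nt) shorter than window (%d nt)",
                                  len, window))
  starts <- seq(1L, len - window + 1L, by = step)
  pairs <- combn(nrow(m), 2)
  res <- purrr::map_dfr(starts, function(s) {
    w <- m[, s:(s + window - 1L), drop = FALSE]
    p <- mean(apply(pairs, 2, function(ij) {
      ok <- w[ij[1], ] %in% BASES & w[ij[2], ] %in% BASES
      if (!any(ok)) return(NA_real_)
      mean(w[ij[1], ok] != w[ij[2], ok])
    }), na.rm = TRUE)
    tibble(start = s, end = s + window - 1L, midpoint = s + (window - 1) / 2,
           p = p, divergence = unname(jc_correct(p)))
  })
  res
}

#' Ternary relative-dS analysis
#'
#' For each gene with three pairwise dS values, caps the values at `cap`,
#' normalises the triplet to sum to 1, assigns a colour category from the
#' maximum raw dS (< 0.1 yellow, >= 0.1 orange, >= 1 red) and computes the
#' spread: the mean and the median Euclidean distance from the normalised
#' points to their mean point in the simplex plane. Genes whose capped
#' triplet sums to zero are dropped (and counted).
#'
#' @param triplets tibble with a `gene_id` column and exactly three dS
#'   columns (one per genome pair).
#' @param cap maximum dS (default 3).
#' @param spread_mode which spread to report as `spread` ("mean" default,
#'   or "median"); both are always returned.
#' @return object of class `ternary_points`: list with `points` tibble
#'   (gene_id, x, y, z, category, capped), `spread`, `spread_mean`,
#'   `spread_median`, `dropped` (gene ids with zero triplets),
#'   `pair_names`.
#' @export
ternary_analysis <- function(triplets, cap = 3, spread_mode = c("mean", "median")) {
  spread_mode <- match.arg(spread_mode)
  stopifnot("gene_id" %in% names(triplets))
  val_cols <- setdiff(names(triplets), "gene_id")
  if (length(val_cols) != 3) abort("triplets must have exactly three dS columns")
  raw <- as.matrix(triplets[val_cols])
  if (any(raw < 0, na.rm = TRUE)) abort("negative dS values are not allowed")
  if (any(!is.finite(raw))) abort("all dS values must be finite")
  capped_m <- pmin(raw, cap)
  sums <- rowSums(capped_m)
  drop <- sums == 0
  norm <- capped_m[!drop, , drop = FALSE] / sums[!drop]
  maxraw <- apply(raw[!drop, , drop = FALSE], 1, max)
  category <- ifelse(maxraw >= 1, "red", ifelse(maxraw >= 0.1, "orange", "yellow"))
  points <- tibble(gene_id = triplets$gene_id[!drop],
                   x = unname(norm[, 1]), y = unname(norm[, 2]),
                   z = unname(norm[, 3]),
                   category = category,
                   capped = apply(raw[!drop, , drop = FALSE] > cap, 1, any))
  if (nrow(norm)) {
    centre <- colMeans(norm)
    d <- sqrt(rowSums(sweep(norm, 2, centre)^2))
    spread_mean <- mean(d)
    spread_median <- median(d)
  } else {
    spread_mean <- spread_median <- NA_real_
  }
  structure(list(points = points,
                 spread = if (spread_mode == "mean") spread_mean else spread_median,
                 spread_mean = spread_mean,
                 spread_median = spread_median,
                 dropped = triplets$gene_id[drop],
                 pair_names = val_cols),
            class = "ternary_points")
}

#' @export
print.ternary_points <- function(x, ...) {
  cat("<ternary_points>", nrow(x$points), "genes; spread(mean) =",
      signif(x$spread_mean, 4), "; spread(median) =",
      signif(x$spread_median, 4), "\n")
  invisible(x)
}
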