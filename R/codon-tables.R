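# Codon bookkeeping shared by the NG86 counter, the ML codon model and the
# simulator. Everything is computed once per session and cached in .sagevo.

genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

translate_codons <- function(codons) {
  gc <- genetic_code()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate a coding sequence
#'
#' @param cds character scalar, in-frame coding sequence (length a multiple
#'   of 3). Codons containing characters other than A/C/G/T translate to `X`.
#' @return character scalar of amino acids (stop as `*`).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds) %/% 3
  if (n == 0) return("")
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(translate_codons(codons), collapse = "")
}

split_codons <- function(cds) {
  n <- nchar(cds) %/% 3
  substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# Synonymous site counts per sense codon: at each position, the fraction of
# the three alternative bases that keep the amino acid (changes to stop codons
# count as nonsynonymous opportunity). S + N = 3 per codon.
codon_syn_sites <- function() {
  if (!is.null(.sagevo$syn_sites)) return(.sagevo$syn_sites)
  gc <- genetic_code()
  codons <- sense_codons()
  s <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    ch <- seq_chars(cd)
    aa <- gc[[cd]]
    nsyn <- 0
    for (p in 1:3) {
      for (b in setdiff(BASES, ch[p])) {
        alt <- ch
        alt[p] <- b
        if (gc[[chars_seq(alt)]] == aa) nsyn <- nsyn + 1
      }
    }
    s[cd] <- nsyn / 3
  }
  .sagevo$syn_sites <- s
  s
}

# Average synonymous / nonsynonymous differences between every ordered codon
# pair, averaging over all mutational paths that avoid stop codons (all paths
# if every path passes through a stop). Returned as two 61x61 matrices.
codon_diff_tables <- function() {
  if (!is.null(.sagevo$diff_tables)) return(.sagevo$diff_tables)
  gc <- genetic_code()
  codons <- sense_codons()
  nc <- length(codons)
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  syn <- matrix(0, nc, nc, dimnames = list(codons, codons))
  non <- matrix(0, nc, nc, dimnames = list(codons, codons))
  chmat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      dpos <- which(chmat[i, ] != chmat[j, ])
      k <- length(dpos)
      paths <- perms[[as.character(k)]]
      tally <- matrix(NA_real_, length(paths), 2)
      for (pi in seq_along(paths)) {
        ord <- dpos[paths[[pi]]]
        cur <- chmat[i, ]
        sdiff <- 0; ndiff <- 0; ok <- TRUE
        for (p in ord) {
          nxt <- cur
          nxt[p] <- chmat[j, p]
          aa_cur <- gc[[chars_seq(cur)]]
          aa_nxt <- gc[[chars_seq(nxt)]]
          if (aa_nxt == "*") { ok <- FALSE; break }
          if (aa_cur == aa_nxt) sdiff <- sdiff + 1 else ndiff <- ndiff + 1
          cur <- nxt
        }
        if (ok) tally[pi, ] <- c(sdiff, ndiff)
      }
      if (all(is.na(tally[, 1]))) {
        # all paths blocked by stops: average over all paths, counting the
        # blocked steps as nonsynonymous
        tally <- matrix(NA_real_, length(paths), 2)
        for (pi in seq_along(paths)) {
          ord <- dpos[paths[[pi]]]
          cur <- chmat[i, ]
          sdiff <- 0; ndiff <- 0
          for (p in ord) {
            nxt <- cur
            nxt[p] <- chmat[j, p]
            aa_cur <- gc[[chars_seq(cur)]]
            aa_nxt <- if (gc[[chars_seq(nxt)]] == "*") "*" else gc[[chars_seq(nxt)]]
            if (aa_cur == aa_nxt) sdiff <- sdiff + 1 else ndiff <- ndiff + 1
            cur <- nxt
          }
          tally[pi, ] <- c(sdiff, ndiff)
        }
      }
      mu <- colMeans(tally, na.rm = TRUE)
      syn[i, j] <- syn[j, i] <- mu[1]
      non[i, j] <- non[j, i] <- mu[2]
    }
  }
  .sagevo$diff_tables <- list(syn = syn, non = non)
  .sagevo$diff_tables
}

# Single-nucleotide neighbour structure among sense codons, used to build the
# GY94 rate matrix: index pairs, transition flag, synonymous flag.
codon_pair_index <- function() {
  if (!is.null(.sagevo$pair_index)) return(.sagevo$pair_index)
  gc <- genetic_code()
  codons <- sense_codons()
  nc <- length(codons)
  chmat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  ts_pairs <- c("AG", "GA", "CT", "TC")
  ii <- integer(0); jj <- integer(0); ts <- logical(0); sy <- logical(0)
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (i == j) next
      dpos <- which(chmat[i, ] != chmat[j, ])
      if (length(dpos) != 1) next
      ii <- c(ii, i); jj <- c(jj, j)
      ts <- c(ts, paste0(chmat[i, dpos], chmat[j, dpos]) %in% ts_pairs)
      sy <- c(sy, gc[[codons[i]]] == gc[[codons[j]]])
    }
  }
  .sagevo$pair_index <- list(codons = codons, i = ii, j = jj,
                             transition = ts, synonymous = sy)
  .sagevo$pair_index
}
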