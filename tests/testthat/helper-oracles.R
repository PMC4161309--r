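# Independent oracles and small fixture builders used across the suite.

# exhaustive minimum-recombination oracle: maximum set of pairwise
# non-overlapping four-gamete intervals found by branch-and-bound search
# over every subset (independent of the greedy Hudson-Kaplan path)
oracle_rm <- function(m) {
  sites <- list()
  for (j in seq_len(ncol(m))) {
    u <- unique(m[, j])
    u <- u[u %in% c("A", "C", "G", "T")]
    if (length(u) == 2) sites[[length(sites) + 1]] <- ifelse(m[, j] == u[1], 0L, 1L)
  }
  ns <- length(sites)
  if (ns < 2) return(0L)
  iv <- list()
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      if (length(unique(paste0(sites[[i]], sites[[j]]))) == 4) {
        iv[[length(iv) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(iv)) return(0L)
  iv <- do.call(rbind, iv)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  best <- 0L
  recurse <- function(k, bound, count) {
    best <<- max(best, count)
    if (k > nrow(iv)) return()
    if (count + (nrow(iv) - k + 1L) <= best) return()
    if (iv[k, 1] >= bound) recurse(k + 1L, iv[k, 2], count + 1L)
    recurse(k + 1L, bound, count)
  }
  recurse(1L, -1L, 0L)
  best
}

random_binary_alignment <- function(nseq, nsite) {
  m <- matrix(sample(c("A", "C"), nseq * nsite, replace = TRUE), nseq)
  rownames(m) <- paste0("t", seq_len(nseq))
  m
}

# plain dense MCL reference (no pruning) for tiny matrices
dense_mcl <- function(adj, inflation, iter = 100) {
  diag(adj) <- apply(adj, 2, max)
  M <- sweep(adj, 2, colSums(adj), "/")
  for (i in seq_len(iter)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
  }
  g <- (M > 1e-6) | (t(M) > 1e-6)
  comp <- rep(0L, nrow(adj))
  cur <- 0L
  for (s in seq_len(nrow(adj))) {
    if (comp[s]) next
    cur <- cur + 1L
    q <- s
    while (length(q)) {
      v <- q[[1]]; q <- q[-1]
      if (comp[v]) next
      comp[v] <- cur
      q <- c(q, which(g[v, ] & comp == 0))
    }
  }
  comp
}

# exact expected synonymous p-distance between two descendants separated by
# total divergence d under the thinned codon process (candidate rate 1 per
# site, uniform proposals, nonsynonymous acceptance omega, stops rejected),
# ancestor uniform over sense codons; computed by matrix exponential of the
# symmetric 61-state chain -- an independent check on the Gillespie engine
expected_syn_pdist <- function(d, omega) {
  codons <- Biostrings::GENETIC_CODE
  sense <- names(codons)[codons != "*"]
  nc <- length(sense)
  chm <- do.call(rbind, strsplit(sense, "", fixed = TRUE))
  Q <- matrix(0, nc, nc)
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (i == j) next
      dp <- which(chm[i, ] != chm[j, ])
      if (length(dp) != 1) next
      Q[i, j] <- (1 / 3) * if (codons[[sense[i]]] == codons[[sense[j]]]) 1 else omega
    }
  }
  diag(Q) <- -rowSums(Q)
  e <- eigen(Q, symmetric = TRUE)
  P <- e$vectors %*% diag(exp(e$values * d / 2)) %*% t(e$vectors)
  # per-codon synonymous sites and pairwise synonymous differences
  ss <- sagevo:::codon_syn_sites()[sense]
  dt <- sagevo:::codon_diff_tables()
  Sd_tab <- dt$syn[sense, sense]
  pi0 <- rep(1 / nc, nc)
  pair_prob <- matrix(0, nc, nc)
  for (c0 in seq_len(nc)) {
    pair_prob <- pair_prob + pi0[c0] * (P[c0, ] %o% P[c0, ])
  }
  ESd <- sum(pair_prob * Sd_tab)
  ES <- sum(rowSums(pair_prob) * ss + colSums(pair_prob) * ss) / 2
  ESd / ES
}

# tiny two-contig assembly with a couple of genes, used by io/contigqc tests
tiny_bundle <- function() {
  set.seed(424)
  g1 <- paste(sample(sagevo:::sense_codons(), 120, replace = TRUE), collapse = "")
  g2 <- paste(sample(sagevo:::sense_codons(), 80, replace = TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  c1 <- paste0(pad(50), g1, pad(60))
  c2 <- paste0(pad(30), revcomp(g2), pad(40))
  asm <- genome_assembly("tiny", c(ctg1 = c1, ctg2 = c2),
                         c(ctg1 = 40, ctg2 = 12))
  genes <- tibble::tibble(
    genome = "tiny", contig = c("ctg1", "ctg2", "ctg1"),
    gene_id = c("gA", "gB", "gC"),
    start = c(51L, 31L, 11L), end = c(50L + 360L, 30L + 240L, 110L),
    strand = c("+", "-", "+"),
    product = c("protein A", "protein B", "protein C"))
  list(assembly = asm, genes = extract_genes(asm, genes))
}
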