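# Pairwise maximum-likelihood divergence under a Goldman-Yang-style codon
# model with F3x4 codon frequencies and free parameters t (divergence),
# kappa (transition/transversion) and omega (dN/dS). Expected synonymous and
# nonsynonymous substitution counts come from the fitted model's flow; they
# are converted to rates per site using the same physical (NG86-style) site
# counts used by the counting estimator, in which mutations to stop codons
# count as nonsynonymous opportunity. Keeping one site convention across
# both estimators makes their dS directly comparable (codeml instead
# excludes stop mutations from the opportunity, which deflates dS by the
# stop-neighbour flow, about 4-5% under the standard code).

# F3x4 codon frequencies from the pooled position-specific nucleotide
# composition of the two sequences, with a small floor so no sense codon has
# zero frequency.
f3x4_frequencies <- function(codons_a, codons_b) {
  sense <- sense_codons()
  all_cod <- c(codons_a, codons_b)
  chm <- do.call(rbind, strsplit(all_cod, "", fixed = TRUE))
  posfreq <- sapply(1:3, function(p) {
    tab <- table(factor(chm[, p], levels = BASES))
    as.numeric(tab) / sum(tab)
  })
  rownames(posfreq) <- BASES
  schm <- do.call(rbind, strsplit(sense, "", fixed = TRUE))
  pi <- posfreq[schm[, 1], 1] * posfreq[schm[, 2], 2] * posfreq[schm[, 3], 3]
  pi <- pi + 1e-8
  setNames(pi / sum(pi), sense)
}

# normalised GY94 rate matrix (expected substitutions per codon = 1)
gy94_Q <- function(kappa, omega, pi) {
  px <- codon_pair_index()
  nc <- length(px$codons)
  Q <- matrix(0, nc, nc, dimnames = list(px$codons, px$codons))
  rate <- pi[px$j] * ifelse(px$transition, kappa, 1) *
    ifelse(px$synonymous, 1, omega)
  Q[cbind(px$i, px$j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

# proportion of flow through synonymous changes under a normalised Q
syn_flow <- function(Q, pi) {
  px <- codon_pair_index()
  flows <- pi[px$i] * Q[cbind(px$i, px$j)]
  sum(flows[px$synonymous]) / sum(flows)
}

# transition probabilities via symmetrised eigendecomposition (reversible Q)
gy94_P <- function(Q, pi, t) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  P <- (1 / d) * (e$vectors %*% (exp(e$values * t) * t(e$vectors))) * rep(d, each = length(d))
  P[P < 1e-300] <- 1e-300
  P
}

#' Pairwise maximum-likelihood dS/dN under a codon model
#'
#' Fits t, kappa and omega by maximising the two-sequence likelihood of a
#' GY94-style codon model with F3x4 frequencies (codon-pair counts, columns
#' with gaps/ambiguity/stops dropped pairwise). dS and dN are derived from
#' the fitted parameters and the model's expected proportions of synonymous
#' substitutions and sites. The optimiser runs a bounded quasi-Newton search
#' from three fixed starting divergences (t = 0.1, 1, 3), so results are
#' deterministic. Identical sequences return dS = dN = 0 exactly.
#'
#' @inheritParams ng86_divergence
#' @return one-row divergence record tibble (estimator = "ML").
#' @export
ml_pairwise_divergence <- function(aln, pair = NA_character_,
                                   gene_id = NA_character_, ds_cap = 3) {
  aln <- as_aln(aln)
  stopifnot(length(aln) == 2)
  cc <- comparable_codons(aln[[1]], aln[[2]])
  n <- length(cc$a)
  if (n < 10) abort(sprintf("only %d comparable codons (need >= 10)", n))
  if (all(cc$a == cc$b)) {
    return(divergence_record(pair, gene_id, 0, 0, "ML", FALSE))
  }
  sense <- sense_codons()
  counts <- table(factor(cc$a, levels = sense), factor(cc$b, levels = sense))
  counts <- unclass(counts)
  nz <- which(counts > 0, arr.ind = TRUE)
  cnt <- counts[nz]
  pi <- f3x4_frequencies(cc$a, cc$b)
  negll <- function(par) {
    t <- exp(par[1]); kappa <- exp(par[2]); omega <- exp(par[3])
    Q <- gy94_Q(kappa, omega, pi)
    P <- gy94_P(Q, pi, t)
    ll <- sum(cnt * log(pi[nz[, 1]] * P[nz]))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  lower <- log(c(1e-5, 0.05, 1e-4))
  upper <- log(c(60, 60, 40))
  best <- NULL
  for (t0 in c(0.1, 1, 3)) {
    fit <- tryCatch(
      optim(log(c(t0, 2, 0.5)), negll, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(divergence_record(pair, gene_id, 0, 0, "ML", FALSE))
  t <- exp(best$par[1]); kappa <- exp(best$par[2]); omega <- exp(best$par[3])
  Q <- gy94_Q(kappa, omega, pi)
  rhoS <- syn_flow(Q, pi)
  ss <- codon_syn_sites()
  S <- (sum(ss[cc$a]) + sum(ss[cc$b])) / 2
  dS <- t * rhoS * n / S
  dN <- t * (1 - rhoS) * n / (3 * n - S)
  divergence_record(pair, gene_id, dS, dN, "ML", dS >= 3)
}

#' Maximum-likelihood divergence of concatenated gene alignments
#'
#' Genes are concatenated in canonical (sorted gene id) order and the ML
#' estimator applied once; results are invariant to the input order.
#'
#' @param alignments named list of pairwise codon alignments (each a
#'   2-sequence character vector with the same sequence names).
#' @param pair optional pair label.
#' @param ds_cap saturation cap.
#' @return one-row divergence record (gene_id = "concatenated").
#' @export
concat_divergence <- function(alignments, pair = NA_character_, ds_cap = 3) {
  if (!length(alignments)) abort("empty gene set")
  alignments <- alignments[order(names(alignments))]
  nms <- names(alignments[[1]])
  cat1 <- paste(vapply(alignments, function(a) a[[nms[1]]], character(1)),
                collapse = "")
  cat2 <- paste(vapply(alignments, function(a) a[[nms[2]]], character(1)),
                collapse = "")
  ml_pairwise_divergence(setNames(c(cat1, cat2), nms), pair = pair,
                         gene_id = "concatenated", ds_cap = ds_cap)
}
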