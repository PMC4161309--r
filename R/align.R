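# Local protein alignment helpers (Biostrings pairwiseAlignment, BLOSUM62)
# with a fixed Karlin-Altschul calibration so raw scores can be gated at an
# E-value, reproducing a translated-search cutoff without an external tool.

KA_LAMBDA <- 0.267
KA_K <- 0.041

protein_submat <- function() {
  if (is.null(.sagevo$blosum62)) {
    e <- new.env(parent = emptyenv())
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .sagevo$blosum62 <- as.matrix(e$BLOSUM62)
  }
  .sagevo$blosum62
}

# vectorised local-alignment scores of many patterns vs one subject
protein_scores <- function(patterns, subject) {
  if (!length(patterns)) return(numeric(0))
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = protein_submat(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
}

# E-value of a raw local score for a query of length m vs a database of n
# residues, E = K m n exp(-lambda S)
ka_evalue <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

# full local alignment with identity (matches over aligned columns excluding
# gaps) and coverage of both sequences (aligned footprint / length)
protein_local_align <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = protein_submat(),
    gapOpening = 11, gapExtension = 1)
  nm <- Biostrings::nmatch(al)
  nmm <- Biostrings::nmismatch(al)
  pat <- Biostrings::pattern(al)
  sub <- Biostrings::subject(al)
  qspan <- Biostrings::end(pat) - Biostrings::start(pat) + 1L
  sspan <- Biostrings::end(sub) - Biostrings::start(sub) + 1L
  list(score = Biostrings::score(al),
       identity = if (nm + nmm > 0) 100 * nm / (nm + nmm) else 0,
       qcov = qspan / nchar(a),
       scov = sspan / nchar(b),
       align_len = nchar(as.character(Biostrings::alignedPattern(al))))
}

# translations of a nucleotide fragment in the three forward frames
three_frames <- function(seq) {
  vapply(0:2, function(f) {
    n <- nchar(seq) - f
    if (n < 3) return("")
    translate_cds(substr(seq, f + 1, f + (n %/% 3) * 3))
  }, character(1))
}

# six-frame translations (forward + reverse complement)
six_frames <- function(seq) {
  c(three_frames(seq), three_frames(revcomp(seq)))
}
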