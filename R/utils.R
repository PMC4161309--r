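BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

#' Reverse complement of character sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that keeps
#' sequences as plain character vectors, the representation used internally.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split one sequence into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

# matrix of aligned sequences (rows = sequences) from named character vector
aln_matrix <- function(aln) {
  aln <- as_aln(aln)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

# coerce DNAStringSet / character to a named, uppercased character vector and
# check equal lengths
as_aln <- function(aln, check_equal = TRUE) {
  if (inherits(aln, "XStringSet")) aln <- as.character(aln)
  if (!is.character(aln)) abort("alignment must be a character vector or XStringSet")
  aln <- toupper(aln)
  if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
  if (check_equal && length(unique(nchar(aln))) > 1) {
    abort("aligned sequences must all have the same length")
  }
  aln
}

#' Jukes-Cantor distance correction
#'
#' Corrects an observed proportion of differing sites `p` for multiple hits
#' under the Jukes-Cantor model, `d = -3/4 log(1 - 4p/3)`. Values of `p` at or
#' beyond the model's ceiling of 3/4 are returned as `NA` (saturated).
#'
#' @param p numeric vector of p-distances in `[0, 1]`.
#' @return numeric vector of corrected distances.
#' @export
jc_correct <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  out[p == 0] <- 0
  out
}

# hash of a configuration (or any R object) for report stamping
config_hash <- function(x) rlang::hash(x)

draw_seed <- function() sample.int(.Machine$integer.max, 1)
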