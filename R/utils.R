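# Shared low-level helpers. All sequence work is on plain uppercase character
# strings over {A,C,G,T,N}; coordinates are 1-based and closed throughout the
# package, converted only at the BED boundary.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Vectorised over its argument; N is preserved.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  nonempty <- !is.na(x) & nzchar(x)
  out[!nonempty] <- x[!nonempty]
  if (any(nonempty)) {
    out[nonempty] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[nonempty])
    ))
  }
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round a percentage for reporting
#'
#' Half-up rounding to a fixed number of decimals, applied only at the
#' reporting layer; internal values keep full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
report_percent <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_dna <- function(x, allow_n = FALSE) {
  alpha <- if (allow_n) "ACGTN" else "ACGT"
  grepl(sprintf("^[%s]*$", alpha), x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}
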