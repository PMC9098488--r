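# Degenerate-PAM site enumeration. A site is a spacer_length protospacer
# immediately 5' of a PAM match, reported on both strands. Reverse-strand
# sites carry plus-strand coordinates of the same physical bases; protospacer,
# PAM and scoring context are reported in the protospacer's own 5'->3'
# orientation.

#' PAM specification
#'
#' @param name variant name (e.g. "SpCas9", "SpG", "SpRY").
#' @param pattern IUPAC PAM pattern 3' of the protospacer (e.g. "NGG", "NGN",
#'   "NRN").
#' @param spacer_length protospacer length in bases (default 20).
#' @return an object of class `pam_spec`.
#' @export
pam_spec <- function(name, pattern, spacer_length = 20L) {
  pattern <- toupper(pattern)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", pattern)) {
    stop("invalid IUPAC character in PAM pattern: ", pattern)
  }
  stopifnot(spacer_length >= 1)
  structure(list(name = name, pattern = pattern,
                 spacer_length = as.integer(spacer_length), pam_side = "3prime"),
            class = "pam_spec")
}

#' @export
print.pam_spec <- function(x, ...) {
  cat(sprintf("pam_spec %s: %d-nt spacer + %s (3' PAM)\n",
              x$name, x$spacer_length, x$pattern))
  invisible(x)
}

#' Registry of built-in PAM specifications
#'
#' Covers wild-type SpCas9 (NGG), SpG (NGN), SpRY (NRN, i.e. N[AG]N; plus the
#' less active NYN class), the fully PAMless reference NNN, and the NGH / NAN
#' subsets used to probe non-NGG targets.
#'
#' @return named list of `pam_spec` objects.
#' @export
pam_registry <- function() {
  specs <- list(
    pam_spec("SpCas9", "NGG"),
    pam_spec("SpG", "NGN"),
    pam_spec("SpRY", "NRN"),
    pam_spec("SpRY-NYN", "NYN"),
    pam_spec("Cas-NNN", "NNN"),
    pam_spec("NGH", "NGH"),
    pam_spec("NAN", "NAN")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# Resolve a user-supplied PAM argument: a pam_spec, a registry name, or a raw
# IUPAC pattern.
as_pam_spec <- function(pam) {
  if (inherits(pam, "pam_spec")) return(pam)
  stopifnot(is.character(pam), length(pam) == 1)
  reg <- pam_registry()
  if (pam %in% names(reg)) return(reg[[pam]])
  by_pattern <- vapply(reg, `[[`, character(1), "pattern")
  if (toupper(pam) %in% by_pattern) {
    return(reg[[match(toupper(pam), by_pattern)]])
  }
  pam_spec(toupper(pam), pam)
}

iupac_regex <- function(pattern) {
  # N in the *genome* never satisfies any pattern position, so character
  # classes are built over ACGT only.
  chars <- strsplit(pattern, "")[[1]]
  classes <- vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("invalid IUPAC character: ", ch)
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  paste0("^", paste(classes, collapse = ""), "$")
}

#' Compile an IUPAC PAM pattern into a matcher
#'
#' The matcher is a predicate over equal-length nucleotide strings. An N in
#' the genome never satisfies a pattern position (not even pattern N), so
#' ambiguous genomic regions produce no sites.
#'
#' @param pattern IUPAC string (e.g. "NGN").
#' @return a function taking a character vector of sequences of the pattern's
#'   length and returning a logical vector.
#' @export
compile_pam <- function(pattern) {
  pattern <- toupper(pattern)
  rx <- iupac_regex(pattern)
  plen <- nchar(pattern)
  function(x) {
    if (any(nchar(x) != plen)) stop("sequence length must equal pattern length")
    grepl(rx, x)
  }
}

empty_sites <- function(pam) {
  structure(
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), protospacer = character(),
               pam = character(), context35 = character(),
               gg_start = logical(), contains_N = logical(),
               edge_truncated = logical(), stringsAsFactors = FALSE),
    pam_name = pam$name, pam_pattern = pam$pattern,
    spacer_length = pam$spacer_length,
    class = c("target_sites", "data.frame")
  )
}

scan_one_strand <- function(seq, ct, pam, rx) {
  sp <- pam$spacer_length
  pl <- nchar(pam$pattern)
  L <- nchar(seq)
  n <- L - sp - pl + 1L
  if (n < 1L) {
    return(data.frame(pos = integer(), protospacer = character(),
                      pam = character(), stringsAsFactors = FALSE))
  }
  starts <- seq_len(n)
  pams <- substring(seq, starts + sp, starts + sp + pl - 1L)
  keep <- grepl(rx, pams)
  starts <- starts[keep]
  if (!length(starts)) {
    return(data.frame(pos = integer(), protospacer = character(),
                      pam = character(), stringsAsFactors = FALSE))
  }
  data.frame(pos = starts,
             protospacer = substring(seq, starts, starts + sp - 1L),
             pam = pams[keep], stringsAsFactors = FALSE)
}

#' Enumerate all protospacer+PAM sites in a genome
#'
#' Scans both strands of every contig for occurrences of a spacer-length
#' protospacer immediately 5' of a PAM match. Overlapping sites and sites on
#' opposite strands over the same bases are all reported. Sites whose
#' protospacer contains N are reported with `contains_N = TRUE`. The 35-mer
#' scoring context (6 nt upstream + protospacer + PAM + 6 nt downstream, in
#' protospacer orientation) is attached where the flanks exist;
#' edge-truncated sites carry `context35 = NA`.
#'
#' @param genome a `pam_genome`.
#' @param pam a `pam_spec`, a registry name, or an IUPAC pattern.
#' @return a `target_sites` data.frame sorted by (contig, start, strand), with
#'   1-based closed protospacer coordinates on the plus strand.
#' @export
enumerate_sites <- function(genome, pam) {
  stopifnot(inherits(genome, "pam_genome"))
  pam <- as_pam_spec(pam)
  rx <- iupac_regex(pam$pattern)
  sp <- pam$spacer_length
  pl <- nchar(pam$pattern)
  per_contig <- lapply(names(genome$seq), function(ct) {
    seq <- genome$seq[[ct]]
    L <- nchar(seq)
    plus <- scan_one_strand(seq, ct, pam, rx)
    minus <- scan_one_strand(revcomp(seq), ct, pam, rx)
    res <- list()
    if (nrow(plus)) {
      res$p <- data.frame(contig = ct, start = plus$pos,
                          end = plus$pos + sp - 1L, strand = "+",
                          protospacer = plus$protospacer, pam = plus$pam,
                          stringsAsFactors = FALSE)
    }
    if (nrow(minus)) {
      j <- minus$pos
      res$m <- data.frame(contig = ct, start = L - j - sp + 2L,
                          end = L - j + 1L, strand = "-",
                          protospacer = minus$protospacer, pam = minus$pam,
                          stringsAsFactors = FALSE)
    }
    if (!length(res)) NULL else do.call(rbind, res)
  })
  per_contig <- per_contig[!vapply(per_contig, is.null, logical(1))]
  if (!length(per_contig)) return(empty_sites(pam))
  out <- do.call(rbind, per_contig)
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$context35 <- NA_character_
  out$gg_start <- substr(out$protospacer, 1, 2) == "GG"
  out$contains_N <- grepl("N", out$protospacer) | grepl("N", out$pam)
  out$edge_truncated <- FALSE
  out <- structure(out, pam_name = pam$name, pam_pattern = pam$pattern,
                   spacer_length = sp,
                   class = c("target_sites", "data.frame"))
  extract_context(out, genome, flank = 6L)
}

#' Attach 35-mer scoring contexts to sites
#'
#' The context is flank + protospacer + PAM + flank in the protospacer's own
#' orientation (reverse-complemented for minus-strand sites). Sites with fewer
#' than `flank` bases on either side are flagged `edge_truncated` and keep
#' `context35 = NA`.
#'
#' @param sites a `target_sites` data.frame.
#' @param genome the `pam_genome` the sites came from.
#' @param flank flank length on each side (default 6, giving 6+20+3+6 = 35).
#' @return `sites` with `context35` and `edge_truncated` filled in.
#' @export
extract_context <- function(sites, genome, flank = 6L) {
  if (!nrow(sites)) return(sites)
  pl <- nchar(sites$pam)
  win_start <- ifelse(sites$strand == "+", sites$start - flank,
                      sites$start - pl - flank)
  win_end <- ifelse(sites$strand == "+", sites$end + pl + flank,
                    sites$end + flank)
  lens <- genome$lengths[sites$contig]
  ok <- win_start >= 1L & win_end <= lens
  ctx <- rep(NA_character_, nrow(sites))
  if (any(ok)) {
    raw <- substring(genome$seq[sites$contig[ok]], win_start[ok], win_end[ok])
    minus <- sites$strand[ok] == "-"
    raw[minus] <- revcomp(raw[minus])
    ctx[ok] <- raw
  }
  sites$context35 <- ctx
  sites$edge_truncated <- !ok
  sites
}

#' Keep only sites whose protospacer starts with GG
#'
#' Spacers transcribed in vitro from a T7 promoter start with GG; designs
#' whose protospacer already starts with GG give a 100% match between target
#' and transcribed gRNA.
#'
#' @param sites a `target_sites` data.frame.
#' @return the GG-start subset, attributes preserved.
#' @export
filter_gg_start <- function(sites) {
  out <- sites[substr(sites$protospacer, 1, 2) == "GG", , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("pam_name", "pam_pattern", "spacer_length")] <-
    attributes(sites)[c("pam_name", "pam_pattern", "spacer_length")]
  out
}

#' Cut positions of target sites
#'
#' SpCas9-family nucleases cut bluntly 3 bp 5' of the PAM, between protospacer
#' positions 17 and 18 (for a 20-nt spacer). The reported anchor is the
#' plus-strand coordinate of the protospacer base immediately 3' of the cut
#' (position 18).
#'
#' @param sites a `target_sites` data.frame.
#' @return integer vector of 1-based plus-strand positions.
#' @export
cut_position <- function(sites) {
  sp <- nchar(sites$protospacer)
  offset <- sp - 3L  # 0-based offset of protospacer position sp-2
  as.integer(ifelse(sites$strand == "+", sites$start + offset,
                    sites$end - offset))
}
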