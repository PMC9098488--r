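# Genome and annotation I/O. One internal coordinate convention is used
# everywhere: 1-based, closed intervals on the plus strand (the GTF and
# Bioconductor convention). BED is 0-based half-open and is converted at the
# write/read boundary only.

#' Read a genome from FASTA
#'
#' Sequences are uppercased on load. Lowercase (soft-masked) input is recorded
#' as a per-contig flag. IUPAC ambiguity codes other than N are converted to N
#' with a warning; characters outside the IUPAC DNA alphabet are an error, as
#' are duplicate contig names.
#'
#' @param path path to a FASTA file.
#' @return an object of class `pam_genome`: a list with `seq` (named character
#'   vector of A/C/G/T/N sequences), `lengths` (named integer) and
#'   `softmasked` (named logical, TRUE when the input contig contained
#'   lowercase).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- as.character(raw)
  softmasked <- grepl("[a-z]", seqs)
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in contig(s): ", paste(nm[bad], collapse = ", "))
  }
  ambig <- grepl("[RYSWKMBDHV]", seqs)
  if (any(ambig)) {
    warning("ambiguity codes other than N converted to N in contig(s): ",
            paste(nm[ambig], collapse = ", "))
    seqs <- chartr("RYSWKMBDHV", strrep("N", 10), seqs)
  }
  names(seqs) <- nm
  names(softmasked) <- nm
  new_genome(seqs, softmasked)
}

new_genome <- function(seqs, softmasked = NULL) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (is.null(softmasked)) {
    softmasked <- stats::setNames(rep(FALSE, length(seqs)), names(seqs))
  }
  lengths <- stats::setNames(nchar(seqs), names(seqs))
  structure(list(seq = seqs, lengths = lengths, softmasked = softmasked),
            class = "pam_genome")
}

#' Construct a genome object from in-memory sequences
#'
#' @param seqs named character vector of A/C/G/T/N sequences.
#' @return a `pam_genome` object.
#' @export
genome_from_seqs <- function(seqs) {
  seqs <- toupper(seqs)
  if (any(!is_dna(seqs, allow_n = TRUE))) {
    stop("sequences must contain only A, C, G, T, N")
  }
  new_genome(seqs)
}

#' @export
print.pam_genome <- function(x, ...) {
  cat(sprintf("pam_genome: %d contig(s), %s bases total\n",
              length(x$seq), format(sum(x$lengths), big.mark = ",")))
  for (nm in utils::head(names(x$seq), 6)) {
    cat(sprintf("  %s  %d bp%s\n", nm, x$lengths[[nm]],
                if (x$softmasked[[nm]]) "  [softmasked]" else ""))
  }
  if (length(x$seq) > 6) cat(sprintf("  ... and %d more\n", length(x$seq) - 6))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome a `pam_genome` object.
#' @param path output path.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "pam_genome"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path,
                              width = width)
  invisible(path)
}

REGION_CLASSES <- c("CDS", "UTR", "intron", "other", "intergenic")

map_region_class <- function(type) {
  type_l <- tolower(type)
  out <- rep("other", length(type))
  out[type_l == "cds"] <- "CDS"
  out[type_l %in% c("utr", "five_prime_utr", "three_prime_utr",
                    "5utr", "3utr")] <- "UTR"
  out[type_l == "intron"] <- "intron"
  out
}

#' Read a gene annotation (GTF or GFF3)
#'
#' Feature types are mapped to region classes: CDS stays CDS;
#' five_prime_utr/three_prime_utr/UTR become UTR; intron features are used
#' when present, otherwise introns are derived as the gaps between exons of
#' each transcript; everything else is class "other". Coordinates stay in the
#' file's native 1-based closed convention, which is also the package's
#' internal convention.
#'
#' @param path path to a GTF or GFF3 file.
#' @param dialect "gtf", "gff3" or "auto" (sniffed from the extension, then
#'   from the `##gff-version 3` header line).
#' @param genome optional `pam_genome`; when supplied, features must lie on
#'   known contigs and within their lengths.
#' @return an object of class `pam_annotation`: a data.frame with columns
#'   contig, start, end, strand, region_class, type, gene_id, transcript_id,
#'   plus a `dialect` attribute.
#' @export
read_annotation <- function(path, dialect = c("auto", "gtf", "gff3"),
                            genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    dialect <- if (ext == "gtf") {
      "gtf"
    } else if (ext %in% c("gff", "gff3")) {
      "gff3"
    } else {
      first <- readLines(path, n = 5)
      if (any(grepl("^##gff-version\\s+3", first))) "gff3" else "gtf"
    }
  }
  gr <- rtracklayer::import(path, format = dialect)
  mc <- S4Vectors::mcols(gr)
  getcol <- function(col) {
    if (col %in% names(mc)) as.character(mc[[col]]) else rep(NA_character_, length(gr))
  }
  feats <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    gene_id = getcol("gene_id"),
    transcript_id = getcol("transcript_id"),
    stringsAsFactors = FALSE
  )
  if (any(feats$start > feats$end)) stop("annotation has start > end")
  if (any(!feats$strand %in% c("+", "-"))) {
    stop("annotation has features with unknown strand symbol")
  }
  feats$region_class <- map_region_class(feats$type)
  if (!any(tolower(feats$type) == "intron")) {
    feats <- rbind(feats, derive_introns(feats))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(feats$contig), names(genome$seq))
    if (length(unknown)) {
      stop("annotation references unknown contig(s): ",
           paste(unknown, collapse = ", "))
    }
    too_far <- feats$end > genome$lengths[feats$contig]
    if (any(too_far)) stop("annotation features extend beyond contig length")
  }
  rownames(feats) <- NULL
  structure(feats, dialect = dialect, class = c("pam_annotation", "data.frame"))
}

# Introns = gaps between exons within one transcript, inheriting the
# transcript's contig/strand/ids.
derive_introns <- function(feats) {
  ex <- feats[tolower(feats$type) == "exon" & !is.na(feats$transcript_id), ]
  out <- feats[0, ]
  if (!nrow(ex)) return(out)
  pieces <- lapply(split(ex, ex$transcript_id), function(e) {
    if (nrow(e) < 2) return(NULL)
    r <- IRanges::reduce(IRanges::IRanges(e$start, e$end))
    g <- IRanges::gaps(r, start = min(IRanges::start(r)),
                       end = max(IRanges::end(r)))
    if (!length(g)) return(NULL)
    data.frame(
      contig = e$contig[1], start = IRanges::start(g), end = IRanges::end(g),
      strand = e$strand[1], type = "intron", gene_id = e$gene_id[1],
      transcript_id = e$transcript_id[1], region_class = "intron",
      stringsAsFactors = FALSE
    )
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(out)
  do.call(rbind, pieces)
}

#' Build a region-class index over a genome
#'
#' Every base of every contig resolves to exactly one class, with overlap
#' precedence CDS > UTR > intron > other > intergenic; positions covered by no
#' feature are intergenic.
#'
#' @param annotation a `pam_annotation` (may have zero rows).
#' @param genome a `pam_genome`.
#' @return an object of class `region_index`: per contig, a named list of
#'   disjoint `IRanges` per region class, plus contig lengths.
#' @export
build_region_index <- function(annotation, genome) {
  stopifnot(inherits(genome, "pam_genome"))
  unknown <- setdiff(unique(annotation$contig), names(genome$seq))
  if (length(unknown)) {
    stop("annotation references unknown contig(s): ",
         paste(unknown, collapse = ", "))
  }
  contigs <- names(genome$seq)
  idx <- lapply(contigs, function(ct) {
    len <- genome$lengths[[ct]]
    f <- annotation[annotation$contig == ct, , drop = FALSE]
    taken <- IRanges::IRanges()
    classes <- list()
    for (cls in c("CDS", "UTR", "intron", "other")) {
      r <- IRanges::reduce(IRanges::IRanges(
        f$start[f$region_class == cls], f$end[f$region_class == cls]))
      r <- IRanges::setdiff(r, taken)
      classes[[cls]] <- r
      taken <- IRanges::reduce(IRanges::union(taken, r))
    }
    classes[["intergenic"]] <- IRanges::setdiff(IRanges::IRanges(1, len), taken)
    classes
  })
  names(idx) <- contigs
  structure(list(classes = idx, lengths = genome$lengths),
            class = "region_index")
}

#' Classify genomic positions by region class
#'
#' @param index a `region_index`.
#' @param contig contig name (scalar or vector recycled against `pos`).
#' @param pos 1-based positions.
#' @return character vector of region classes.
#' @export
region_at <- function(index, contig, pos) {
  stopifnot(inherits(index, "region_index"))
  n <- max(length(contig), length(pos))
  contig <- rep_len(contig, n)
  pos <- rep_len(pos, n)
  out <- character(n)
  for (ct in unique(contig)) {
    if (!ct %in% names(index$classes)) stop("unknown contig: ", ct)
    sel <- contig == ct
    p <- pos[sel]
    if (any(p < 1 | p > index$lengths[[ct]])) {
      stop("position outside contig ", ct)
    }
    cls <- rep(NA_character_, length(p))
    q <- IRanges::IRanges(p, p)
    for (nm in REGION_CLASSES) {
      hit <- IRanges::overlapsAny(q, index$classes[[ct]][[nm]])
      cls[is.na(cls) & hit] <- nm
    }
    out[sel] <- cls
  }
  out
}

#' Base counts per region class
#'
#' @param index a `region_index`.
#' @return data.frame with columns region_class and n_bases; the counts sum to
#'   the genome length.
#' @export
region_base_counts <- function(index) {
  counts <- vapply(REGION_CLASSES, function(nm) {
    sum(vapply(index$classes,
               function(ct) sum(IRanges::width(ct[[nm]])), numeric(1)))
  }, numeric(1))
  data.frame(region_class = REGION_CLASSES, n_bases = as.numeric(counts),
             stringsAsFactors = FALSE)
}

#' Write target sites as BED6
#'
#' Intervals span protospacer plus PAM, converted to BED's 0-based half-open
#' convention. The score column is the on-target score rounded to an integer,
#' or "." for unscored sites.
#'
#' @param sites a `target_sites` data.frame (optionally with a `score`
#'   column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  if (!nrow(sites)) {
    file.create(path)
    return(invisible(path))
  }
  pl <- nchar(sites$pam)
  bed_start <- ifelse(sites$strand == "+", sites$start - 1L, sites$start - 1L - pl)
  bed_end <- ifelse(sites$strand == "+", sites$end + pl, sites$end)
  score <- if ("score" %in% names(sites)) {
    ifelse(is.na(sites$score), ".", as.character(round(sites$score)))
  } else {
    rep(".", nrow(sites))
  }
  name <- sprintf("%s:%d-%d:%s", sites$contig, bed_start, bed_end, sites$strand)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   sites$contig, bed_start, bed_end, name, score, sites$strand)
  writeLines(lines, path)
  invisible(path)
}
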