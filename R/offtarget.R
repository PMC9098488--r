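# Off-target search and adapted CFD scoring. Candidate off-targets are all
# genomic sites (both strands) whose PAM matches the variant's own pattern and
# whose protospacer is within a mismatch budget of the spacer. The CFD score
# is the product of per-position mismatch penalty factors times a PAM factor;
# for the PAM-relaxed variants a PAM matching the variant pattern carries
# factor 1.0, while for wild-type SpCas9 the PAM factor is looked up from the
# NGG-variant 2-mer table.

#' Construct CFD penalty tables
#'
#' @param mismatch data.frame with columns `position` (1..20 counted from the
#'   PAM-proximal end), `rna_base` (spacer base, U normalised to T),
#'   `dna_base` (genomic base of the off-target protospacer) and `penalty` in
#'   \[0, 1\]. All 20 x 4 x 3 mismatched combinations must be present; matched
#'   pairs may be listed but must then have penalty 1.0.
#' @param pam_factors data.frame with columns `pam2` (the 16 2-mers over
#'   A/C/G/T at PAM positions 2-3) and `factor` in \[0, 1\]; used only for
#'   SpCas9/NGG scoring.
#' @param spacer_length spacer length the table covers (default 20).
#' @return an object of class `cfd_tables` holding a lookup environment.
#' @export
cfd_tables <- function(mismatch, pam_factors, spacer_length = 20L) {
  mismatch <- as.data.frame(mismatch)
  pam_factors <- as.data.frame(pam_factors)
  stopifnot(all(c("position", "rna_base", "dna_base", "penalty") %in%
                  names(mismatch)),
            all(c("pam2", "factor") %in% names(pam_factors)))
  mismatch$position <- as.integer(mismatch$position)
  mismatch$rna_base <- chartr("U", "T", toupper(mismatch$rna_base))
  mismatch$dna_base <- toupper(mismatch$dna_base)
  if (any(mismatch$penalty < 0 | mismatch$penalty > 1)) {
    stop("mismatch penalties must lie in [0, 1]")
  }
  matched <- mismatch$rna_base == mismatch$dna_base
  if (any(matched & mismatch$penalty != 1)) {
    stop("matched base pairs must have penalty 1.0")
  }
  mm <- mismatch[!matched, , drop = FALSE]
  key <- paste(mm$position, mm$rna_base, mm$dna_base)
  if (anyDuplicated(key)) stop("duplicate mismatch-penalty entries")
  bases <- c("A", "C", "G", "T")
  need <- expand.grid(position = seq_len(spacer_length), rna_base = bases,
                      dna_base = bases, stringsAsFactors = FALSE)
  need <- need[need$rna_base != need$dna_base, ]
  need_key <- paste(need$position, need$rna_base, need$dna_base)
  missing <- setdiff(need_key, key)
  if (length(missing)) {
    stop("mismatch-penalty table incomplete; first missing entry: ",
         missing[1])
  }
  pam_factors$pam2 <- toupper(pam_factors$pam2)
  if (any(pam_factors$factor < 0 | pam_factors$factor > 1)) {
    stop("PAM factors must lie in [0, 1]")
  }
  all2 <- as.vector(outer(bases, bases, paste0))
  if (length(setdiff(all2, pam_factors$pam2))) {
    stop("PAM-factor table must cover all 16 2-mers")
  }
  lookup <- stats::setNames(mm$penalty, key)
  pam_lookup <- stats::setNames(pam_factors$factor, pam_factors$pam2)
  structure(list(mismatch = mm, pam_factors = pam_factors, lookup = lookup,
                 pam_lookup = pam_lookup,
                 spacer_length = as.integer(spacer_length)),
            class = "cfd_tables")
}

#' Read CFD tables from TSV
#'
#' @param mismatch_path TSV with columns position, rna_base, dna_base,
#'   penalty.
#' @param pam_path TSV with columns pam2, factor.
#' @return a `cfd_tables` object.
#' @export
read_cfd_tables <- function(mismatch_path, pam_path) {
  cfd_tables(read_tsv(mismatch_path), read_tsv(pam_path))
}

#' Write CFD tables to TSV
#'
#' @param tables a `cfd_tables` object.
#' @param mismatch_path,pam_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cfd_tables <- function(tables, mismatch_path, pam_path) {
  write_tsv(tables$mismatch, mismatch_path)
  write_tsv(tables$pam_factors, pam_path)
  invisible(c(mismatch_path, pam_path))
}

#' Generate a synthetic CFD table set
#'
#' A complete, reproducible stand-in penalty matrix for testing and
#' demonstration; the values are synthetic (seed-determined draws with
#' PAM-proximal mismatches penalised more heavily, echoing the seed effect),
#' not an empirical cutting-frequency matrix. The NGG PAM 2-mer "GG" carries
#' factor 1.0.
#'
#' @param seed integer seed.
#' @param spacer_length spacer length (default 20).
#' @return a `cfd_tables` object.
#' @export
synthetic_cfd_tables <- function(seed = 1L, spacer_length = 20L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(position = seq_len(spacer_length), rna_base = bases,
                      dna_base = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$rna_base != grid$dna_base, ]
  # PAM-proximal positions (low index) get lower tolerated penalties.
  base_level <- 0.15 + 0.75 * (grid$position - 1) / (spacer_length - 1)
  grid$penalty <- clamp(base_level * stats::runif(nrow(grid), 0.5, 1.2), 0, 1)
  pam2 <- as.vector(outer(bases, bases, paste0))
  factor <- round(stats::runif(length(pam2), 0.01, 0.6), 3)
  factor[pam2 == "GG"] <- 1.0
  factor[pam2 %in% c("AG", "GA")] <- round(stats::runif(2, 0.2, 0.3), 3)
  cfd_tables(grid[order(grid$position, grid$rna_base, grid$dna_base), ],
             data.frame(pam2 = pam2, factor = factor,
                        stringsAsFactors = FALSE),
             spacer_length = spacer_length)
}

# PAM-proximal mismatch positions of a hit protospacer vs the spacer, both in
# 5'->3' protospacer orientation: protospacer position i is PAM-proximal
# position sp - i + 1.
mismatch_positions <- function(spacer, protospacer) {
  a <- strsplit(spacer, "")[[1]]
  b <- strsplit(protospacer, "")[[1]]
  sp <- length(a)
  which(a != b)  # 5'->3' indices
}

#' Find candidate off-target sites for a spacer
#'
#' Scans both strands for sites whose PAM matches the variant pattern and
#' whose protospacer differs from the spacer at no more than `max_mismatches`
#' positions. Genomic N counts as a mismatch. Mismatch positions are numbered
#' from the PAM-proximal end (position 1 abuts the PAM). In seed-restricted
#' mode only hits whose PAM-proximal `seed_length` bases match the spacer
#' perfectly are returned. The on-target site itself (0 mismatches) is
#' included.
#'
#' @param genome a `pam_genome`.
#' @param spacer 20-nt spacer (RNA U accepted and normalised to T).
#' @param pam a `pam_spec`, registry name or IUPAC pattern.
#' @param max_mismatches maximum mismatches tolerated (default 4).
#' @param seed_restricted require a perfect PAM-proximal seed match (default
#'   FALSE).
#' @param seed_length seed length in bases from the PAM-proximal end (default
#'   12).
#' @return an `offtarget_hits` data.frame: site columns plus
#'   `mismatch_positions` (comma-separated PAM-proximal positions),
#'   `n_mismatches` and `seed_only` (TRUE when every mismatch lies inside the
#'   seed; vacuously TRUE for the 0-mismatch hit).
#' @export
find_offtargets <- function(genome, spacer, pam, max_mismatches = 4L,
                            seed_restricted = FALSE, seed_length = 12L) {
  spacer <- chartr("U", "T", toupper(spacer))
  if (!is_dna(spacer)) stop("spacer must contain only A, C, G, T (or U)")
  pam <- as_pam_spec(pam)
  if (nchar(spacer) != pam$spacer_length) {
    stop("spacer length must equal the PAM spec's spacer_length")
  }
  sp <- pam$spacer_length
  sites <- enumerate_sites(genome, pam)
  if (!nrow(sites)) {
    out <- sites
    out$mismatch_positions <- character(0)
    out$n_mismatches <- integer(0)
    out$seed_only <- logical(0)
    return(structure(out, spacer = spacer,
                     class = c("offtarget_hits", class(out))))
  }
  spacer_chars <- strsplit(spacer, "")[[1]]
  proto_mat <- matrix(unlist(strsplit(sites$protospacer, ""), use.names = FALSE),
                      ncol = sp, byrow = TRUE)
  mm_mat <- sweep(proto_mat, 2, spacer_chars, FUN = "!=")
  n_mm <- rowSums(mm_mat)
  keep <- n_mm <= max_mismatches
  if (seed_restricted) {
    # seed occupies protospacer 5'->3' positions (sp - seed_length + 1) .. sp
    seed_cols <- seq.int(sp - seed_length + 1L, sp)
    keep <- keep & rowSums(mm_mat[, seed_cols, drop = FALSE]) == 0
  }
  out <- sites[keep, , drop = FALSE]
  mm_mat <- mm_mat[keep, , drop = FALSE]
  n_mm <- n_mm[keep]
  pp <- lapply(seq_len(nrow(out)), function(i) {
    sort(sp - which(mm_mat[i, ]) + 1L)  # PAM-proximal numbering
  })
  out$mismatch_positions <- vapply(pp, paste, character(1), collapse = ",")
  out$n_mismatches <- as.integer(n_mm)
  out$seed_only <- vapply(pp, function(p) all(p <= seed_length), logical(1))
  rownames(out) <- NULL
  structure(out, spacer = spacer, seed_length = as.integer(seed_length),
            pam_name = attr(sites, "pam_name"),
            pam_pattern = attr(sites, "pam_pattern"),
            spacer_length = sp,
            class = c("offtarget_hits", "target_sites", "data.frame"))
}

variant_pam_factor <- function(pam_seq, pam_spec, tables) {
  matcher <- compile_pam(pam_spec$pattern)
  matches <- matcher(pam_seq)
  if (identical(pam_spec$pattern, "NGG")) {
    f <- unname(tables$pam_lookup[substr(pam_seq, 2, 3)])
    f[is.na(f)] <- 0
  } else {
    f <- ifelse(matches, 1.0, 0.0)
  }
  f
}

#' Adapted CFD score of off-target hits
#'
#' cfd = product over mismatched positions of the mismatch penalty factors,
#' times a PAM factor. For wild-type SpCas9 (NGG) the PAM factor is the
#' empirical 2-mer factor of PAM positions 2-3; for PAM-relaxed variants a
#' PAM matching the variant's own pattern is scored 1.0 (a non-matching PAM,
#' reachable only through a widened search, is scored 0 for audit).
#'
#' @param spacer the 20-nt spacer.
#' @param hits an `offtarget_hits` data.frame (or any site table with
#'   `protospacer` and `pam` columns).
#' @param tables a `cfd_tables` object.
#' @param pam a `pam_spec`, registry name or IUPAC pattern of the variant.
#' @return numeric CFD scores in \[0, 1\], one per hit.
#' @export
cfd_score <- function(spacer, hits, tables, pam) {
  stopifnot(inherits(tables, "cfd_tables"))
  spacer <- chartr("U", "T", toupper(spacer))
  pam <- as_pam_spec(pam)
  sp <- nchar(spacer)
  if (!nrow(hits)) return(numeric(0))
  spacer_chars <- strsplit(spacer, "")[[1]]
  f_pam <- variant_pam_factor(hits$pam, pam, tables)
  vapply(seq_len(nrow(hits)), function(i) {
    proto <- strsplit(hits$protospacer[i], "")[[1]]
    mism <- which(proto != spacer_chars)
    fac <- 1.0
    for (j in mism) {
      key <- paste(sp - j + 1L, spacer_chars[j], proto[j])
      pen <- tables$lookup[[key]]
      if (is.null(pen) || is.na(pen)) {
        stop("missing mismatch-penalty entry: ", key)
      }
      fac <- fac * pen
    }
    fac * f_pam[i]
  }, numeric(1))
}

#' Summarise off-target hits for one spacer
#'
#' @param hits an `offtarget_hits` data.frame.
#' @param tables a `cfd_tables` object (for CFD scores).
#' @param pam the variant `pam_spec` (or name/pattern) used for the search.
#' @param seed_length seed length for the seed-perfect count (default the
#'   hits' own, else 12).
#' @return a list of class `offtarget_report` with elements `hits` (CFD
#'   scored, sorted by cfd descending then coordinates), `counts_by_mismatch`
#'   (named integer vector over 0..max), `n_seed_perfect` (hits whose seed
#'   region matches perfectly) and `max_offtarget_cfd` (maximum CFD excluding
#'   one on-target 0-mismatch hit; 0 when no off-target exists).
#' @export
offtarget_report <- function(hits, tables, pam,
                             seed_length = NULL) {
  pam <- as_pam_spec(pam)
  if (is.null(seed_length)) {
    seed_length <- attr(hits, "seed_length")
    if (is.null(seed_length)) seed_length <- 12L
  }
  spacer <- attr(hits, "spacer")
  hits$cfd <- cfd_score(spacer, hits, tables, pam)
  ord <- order(-hits$cfd, hits$contig, hits$start, hits$strand)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  max_mm <- if (nrow(hits)) max(hits$n_mismatches) else 0L
  counts <- vapply(0:max_mm, function(k) sum(hits$n_mismatches == k),
                   integer(1))
  names(counts) <- as.character(0:max_mm)
  sp <- nchar(spacer)
  seed_pos <- seq_len(seed_length)
  seed_perfect <- vapply(seq_len(nrow(hits)), function(i) {
    p <- hits$mismatch_positions[i]
    if (!nzchar(p)) return(TRUE)
    !any(as.integer(strsplit(p, ",")[[1]]) %in% seed_pos)
  }, logical(1))
  # exclude exactly one zero-mismatch hit (the on-target) from the max
  cfd_off <- hits$cfd
  on_idx <- which(hits$n_mismatches == 0L)[1]
  if (!is.na(on_idx)) cfd_off <- cfd_off[-on_idx]
  structure(list(
    spacer = spacer,
    hits = hits,
    counts_by_mismatch = counts,
    n_seed_perfect = sum(seed_perfect),
    n_offtargets = nrow(hits) - as.integer(!is.na(on_idx)),
    max_offtarget_cfd = if (length(cfd_off)) max(cfd_off) else 0
  ), class = "offtarget_report")
}

#' @export
print.offtarget_report <- function(x, ...) {
  cat(sprintf("offtarget_report for spacer %s\n", x$spacer))
  cat(sprintf("  %d hit(s), %d off-target(s); max off-target CFD %.3f\n",
              nrow(x$hits), x$n_offtargets, x$max_offtarget_cfd))
  cat("  hits by mismatch count: ",
      paste(sprintf("%s:%d", names(x$counts_by_mismatch),
                    x$counts_by_mismatch), collapse = "  "), "\n")
  invisible(x)
}
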