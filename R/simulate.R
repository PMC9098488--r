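# Reproducible synthetic fixtures: genomes with planted protospacer+PAM sites
# and a simple gene annotation, and experiment tables with known ground
# truth. One seed controls every draw, so re-running with the same seed
# reproduces byte-identical outputs.

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_pam_from_pattern <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) sample(IUPAC_SETS[[ch]], 1), character(1)),
        collapse = "")
}

spacer_occurs <- function(seq, spacer) {
  grepl(spacer, seq, fixed = TRUE) || grepl(revcomp(spacer), seq, fixed = TRUE)
}

#' Simulate a genome with planted target sites
#'
#' Background sequence is i.i.d. with the stated GC content and is
#' rejection-resampled until it contains no accidental copy (either strand) of
#' any planted spacer. Planted spacer+PAM substrings are then written in at
#' their stated positions; planted spacers are generated unique, sites do not
#' overlap, and every site keeps at least 6 nt of flank so its full scoring
#' context exists.
#'
#' @param seed integer seed controlling all draws.
#' @param n_contigs number of contigs (default 1).
#' @param contig_length length of each contig in bases (default 3000).
#' @param gc background GC content (default 0.36, the nematode/zebrafish
#'   range).
#' @param n_planted number of sites to plant per contig (default 3; 0 for a
#'   plain background).
#' @param pam a `pam_spec`, registry name or IUPAC pattern for the planted
#'   sites (default "NGG").
#' @param n_genes genes to lay out per contig for the annotation (default 2;
#'   each gene is 5'UTR, CDS exon, intron, CDS exon, 3'UTR on the plus
#'   strand).
#' @param max_retries bound on background resampling attempts (default 50).
#' @return a list of class `synthetic_genome` with elements `genome`
#'   (`pam_genome`), `annotation` (`pam_annotation`), `truth` (a
#'   `target_sites`-shaped data.frame of the planted sites) and `seed`.
#' @export
simulate_genome <- function(seed, n_contigs = 1L, contig_length = 3000L,
                            gc = 0.36, n_planted = 3L, pam = "NGG",
                            n_genes = 2L, max_retries = 50L) {
  set.seed(seed)
  pam <- as_pam_spec(pam)
  sp <- pam$spacer_length
  pl <- nchar(pam$pattern)
  span <- sp + pl
  contigs <- sprintf("ctg%02d", seq_len(n_contigs))
  seqs <- character(n_contigs)
  truth_rows <- list()
  for (ci in seq_len(n_contigs)) {
    ct <- contigs[ci]
    if (n_planted > 0) {
      # unique spacers, drawn until distinct
      repeat {
        spacers <- vapply(seq_len(n_planted),
                          function(i) random_dna(sp, 0.5), character(1))
        if (!anyDuplicated(spacers)) break
      }
      pams <- vapply(seq_len(n_planted),
                     function(i) random_pam_from_pattern(pam$pattern),
                     character(1))
      # non-overlapping positions with >= 6 nt flanks
      slot_width <- span + 12L
      avail <- contig_length - 6L - span - 6L
      if (avail < n_planted * slot_width) {
        stop("infeasible planting: contig too short for ", n_planted, " sites")
      }
      offsets <- sort(sample.int(avail - n_planted * (slot_width - 1L),
                                 n_planted))
      positions <- 7L + offsets + (seq_len(n_planted) - 1L) * (slot_width - 1L)
      strands <- sample(c("+", "-"), n_planted, replace = TRUE)
    } else {
      spacers <- character(0)
      pams <- character(0)
      positions <- integer(0)
      strands <- character(0)
    }
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      bg <- random_dna(contig_length, gc)
      if (!any(vapply(spacers, spacer_occurs, logical(1), seq = bg))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("background resampling failed after ", max_retries,
                  " attempts")
    for (i in seq_along(positions)) {
      insert <- paste0(spacers[i], pams[i])
      if (strands[i] == "-") insert <- revcomp(insert)
      substr(bg, positions[i], positions[i] + span - 1L) <- insert
    }
    # planting must not have created extra spacer copies across junctions
    for (s in spacers) {
      n_fwd <- length(gregexpr(s, bg, fixed = TRUE)[[1]]
                      [gregexpr(s, bg, fixed = TRUE)[[1]] > 0])
      n_rev <- length(gregexpr(revcomp(s), bg, fixed = TRUE)[[1]]
                      [gregexpr(revcomp(s), bg, fixed = TRUE)[[1]] > 0])
      if (n_fwd + n_rev != 1L) {
        stop("planting produced an unexpected spacer copy; choose another seed")
      }
    }
    seqs[ci] <- bg
    if (length(positions)) {
      proto_start <- ifelse(strands == "+", positions, positions + pl)
      truth_rows[[ct]] <- data.frame(
        contig = ct, start = as.integer(proto_start),
        end = as.integer(proto_start + sp - 1L), strand = strands,
        protospacer = spacers, pam = pams, stringsAsFactors = FALSE
      )
    }
  }
  names(seqs) <- contigs
  genome <- genome_from_seqs(seqs)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), protospacer = character(),
               pam = character(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  annotation <- simulate_annotation(genome, n_genes)
  structure(list(genome = genome, annotation = annotation, truth = truth,
                 pam = pam, seed = seed),
            class = "synthetic_genome")
}

# Lay out n_genes equally spaced plus-strand genes per contig, each
# 5'UTR - CDS exon - intron - CDS exon - 3'UTR.
simulate_annotation <- function(genome, n_genes) {
  rows <- list()
  for (ct in names(genome$seq)) {
    L <- genome$lengths[[ct]]
    if (n_genes < 1) next
    gene_len <- max(60L, (L %/% (2L * n_genes)))
    utr <- max(10L, gene_len %/% 10L)
    cds <- max(15L, gene_len %/% 4L)
    intr <- max(10L, gene_len %/% 10L)
    step <- L %/% n_genes
    for (gi in seq_len(n_genes)) {
      g0 <- (gi - 1L) * step + max(1L, step %/% 10L)
      gid <- sprintf("%s_g%d", ct, gi)
      tid <- paste0(gid, ".t1")
      b <- g0
      seg <- function(type, cls, len) {
        r <- data.frame(contig = ct, start = b, end = b + len - 1L,
                        strand = "+", type = type, gene_id = gid,
                        transcript_id = tid, region_class = cls,
                        stringsAsFactors = FALSE)
        b <<- b + len
        r
      }
      parts <- list(seg("five_prime_utr", "UTR", utr),
                    seg("CDS", "CDS", cds),
                    seg("intron", "intron", intr),
                    seg("CDS", "CDS", cds),
                    seg("three_prime_utr", "UTR", utr))
      gene <- do.call(rbind, parts)
      if (max(gene$end) > L) next
      rows[[gid]] <- gene
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), type = character(),
               gene_id = character(), transcript_id = character(),
               region_class = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, dialect = "gtf", class = c("pam_annotation", "data.frame"))
}

#' Write an annotation as GTF
#'
#' @param annotation a `pam_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   annotation$gene_id, annotation$transcript_id)
  lines <- sprintf("%s\tminipam\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   annotation$contig, annotation$type, annotation$start,
                   annotation$end, annotation$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate co-CRISPR and phenotype experiment tables
#'
#' Per-P0 F1 totals are Poisson-distributed around `f1_mean`; positive F1s are
#' binomial with the true per-P0 efficiency; among positives, homozygous
#' knockouts are binomial with `p_hom`. Phenotype tables draw each condition's
#' embryo classes from a multinomial over (class_III, class_II, class_I, wt).
#'
#' @param seed integer seed.
#' @param n_p0 number of injected P0s (default 200).
#' @param f1_mean mean F1s per P0 (default 100).
#' @param true_efficiency true per-F1 editing probability (default 0.3).
#' @param p_hom probability that a positive F1 is homozygous (default 0.2).
#' @param phenotype_conditions data.frame with columns condition, n_embryos,
#'   p_class_III, p_class_II, p_class_I, p_wt (probabilities summing to 1);
#'   default one 100-embryo condition at (0.3, 0.25, 0.2, 0.25).
#' @return a list of class `synthetic_experiments` with `p0` (data.frame
#'   p0_id, n_f1_total, n_positive, n_hom, n_het), `phenotypes` (data.frame
#'   condition, class_III, class_II, class_I, wt) and `truth` (the
#'   parameters).
#' @export
simulate_experiments <- function(seed, n_p0 = 200L, f1_mean = 100,
                                 true_efficiency = 0.3, p_hom = 0.2,
                                 phenotype_conditions = NULL) {
  set.seed(seed)
  stopifnot(true_efficiency >= 0, true_efficiency <= 1)
  n_f1 <- stats::rpois(n_p0, f1_mean)
  n_pos <- stats::rbinom(n_p0, n_f1, true_efficiency)
  n_hom <- stats::rbinom(n_p0, n_pos, p_hom)
  p0 <- data.frame(p0_id = sprintf("P0_%03d", seq_len(n_p0)),
                   n_f1_total = n_f1, n_positive = n_pos,
                   n_hom = n_hom, n_het = n_pos - n_hom,
                   stringsAsFactors = FALSE)
  if (is.null(phenotype_conditions)) {
    phenotype_conditions <- data.frame(
      condition = "cond1", n_embryos = 100L,
      p_class_III = 0.3, p_class_II = 0.25, p_class_I = 0.2, p_wt = 0.25,
      stringsAsFactors = FALSE)
  }
  probs <- as.matrix(phenotype_conditions[, c("p_class_III", "p_class_II",
                                              "p_class_I", "p_wt")])
  if (any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("phenotype class probabilities must sum to 1")
  }
  counts <- t(vapply(seq_len(nrow(phenotype_conditions)), function(i) {
    as.integer(stats::rmultinom(1, phenotype_conditions$n_embryos[i],
                                probs[i, ]))
  }, integer(4)))
  phenotypes <- data.frame(condition = phenotype_conditions$condition,
                           class_III = counts[, 1], class_II = counts[, 2],
                           class_I = counts[, 3], wt = counts[, 4],
                           stringsAsFactors = FALSE)
  structure(list(p0 = p0, phenotypes = phenotypes,
                 truth = list(n_p0 = n_p0, f1_mean = f1_mean,
                              true_efficiency = true_efficiency,
                              p_hom = p_hom,
                              phenotype_conditions = phenotype_conditions),
                 seed = seed),
            class = "synthetic_experiments")
}
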