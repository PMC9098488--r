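# Independent brute-force oracles used to cross-check the scanner, the
# off-target search and the exact test. These deliberately avoid the
# implementation's code paths (regex matching, vectorised mismatch matrices,
# stats::fisher.test) in favour of explicit per-position loops and direct
# combinatorics.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

oracle_pam_match <- function(pam_seq, pattern) {
  p <- strsplit(pam_seq, "")[[1]]
  q <- strsplit(pattern, "")[[1]]
  if (length(p) != length(q)) return(FALSE)
  all(vapply(seq_along(p), function(i) p[i] %in% IUPAC_ORACLE[[q[i]]],
             logical(1)))
}

# Slide a (spacer + pam) window over both strands of every contig.
oracle_enumerate <- function(genome, pattern, spacer_length = 20L) {
  pl <- nchar(pattern)
  sp <- spacer_length
  rows <- list()
  k <- 0L
  for (ct in names(genome$seq)) {
    seq <- genome$seq[[ct]]
    L <- nchar(seq)
    for (i in seq_len(max(0L, L - sp - pl + 1L))) {
      pam <- substr(seq, i + sp, i + sp + pl - 1L)
      if (oracle_pam_match(pam, pattern)) {
        k <- k + 1L
        rows[[k]] <- data.frame(contig = ct, start = i, end = i + sp - 1L,
                                strand = "+",
                                protospacer = substr(seq, i, i + sp - 1L),
                                pam = pam, stringsAsFactors = FALSE)
      }
    }
    rc <- oracle_revcomp(seq)
    for (j in seq_len(max(0L, L - sp - pl + 1L))) {
      pam <- substr(rc, j + sp, j + sp + pl - 1L)
      if (oracle_pam_match(pam, pattern)) {
        k <- k + 1L
        rows[[k]] <- data.frame(contig = ct, start = L - j - sp + 2L,
                                end = L - j + 1L, strand = "-",
                                protospacer = substr(rc, j, j + sp - 1L),
                                pam = pam, stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      protospacer = character(), pam = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

site_key <- function(df) {
  if (!nrow(df)) return(character(0))
  paste(df$contig, df$start, df$end, df$strand, df$protospacer, df$pam)
}

# Exhaustive off-target scan: every window of every strand, per-position
# character comparison against the spacer, PAM checked with the per-position
# oracle matcher.
oracle_offtargets <- function(genome, spacer, pattern, max_mm,
                              seed_restricted = FALSE, seed_length = 12L) {
  sp <- nchar(spacer)
  sc <- strsplit(spacer, "")[[1]]
  cand <- oracle_enumerate(genome, pattern, sp)
  keep <- logical(nrow(cand))
  n_mm <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pc <- strsplit(cand$protospacer[i], "")[[1]]
    mism_53 <- which(pc != sc)
    pp <- sp - mism_53 + 1L  # PAM-proximal numbering
    n_mm[i] <- length(pp)
    ok <- length(pp) <= max_mm
    if (seed_restricted && any(pp <= seed_length)) ok <- FALSE
    keep[i] <- ok
  }
  out <- cand[keep, , drop = FALSE]
  out$n_mismatches <- n_mm[keep]
  rownames(out) <- NULL
  out
}

# Probability-mass two-sided Fisher p by direct enumeration over all 2x2
# tables with the observed margins, using choose() directly.
oracle_fisher2x2 <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  p_of <- function(a) choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  a_min <- max(0, c1 - r2); a_max <- min(r1, c1)
  probs <- vapply(a_min:a_max, p_of, numeric(1))
  obs <- p_of(tab[1, 1])
  sum(probs[probs <= obs * (1 + 1e-7)])
}

random_genome <- function(seed, length = 1000L, n_contigs = 1L, gc = 0.4) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_contigs), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1))
  names(seqs) <- sprintf("chr%d", seq_len(n_contigs))
  genome_from_seqs(seqs)
}

random_context <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 35, replace = TRUE), collapse = "")
  }, character(1))
}

random_score_model <- function(n_entries = 30) {
  pos <- sample(1:34, n_entries, replace = TRUE)
  len <- sample(1:2, n_entries, replace = TRUE)
  feat <- vapply(len, function(k) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, character(1))
  df <- data.frame(position = pos, feature = feat,
                   weight = stats::rnorm(n_entries), stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$position, df$feature)), ]
  score_model(df, intercept = stats::rnorm(1), raw_min = -10, raw_max = 10,
              model_id = "random")
}
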