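# Editing-efficiency statistics for injection experiments.
#
# Zebrafish phenotype assays score each embryo into one of four classes, from
# most to least severe: class III (albino-like/golden-like, or absent
# notochord with extremely short tail), class II (severe mosaic), class I
# (mild mosaic) and phenotypically wild type. C. elegans co-CRISPR screens
# record, per injected P0, the F1s screened and the F1s positive for the edit,
# and per-F1 genotypes (homozygous/heterozygous knockouts) for the
# edited-allele percentage.

PHENOTYPE_CLASSES <- c("class_III", "class_II", "class_I", "wt")

as_phenotype_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- unlist(counts[1, PHENOTYPE_CLASSES])
  if (!is.null(names(counts))) {
    missing <- setdiff(PHENOTYPE_CLASSES, names(counts))
    if (length(missing)) stop("missing phenotype class(es): ",
                              paste(missing, collapse = ", "))
    counts <- counts[PHENOTYPE_CLASSES]
  } else if (length(counts) == 4) {
    names(counts) <- PHENOTYPE_CLASSES
  } else {
    stop("phenotype counts must be 4 values: class_III, class_II, class_I, wt")
  }
  if (any(counts < 0)) stop("phenotype counts must be non-negative")
  counts
}

#' Per-class phenotype proportions
#'
#' @param counts numeric vector of 4 embryo counts in severity order
#'   (class_III, class_II, class_I, wt), optionally named.
#' @return named proportions summing to 1.
#' @export
phenotype_fractions <- function(counts) {
  counts <- as_phenotype_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("total embryo count is zero")
  counts / n
}

#' Classify an injection as highly efficient
#'
#' Highly efficient gRNAs generate at least `severe_min` (default 50%) of
#' embryos with class III or class II phenotypes and less than `wt_max`
#' (default 10%) phenotypically wild-type embryos.
#'
#' @param counts phenotype counts (see [phenotype_fractions()]).
#' @param severe_min minimum combined class III + class II fraction
#'   (inclusive, default 0.5).
#' @param wt_max maximum wild-type fraction (exclusive, default 0.1).
#' @return logical.
#' @export
classify_highly_efficient <- function(counts, severe_min = 0.5, wt_max = 0.1) {
  f <- phenotype_fractions(counts)
  unname(f[["class_III"]] + f[["class_II"]] >= severe_min &&
           f[["wt"]] < wt_max)
}

#' Fraction of mosaic mutant embryos
#'
#' Mosaic mutants are embryos in any non-wild-type class (I, II or III).
#'
#' @param counts phenotype counts.
#' @return proportion in \[0, 1\].
#' @export
mosaic_mutant_fraction <- function(counts) {
  counts <- as_phenotype_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("total embryo count is zero")
  unname((n - counts[["wt"]]) / n)
}

#' Per-P0 editing efficiency
#'
#' Efficiency is the number of positive F1s divided by the total F1s counted
#' for that P0 (e.g. F1s whose F2 lost fluorescence over separated co-edited
#' F1s). P0s producing fewer than `min_f1` F1s are excluded (NA), never
#' imputed as zero; figure-style inclusion thresholds are 100 F1s for direct
#' dpy-10 screens and 5 or 10 co-edited F1s for co-CRISPR screens.
#'
#' @param n_positive,n_f1_total integer vectors (recycled to equal length).
#' @param min_f1 minimum F1 count for inclusion (default 10).
#' @return numeric efficiencies in \[0, 1\], NA for excluded P0s.
#' @export
p0_efficiency <- function(n_positive, n_f1_total, min_f1 = 10) {
  n <- max(length(n_positive), length(n_f1_total))
  n_positive <- rep_len(n_positive, n)
  n_f1_total <- rep_len(n_f1_total, n)
  if (any(n_positive < 0 | n_f1_total < 0)) stop("counts must be non-negative")
  if (any(n_positive > n_f1_total)) {
    stop("n_positive cannot exceed n_f1_total")
  }
  ifelse(n_f1_total >= min_f1 & n_f1_total > 0, n_positive / n_f1_total,
         NA_real_)
}

#' Percentage of edited alleles among screened F1s
#'
#' (2 x homozygous + heterozygous) / (2 x screened) x 100.
#'
#' @param n_hom,n_het,n_screened integer vectors (recycled).
#' @return percentages in \[0, 100\].
#' @export
edited_allele_percent <- function(n_hom, n_het, n_screened) {
  n <- max(length(n_hom), length(n_het), length(n_screened))
  n_hom <- rep_len(n_hom, n)
  n_het <- rep_len(n_het, n)
  n_screened <- rep_len(n_screened, n)
  if (any(n_screened <= 0)) stop("n_screened must be positive")
  if (any(n_hom + n_het > n_screened)) {
    stop("n_hom + n_het cannot exceed n_screened")
  }
  100 * (2 * n_hom + n_het) / (2 * n_screened)
}

#' HDR insertion efficiency
#'
#' Proportion of genotyped F1 animals harbouring an insertion of the correct
#' size, as a percentage.
#'
#' @param n_correct,n_genotyped integer vectors (recycled).
#' @return percentages in \[0, 100\].
#' @export
hdr_efficiency <- function(n_correct, n_genotyped) {
  n <- max(length(n_correct), length(n_genotyped))
  n_correct <- rep_len(n_correct, n)
  n_genotyped <- rep_len(n_genotyped, n)
  if (any(n_genotyped <= 0)) stop("n_genotyped must be positive")
  if (any(n_correct > n_genotyped)) {
    stop("n_correct cannot exceed n_genotyped")
  }
  100 * n_correct / n_genotyped
}

#' Build the score-by-efficiency enrichment table
#'
#' Cross-tabulates predicted high-score targets (score > threshold) against
#' observed highly efficient targets into the 2x2 table tested with Fisher's
#' exact test.
#'
#' @param high_score logical vector (predicted).
#' @param highly_efficient logical vector (observed), same length.
#' @return a 2x2 integer matrix with rows score > threshold / score <=
#'   threshold and columns highly efficient / not.
#' @export
enrichment_table <- function(high_score, highly_efficient) {
  stopifnot(length(high_score) == length(highly_efficient))
  keep <- !is.na(high_score) & !is.na(highly_efficient)
  hs <- factor(high_score[keep], levels = c(TRUE, FALSE),
               labels = c("score_gt_threshold", "score_le_threshold"))
  he <- factor(highly_efficient[keep], levels = c(TRUE, FALSE),
               labels = c("highly_efficient", "not_highly_efficient"))
  table(hs, he)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value uses the probability-mass convention: the sum of the
#' probabilities of all tables with the observed margins whose hypergeometric
#' point probability does not exceed the observed table's.
#'
#' @param tab 2x2 matrix/table of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_enrichment <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (sum(tab) == 0) stop("all-zero table")
  stats::fisher.test(tab)$p.value
}

#' Chi-squared test of contingency with Yates' correction
#'
#' For 2x2 tables the statistic applies Yates' continuity correction (|O - E|
#' reduced by 0.5, floored at 0, per cell); larger tables use the uncorrected
#' statistic with df = (r-1)(c-1).
#'
#' @param tab r x c matrix/table of non-negative counts with positive margins.
#' @param correct apply Yates' correction for 2x2 tables (default TRUE).
#' @return an object of class `htest` (statistic, parameter, p.value).
#' @export
chisq_yates <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has a zero margin")
  }
  suppressWarnings(stats::chisq.test(tab, correct = correct))
}

#' Read a phenotype-count experiment table
#'
#' TSV with one row per injection condition: a `condition` column plus the
#' four class-count columns class_III, class_II, class_I, wt.
#'
#' @param path TSV path.
#' @return data.frame with an added `n_total` column.
#' @export
read_phenotype_table <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(c("condition", PHENOTYPE_CLASSES), names(df))
  if (length(missing)) stop("phenotype table missing column(s): ",
                            paste(missing, collapse = ", "))
  df$n_total <- rowSums(df[PHENOTYPE_CLASSES])
  df
}

#' Read a per-P0 experiment table
#'
#' TSV with one row per injected P0: p0_id, n_f1_total, n_positive and
#' optionally n_hom, n_het.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_p0_table <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(c("p0_id", "n_f1_total", "n_positive"), names(df))
  if (length(missing)) stop("P0 table missing column(s): ",
                            paste(missing, collapse = ", "))
  if (any(df$n_positive > df$n_f1_total)) {
    stop("n_positive cannot exceed n_f1_total")
  }
  df
}
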