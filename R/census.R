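# Genome-wide PAM-accessibility summaries: sites per region class and targets
# (all, and above the score threshold) per CDS. A site is assigned to a region
# by its cut position (the blunt cut 3 bp 5' of the PAM), not by the PAM's
# first base.

#' Census of target sites by region class
#'
#' Each site is assigned exactly one region class, the class of the base at
#' its cut position, and counts are aggregated.
#'
#' @param sites a `target_sites` data.frame.
#' @param region_index a `region_index` built from the same genome.
#' @return a data.frame of class `census_table` with columns pam_name,
#'   region_class, site_count (one row per class, zero classes included); the
#'   counts sum to `nrow(sites)`.
#' @export
census_by_region <- function(sites, region_index) {
  pam_name <- attr(sites, "pam_name")
  if (is.null(pam_name)) pam_name <- NA_character_
  if (nrow(sites)) {
    cls <- region_at(region_index, sites$contig, cut_position(sites))
    counts <- vapply(REGION_CLASSES, function(nm) sum(cls == nm), numeric(1))
  } else {
    counts <- stats::setNames(rep(0, length(REGION_CLASSES)), REGION_CLASSES)
  }
  structure(
    data.frame(pam_name = pam_name, region_class = REGION_CLASSES,
               site_count = as.numeric(counts), stringsAsFactors = FALSE,
               row.names = NULL),
    total_sites = nrow(sites),
    class = c("census_table", "data.frame")
  )
}

#' Targets per CDS
#'
#' A target is counted for a gene when its cut position lies within one of the
#' gene's CDS intervals; a target overlapping the CDS of two genes counts for
#' both. Genes with zero targets are included. When the sites carry scores,
#' the count of targets scoring strictly above `threshold` is also reported.
#'
#' @param sites a `target_sites` data.frame (optionally scored via
#'   [score_targets()]).
#' @param annotation a `pam_annotation` with CDS features carrying gene_id.
#' @param threshold score threshold for the filtered column (default 66,
#'   strict).
#' @return a data.frame of class `per_cds_summary` with columns gene_id,
#'   cds_length, n_targets, n_targets_score_gt_threshold, plus a `summary`
#'   attribute holding mean/median/quartiles of both count columns.
#' @export
targets_per_cds <- function(sites, annotation, threshold = 66) {
  cds <- annotation[annotation$region_class == "CDS" & !is.na(annotation$gene_id), ,
                    drop = FALSE]
  genes <- unique(cds$gene_id)
  if (!length(genes)) {
    out <- data.frame(gene_id = character(), cds_length = integer(),
                      n_targets = integer(),
                      n_targets_score_gt_threshold = integer(),
                      stringsAsFactors = FALSE)
    return(structure(out, summary = NULL, threshold = threshold,
                     class = c("per_cds_summary", "data.frame")))
  }
  has_score <- "score" %in% names(sites) && nrow(sites) > 0
  cut_pos <- if (nrow(sites)) cut_position(sites) else integer(0)
  high <- if (has_score) classify_high_score(sites$score, threshold) else
    rep(FALSE, nrow(sites))
  high[is.na(high)] <- FALSE
  rows <- lapply(genes, function(g) {
    gc <- cds[cds$gene_id == g, , drop = FALSE]
    n_t <- 0L
    n_hi <- 0L
    cds_len <- 0L
    for (ct in unique(gc$contig)) {
      r <- IRanges::reduce(IRanges::IRanges(gc$start[gc$contig == ct],
                                            gc$end[gc$contig == ct]))
      cds_len <- cds_len + sum(IRanges::width(r))
      if (nrow(sites)) {
        sel <- sites$contig == ct
        if (any(sel)) {
          inside <- IRanges::overlapsAny(
            IRanges::IRanges(cut_pos[sel], cut_pos[sel]), r)
          n_t <- n_t + sum(inside)
          n_hi <- n_hi + sum(inside & high[sel])
        }
      }
    }
    data.frame(gene_id = g, cds_length = cds_len, n_targets = n_t,
               n_targets_score_gt_threshold = n_hi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  summ <- lapply(c(n_targets = "n_targets",
                   n_targets_score_gt_threshold = "n_targets_score_gt_threshold"),
                 function(col) {
                   q <- stats::quantile(out[[col]], c(0.25, 0.5, 0.75))
                   c(mean = mean(out[[col]]), median = stats::median(out[[col]]),
                     q25 = unname(q[1]), q75 = unname(q[3]))
                 })
  structure(out, summary = summ, threshold = threshold,
            class = c("per_cds_summary", "data.frame"))
}

#' @export
summary.per_cds_summary <- function(object, ...) {
  s <- attr(object, "summary")
  cat(sprintf("targets per CDS over %d gene(s):\n", nrow(object)))
  if (!is.null(s)) {
    cat(sprintf("  all targets:      mean %.2f, median %.1f\n",
                s$n_targets["mean"], s$n_targets["median"]))
    cat(sprintf("  score > %g:       mean %.2f, median %.1f\n",
                attr(object, "threshold"),
                s$n_targets_score_gt_threshold["mean"],
                s$n_targets_score_gt_threshold["median"]))
  }
  invisible(s)
}
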