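# On-target activity scoring. The model is a positional-feature linear score
# over a 35-mer context (6 nt + 20-nt protospacer + 3-nt PAM + 6 nt), scaled
# affinely to 0-100. Targets of PAM-relaxed variants are scored with the same
# model as wild-type SpCas9 by forcing PAM positions 2-3 of the context to GG
# before scoring (the NGG-substitution rule), so the score never depends on
# the variant PAM actually present.

CONTEXT_LEN <- 35L
PAM_POS_2 <- 28L  # 1-based positions of the 2nd and 3rd PAM base in the 35-mer
PAM_POS_3 <- 29L

#' Construct an on-target score model
#'
#' @param entries data.frame with columns `position` (1..35), `feature`
#'   (a 1-mer or 2-mer over A/C/G/T; a 2-mer at position p covers p and p+1)
#'   and `weight` (real).
#' @param intercept model intercept on the raw scale.
#' @param raw_min,raw_max raw-score range mapped affinely onto 0-100; scores
#'   outside are clamped.
#' @param model_id free-text identifier.
#' @return an object of class `score_model`.
#' @export
score_model <- function(entries, intercept, raw_min, raw_max,
                        model_id = "unnamed") {
  entries <- as.data.frame(entries)
  stopifnot(all(c("position", "feature", "weight") %in% names(entries)))
  entries$position <- as.integer(entries$position)
  entries$feature <- toupper(as.character(entries$feature))
  entries$weight <- as.numeric(entries$weight)
  if (nrow(entries)) {
    if (any(!grepl("^[ACGT]{1,2}$", entries$feature))) {
      stop("features must be 1-mers or 2-mers over A/C/G/T")
    }
    span <- entries$position + nchar(entries$feature) - 1L
    if (any(entries$position < 1L | span > CONTEXT_LEN)) {
      stop("feature positions must lie within 1..", CONTEXT_LEN)
    }
    key <- paste(entries$position, entries$feature)
    if (anyDuplicated(key)) {
      stop("duplicate (position, feature) rows: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
  }
  stopifnot(is.numeric(intercept), length(intercept) == 1)
  if (!(raw_min < raw_max)) stop("raw_min must be < raw_max")
  structure(list(entries = entries, intercept = as.numeric(intercept),
                 raw_min = as.numeric(raw_min), raw_max = as.numeric(raw_max),
                 model_id = model_id),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf(
    "score_model '%s': %d positional features, intercept %.4g, raw range [%.4g, %.4g]\n",
    x$model_id, nrow(x$entries), x$intercept, x$raw_min, x$raw_max))
  invisible(x)
}

#' Read an on-target score model from TSV
#'
#' Format: a header line `position<TAB>feature<TAB>weight`, one row per
#' positional feature, then footer rows whose first field is `intercept`,
#' `raw_min` or `raw_max` (second field ".", third the value). Lines starting
#' with `#` are comments; a `# model_id: <id>` comment is honoured.
#'
#' @param path path to the model file.
#' @return a `score_model`.
#' @export
read_score_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  id_line <- grep("^#\\s*model_id:", lines, value = TRUE)
  model_id <- if (length(id_line)) {
    trimws(sub("^#\\s*model_id:", "", id_line[1]))
  } else {
    "unnamed"
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) stop("malformed model line(s): ", lines[bad][1])
  m <- do.call(rbind, parts)
  if (!identical(tolower(m[1, ]), c("position", "feature", "weight"))) {
    stop("model file must start with header: position<TAB>feature<TAB>weight")
  }
  m <- m[-1, , drop = FALSE]
  footer_keys <- c("intercept", "raw_min", "raw_max")
  is_footer <- m[, 1] %in% footer_keys
  footer <- stats::setNames(as.numeric(m[is_footer, 3]), m[is_footer, 1])
  missing <- setdiff(footer_keys, names(footer))
  if (length(missing)) {
    stop("model file is missing footer key(s): ", paste(missing, collapse = ", "))
  }
  rows <- m[!is_footer, , drop = FALSE]
  entries <- data.frame(position = as.integer(rows[, 1]), feature = rows[, 2],
                        weight = as.numeric(rows[, 3]),
                        stringsAsFactors = FALSE)
  score_model(entries, footer[["intercept"]], footer[["raw_min"]],
              footer[["raw_max"]], model_id = model_id)
}

#' Write an on-target score model to TSV
#'
#' @param model a `score_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  lines <- c(
    sprintf("# model_id: %s", model$model_id),
    "position\tfeature\tweight",
    sprintf("%d\t%s\t%.17g", model$entries$position, model$entries$feature,
            model$entries$weight),
    sprintf("intercept\t.\t%.17g", model$intercept),
    sprintf("raw_min\t.\t%.17g", model$raw_min),
    sprintf("raw_max\t.\t%.17g", model$raw_max)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Canonicalize the PAM of a scoring context to NGG
#'
#' Sets positions 28 and 29 of the 35-mer (the 2nd and 3rd PAM bases) to G,G;
#' the first PAM base (position 27, the N of NGG) is retained. This makes the
#' SpCas9 on-target model applicable to targets of PAM-relaxed variants.
#'
#' @param context35 character vector of length-35 contexts (NA passed
#'   through).
#' @return the canonicalized contexts.
#' @export
canonicalize_pam <- function(context35) {
  ok <- !is.na(context35)
  if (any(nchar(context35[ok]) != CONTEXT_LEN)) {
    stop("contexts must be exactly ", CONTEXT_LEN, " nt")
  }
  out <- context35
  substr(out[ok], PAM_POS_2, PAM_POS_3) <- "GG"
  out
}

#' Score 35-mer contexts with an on-target model
#'
#' Raw score = intercept + sum of the weights of matched (position, feature)
#' pairs over the PAM-canonicalized context; the raw score is mapped affinely
#' from [raw_min, raw_max] onto [0, 100] and clamped. Deterministic.
#'
#' @param model a `score_model`.
#' @param context35 character vector of contexts; NA scores NA.
#' @return numeric scores in [0, 100].
#' @export
score_context <- function(model, context35) {
  stopifnot(inherits(model, "score_model"))
  ctx <- canonicalize_pam(context35)
  raw <- rep(model$intercept, length(ctx))
  e <- model$entries
  for (i in seq_len(nrow(e))) {
    k <- nchar(e$feature[i])
    hit <- !is.na(ctx) &
      substring(ctx, e$position[i], e$position[i] + k - 1L) == e$feature[i]
    raw[hit] <- raw[hit] + e$weight[i]
  }
  raw[is.na(ctx)] <- NA_real_
  clamp(100 * (raw - model$raw_min) / (model$raw_max - model$raw_min), 0, 100)
}

#' Score target sites
#'
#' Adds `score` and `high_efficiency_predicted` columns to a site table.
#' Edge-truncated sites (no 35-mer context) are reported unscored (NA), not an
#' error.
#'
#' @param model a `score_model`.
#' @param sites a `target_sites` data.frame with a `context35` column.
#' @param threshold high-efficiency threshold on the 0-100 scale (default 66,
#'   strict: predicted high efficiency iff score > threshold).
#' @return `sites` with scoring columns added.
#' @export
score_targets <- function(model, sites, threshold = 66) {
  sites$score <- score_context(model, sites$context35)
  sites$high_efficiency_predicted <- classify_high_score(sites$score, threshold)
  attr(sites, "score_threshold") <- threshold
  sites
}

#' Classify scores as predicted high-efficiency
#'
#' Strict inequality: a score equal to the threshold is not classified high.
#'
#' @param score numeric scores in [0, 100] (NA propagates).
#' @param threshold cutoff (default 66).
#' @return logical vector.
#' @export
classify_high_score <- function(score, threshold = 66) {
  score > threshold
}
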