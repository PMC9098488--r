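# Fill-in PCR template design for T7 in vitro transcription of sgRNAs, and
# reaction-mix molarity arithmetic. The forward oligo is T7 promoter (17 nt) +
# spacer (20 nt) + a constant annealing tail (15 nt) = 52 nt; an 80-nt
# universal reverse oligo adds the invariant sgRNA 3' end, and the fill-in
# product is 52 + 80 - 15 = 117 bp.

T7_PROMOTER <- "TAATACGACTCACTATA"

# Default annealing tail: the first 15 nt of the invariant sgRNA scaffold.
DEFAULT_TAIL15 <- "GTTTTAGAGCTAGAA"

#' Design a fill-in PCR template for sgRNA in vitro transcription
#'
#' @param spacer 20-nt spacer (A/C/G/T). Spacers transcribed from T7 should
#'   start with GG; a spacer that does not triggers a warning, not an error.
#' @param tail15 15-nt constant annealing tail (default: the first 15 nt of
#'   the sgRNA scaffold).
#' @param universal_len length of the universal reverse oligo (default 80).
#' @param t7 T7 promoter sequence (default the 17-nt core).
#' @return an object of class `fillin_design` with the forward oligo (52 nt
#'   for default geometry), the product length (fwd + universal - overlap) and
#'   a `gg_start_ok` flag.
#' @export
design_fillin <- function(spacer, tail15 = DEFAULT_TAIL15, universal_len = 80L,
                          t7 = T7_PROMOTER) {
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L) stop("spacer must be exactly 20 nt")
  if (!is_dna(spacer)) stop("spacer must contain only A, C, G, T")
  tail15 <- toupper(tail15)
  if (nchar(tail15) != 15L) stop("annealing tail must be exactly 15 nt")
  if (!is_dna(tail15)) stop("tail must contain only A, C, G, T")
  gg_start_ok <- substr(spacer, 1, 2) == "GG"
  if (!gg_start_ok) {
    warning("spacer does not start with GG; T7-transcribed gRNA will not ",
            "match the target at its 5' end")
  }
  forward <- paste0(t7, spacer, tail15)
  structure(list(
    spacer = spacer,
    forward_oligo = forward,
    forward_length = nchar(forward),
    universal_oligo_length = as.integer(universal_len),
    overlap = nchar(tail15),
    product_length = nchar(forward) + as.integer(universal_len) - nchar(tail15),
    gg_start_ok = gg_start_ok
  ), class = "fillin_design")
}

#' @export
print.fillin_design <- function(x, ...) {
  cat(sprintf("fillin_design: %d-nt forward oligo, %d-nt universal oligo, %d-bp product\n",
              x$forward_length, x$universal_oligo_length, x$product_length))
  cat(sprintf("  forward: %s\n", x$forward_oligo))
  cat(sprintf("  spacer starts GG: %s\n", x$gg_start_ok))
  invisible(x)
}

#' Dilution arithmetic for a reaction mix
#'
#' Final concentration of each component = stock x volume / total volume;
#' diluents (water, buffer) enter as zero-concentration components. The molar
#' ratio is normalised to the smallest nonzero final concentration.
#'
#' @param components data.frame with columns `name`, `stock_nM` and
#'   `volume_uL`.
#' @param total_volume total reaction volume in uL; must equal the summed
#'   volumes.
#' @return an object of class `mix_recipe` with `final_nM` and `ratio`
#'   columns added.
#' @export
mix_concentrations <- function(components, total_volume) {
  components <- as.data.frame(components)
  stopifnot(all(c("name", "stock_nM", "volume_uL") %in% names(components)))
  if (any(components$volume_uL <= 0)) stop("volumes must be positive")
  if (abs(sum(components$volume_uL) - total_volume) > 1e-9) {
    stop("total_volume must equal the sum of component volumes")
  }
  components$final_nM <- components$stock_nM * components$volume_uL / total_volume
  nonzero <- components$final_nM > 0
  base <- if (any(nonzero)) min(components$final_nM[nonzero]) else NA_real_
  components$ratio <- ifelse(nonzero, components$final_nM / base, NA_real_)
  structure(list(components = components,
                 total_volume = total_volume), class = "mix_recipe")
}

#' @export
print.mix_recipe <- function(x, ...) {
  cat(sprintf("mix_recipe: %g uL total\n", x$total_volume))
  df <- x$components
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-12s %8.4g nM stock x %5.3g uL -> %8.4g nM final%s\n",
                df$name[i], df$stock_nM[i], df$volume_uL[i], df$final_nM[i],
                if (!is.na(df$ratio[i])) sprintf("  (ratio %.3g)", df$ratio[i])
                else ""))
  }
  invisible(x)
}

#' Check a protein:gRNA assembly ratio
#'
#' RNPs are assembled with a slight molar excess of gRNA over nuclease
#' (target gRNA/protein ratio 1.3 by default).
#'
#' @param protein_conc,grna_conc positive concentrations in the same unit.
#' @param target target gRNA/protein molar ratio (default 1.3).
#' @param tol relative tolerance (default 0.05).
#' @return a list with `ok`, the observed `ratio`, and `deviation` (signed
#'   relative error versus the target).
#' @export
rnp_ratio_check <- function(protein_conc, grna_conc, target = 1.3,
                            tol = 0.05) {
  stopifnot(protein_conc > 0, grna_conc > 0)
  ratio <- grna_conc / protein_conc
  deviation <- (ratio - target) / target
  list(ok = abs(deviation) <= tol, ratio = ratio, deviation = deviation)
}
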