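# minipam

Target design and quantification for CRISPR-Cas9 nucleases with minimal PAM
requirements.

Wild-type SpCas9 needs an NGG protospacer-adjacent motif (PAM) 3′ of its
20-nt protospacer, which excludes many positions — a real constraint when the
edit must land in a short element (a miRNA, a codon to mimic a missense
mutation, a PAM close enough to an HDR edit site). The engineered variants
SpG (NGN PAM) and SpRY (NRN ≫ NYN) relax that requirement and are active in
vivo in zebrafish embryos and *C. elegans*. `minipam` implements the
computational side of designing and quantifying experiments with these
nucleases:

- **PAM engine** — enumerate every protospacer+PAM site on both strands of a
  genome for any IUPAC PAM pattern (built-ins: NGG, NGN, NRN, NYN, NNN, NGH,
  NAN), with 35-mer scoring contexts and GG-start filtering for T7
  transcription.
- **On-target scoring** — a positional-feature activity model over the
  35-mer context (6 nt + protospacer + PAM + 6 nt), scaled to 0–100. Targets
  of PAM-relaxed variants are scored *as if* their PAM were NGG (context
  positions 28–29 forced to GG), so the SpCas9-trained model applies
  unchanged; scores strictly above 66 predict highly efficient gRNAs. Model
  coefficients are data, loaded from a TSV.
- **Off-target search** — all sites within a mismatch budget of a spacer
  under the variant's own PAM pattern, with optional restriction to
  seed-perfect hits (PAM-proximal 12 nt by default), scored with an adapted
  CFD: the product of per-position mismatch penalties times a PAM factor
  that is the empirical 2-mer factor for NGG but **1.0 for any PAM matching
  the variant's pattern** (SpG/SpRY bind those PAMs natively).
- **Census** — sites per genomic region class (CDS > UTR > intron > other >
  intergenic, assigned at the cut position 3 bp 5′ of the PAM) and targets
  (all, and score > 66) per CDS.
- **Oligo design** — fill-in PCR templates for in vitro transcription: a
  52-nt forward oligo (17-nt T7 promoter + 20-nt spacer + 15-nt annealing
  tail) with an 80-nt universal oligo gives the 117-bp product
  (52 + 80 − 15); plus reaction-mix dilution arithmetic and RNP ratio
  checks.
- **Quantification** — the editing-efficiency statistics for zebrafish
  phenotype assays (class III/II/I/WT fractions, the highly-efficient rule:
  ≥ 50% class III+II and < 10% WT; mosaic fraction) and *C. elegans*
  co-CRISPR screens (per-P0 efficiency with brood-size inclusion thresholds;
  edited alleles % = (2·hom + het)/(2·screened) × 100; HDR efficiency),
  with Fisher's exact test and χ² with Yates' correction.
- **Fixtures** — seed-reproducible synthetic genomes with planted sites and
  synthetic experiment tables with known truth, so everything above is
  testable offline.

## Worked example

```r
library(minipam)

# a reproducible 3-kb synthetic genome with 3 planted SpG (NGN) targets
sim   <- simulate_genome(seed = 42, contig_length = 3000, n_planted = 3, pam = "NGN")
sites <- enumerate_sites(sim$genome, "SpG")
nrow(sites)
#> [1] 1073

# score with a synthetic positional-feature model (real coefficient sets are
# loaded from TSV with read_score_model)
set.seed(1)
entries <- expand.grid(position = 1:34, feature = c("A","C","G","T"),
                       stringsAsFactors = FALSE)
entries$weight <- rnorm(nrow(entries), 0, 0.3)
model  <- score_model(entries, intercept = 0, raw_min = -8, raw_max = 8)
scored <- score_targets(model, sites)          # score + high_efficiency_predicted
sum(scored$high_efficiency_predicted, na.rm = TRUE)
#> [1] 86

# where do the sites fall?
idx <- build_region_index(sim$annotation, sim$genome)
census_by_region(scored, idx)
#>   pam_name region_class site_count
#> 1      SpG          CDS        280
#> 2      SpG          UTR         97
#> 3      SpG       intron         62
#> 4      SpG        other          0
#> 5      SpG   intergenic        634

# off-targets of the first planted spacer, adapted-CFD scored
tabs <- synthetic_cfd_tables(1)
hits <- find_offtargets(sim$genome, sim$truth$protospacer[1], "SpG", max_mismatches = 4)
offtarget_report(hits, tabs, "SpG")
#> offtarget_report for spacer AAGATTTCTTGTAGGAACGT
#>   1 hit(s), 0 off-target(s); max off-target CFD 0.000
#>   hits by mismatch count:  0:1

# IVT template for a GG-start spacer
design_fillin("GGCTAGCTAGCTAGCTAGCT")
#> fillin_design: 52-nt forward oligo, 80-nt universal oligo, 117-bp product
#>   forward: TAATACGACTCACTATAGGCTAGCTAGCTAGCTAGCTGTTTTAGAGCTAGAA
#>   spacer starts GG: TRUE

# recover editing efficiency from a simulated co-CRISPR screen
ex  <- simulate_experiments(seed = 7, n_p0 = 200, f1_mean = 100, true_efficiency = 0.3)
eff <- p0_efficiency(ex$p0$n_positive, ex$p0$n_f1_total, min_f1 = 10)
mean(eff, na.rm = TRUE)
#> [1] 0.2966
```

The 1073 sites are every NGN-adjacent 20-mer on either strand; 86 score
above the 66 threshold under this synthetic model. The off-target report
shows the planted spacer is unique in the genome (only its own 0-mismatch
hit, so the maximum off-target CFD is 0), and the per-P0 efficiencies
average back to the simulated truth of 0.3.

A command-line interface over the same functions is provided in
`inst/cli/minipam.R` (subcommands `scan`, `score`, `offtargets`, `census`,
`design-oligos`, `mix`, `quantify`, `enrich`, `simulate`), or in-process via
`minipam_run(c("scan", "--genome", ...))`.

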