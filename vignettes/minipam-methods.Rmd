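---
title: "Methods: PAM-relaxed target design and efficiency quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAM-relaxed target design and efficiency quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minipam)
```

# Scope and model

`minipam` treats CRISPR target design for PAM-relaxed SpCas9 variants as four
deterministic computations over a genome — site enumeration, on-target
scoring, off-target scoring and region censuses — plus the arithmetic and
statistics used to quantify editing outcomes in zebrafish phenotype assays
and *C. elegans* co-CRISPR screens. Nothing in the package is fit to data:
on-target model coefficients and CFD penalty matrices are *inputs*, loaded
from delimited text, and every computation is reproducible from a genome, a
parameter set and (for the simulators) a seed.

## Coordinates

All internal coordinates are 1-based, closed intervals on the plus strand —
the convention GTF files and the Bioconductor interval stack already use —
so annotation import involves no shifting, and off-by-one conversions happen
at exactly one boundary: BED output (0-based, half-open). Reverse-strand
sites carry plus-strand coordinates of the same physical bases; their
sequences (protospacer, PAM, scoring context) are reported in the
protospacer's own 5′→3′ orientation.

## Site enumeration

A site is a `spacer_length` protospacer (default 20 nt) immediately 5′ of a
PAM matching an IUPAC pattern, on either strand. Two decisions matter:

* **Genomic N never matches** any pattern position, including pattern N.
  Assembly gaps therefore produce no designable sites, which is the
  behaviour a bench scientist wants — an oligo cannot be ordered against an
  N-run. Protospacers that merely *contain* N (with a valid flanking PAM)
  are still reported, flagged `contains_N`.
* **No deduplication.** Overlapping sites, and sites on opposite strands over
  the same bases, are all reported; censuses count per strand.

The enumeration contract is defined by an exhaustive window-sliding scan,
and the test suite holds the implementation to exact equality with an
independently written brute-force oracle on random genomes across all
registered PAM classes, along with the algebraic consequences
(sites(NGG) ⊆ sites(NGN) ⊆ sites(NNN); NGH and NGG partition NGN; strand
mirror symmetry under reverse complement).

## On-target scoring and the NGG-substitution rule

The activity model is a linear score over positional 1-mer/2-mer features of
a 35-mer context laid out as 6 nt upstream + 20-nt protospacer + 3-nt PAM +
6 nt downstream, in protospacer orientation; raw score = intercept + matched
weights, mapped affinely from `[raw_min, raw_max]` onto 0–100 and clamped.
This layout and scale match the published in-vivo activity models for
IVT-gRNA/SpCas9 delivery, whose coefficient sets can be transcribed into the
TSV model format; tests use synthetic models so that correctness never
depends on any particular coefficient set.

Because SpG and SpRY are SpCas9 derivatives with no strong reported sequence
bias beyond the PAM itself, an SpCas9-trained model is applied to their
targets by **forcing context positions 28–29 (the 2nd and 3rd PAM bases) to
GG before scoring**. The first PAM base — the N of NGG — is retained as
observed, since the model's NGG-based featurisation treats it as free. The
testable form of this rule is PAM invariance: scores are unchanged under any
substitution at positions 28–29, which the suite verifies on random
models × contexts.

The high-efficiency threshold is **strict**: predicted highly efficient iff
score > 66 (equivalently ≥ 67 on integer scores). Sources describing the
classification differ between "66 or more" and ">66/≤66" group boundaries;
we adopt the strict form used where the groups are actually defined, and the
threshold is a parameter everywhere it appears.

## Off-target search and the adapted CFD

Candidate off-targets for a spacer are all sites whose PAM matches the
*variant's own* pattern (NGG for SpCas9, NGN for SpG, NRN for SpRY) and
whose protospacer is within `max_mismatches` of the spacer; genomic N counts
as a mismatch. Mismatch positions are numbered from the PAM-proximal end.
The optional seed-restricted mode returns only hits whose PAM-proximal
`seed_length` bases (default 12 — the convention of the scoring lineage this
package follows; no canonical length is established) match perfectly.

The CFD score of a hit is the product of per-position mismatch penalty
factors times a PAM factor. The adaptation for PAM-relaxed variants: a PAM
matching the variant's pattern contributes **1.0** — these enzymes recognise
those PAMs natively, so the NGG-variant 2-mer penalties characterised for
SpCas9 would understate risk — while SpCas9/NGG scoring keeps the empirical
2-mer factor. PAMs outside the variant's pattern are not searched (we do not
invent a penalty for them); a widened search would report them with factor 0
for audit only. NYN PAMs for SpRY are likewise excluded rather than guessed
at. Penalty tables must be complete (all position × base × base mismatch
combinations), and a missing entry is an error rather than a silent 1.0.

The packaged `synthetic_cfd_tables()` matrix is **synthetic** — a
seed-reproducible stand-in with PAM-proximal mismatches penalised more
heavily, used by tests and examples. Users scoring real designs should load
an empirical matrix with `read_cfd_tables()`.

## Censuses

A site is assigned to one region class by the class of the base at its **cut
position** — the blunt cut 3 bp 5′ of the PAM, between protospacer positions
17 and 18; the anchor base is position 18, the PAM-proximal side of the cut.
The cut is where lesions and HDR distance bookkeeping live, which makes it
the biologically meaningful anchor; anchoring at the PAM would shift a few
percent of boundary-straddling sites between classes. Overlapping
annotations resolve by precedence CDS > UTR > intron > other > intergenic
(CDS-first matches the emphasis of a per-CDS census); positions covered by
no feature are intergenic, and every base resolves to exactly one class —
the index is total by construction and the class base-counts sum to the
genome length. Introns are taken from explicit intron features when present,
otherwise derived as gaps between each transcript's exons. A target whose
cut position lies in the CDS of two genes counts for both; no fractional
assignment.

## Oligo and mix arithmetic

The fill-in template geometry is fixed by lengths: forward oligo = 17-nt T7
promoter + 20-nt spacer + 15-nt annealing tail = 52 nt; with an 80-nt
universal reverse oligo and the 15-nt overlap, the product is
52 + 80 − 15 = 117 bp (general formula fwd + rev − overlap). The T7 core
`TAATACGACTCACTATA` is the only 17-nt T7 promoter consistent with that
geometry and is a parameter with that default; the default annealing tail is
the first 15 nt of the invariant sgRNA scaffold, also a parameter, since
published protocols give lengths rather than sequences. Spacers lacking a
5′ GG warn rather than fail — T7 initiation wants GG, and all-GG designs
give a 100% gRNA–target match, but mismatched-5′ designs are still usable.

Mix arithmetic is exact dilution: final = stock × volume / total, ratios
normalised to the smallest nonzero final concentration. The reference
in vitro cleavage setup (gRNA 9 µL @ 300 nM, nuclease 3 µL @ 900 nM, DNA
3 µL @ 90 nM, water 12 µL, buffer 3 µL; 30 µL) reproduces 90:90:9 nM =
10:10:1 by construction, and mass balance and scale invariance are tested
properties.

## Quantification

* Phenotype assays: per-class fractions over (class III, class II, class I,
  WT); *highly efficient* ⇔ fraction(class III + II) ≥ 0.5 **and**
  fraction(WT) < 0.1. The severe cutoff is inclusive ("at least 50%"), the
  WT cutoff exclusive ("less than 10%"); descriptions of the rule vary
  between "more than" and "at least" for the severe arm, and we use ≥ with
  both cutoffs parameterised. *Mosaic* = any non-WT class, computed as
  (n − WT)/n directly on counts so boundary cases like 10/100 compare
  exactly against a 10% cutoff.
* Per-P0 efficiency = positives / F1 total, with P0s under the brood-size
  threshold (`min_f1`; 100, 10 or 5 depending on assay design) **excluded as
  NA, never imputed as zero** — they drop out of means and tests.
* Edited alleles % = (2·hom + het)/(2·screened) × 100; HDR % =
  correct-size insertions / genotyped × 100. Reported percentages round
  half-up to one decimal at the reporting layer only.
* Fisher's exact test (two-sided, probability-mass convention: sum of tables
  at the observed margins with point probability ≤ observed) via
  `stats::fisher.test`, cross-checked in the suite against direct
  hypergeometric enumeration; χ² of contingency with Yates' correction for
  2×2 via `stats::chisq.test`, cross-checked against the explicit
  |O−E|−0.5 formula.

## What the simulators emulate — and what they do not

`simulate_genome()` draws i.i.d. background at a stated GC (default 0.36,
the nematode/zebrafish range), plants unique spacer+PAM substrings with ≥6 nt
flanks, and rejection-resamples the background until no accidental copy of
any planted spacer exists on either strand (bounded retries, then error) —
so the truth table is exhaustive, not merely sufficient. The annotation is a
plain plus-strand gene layout (UTR–CDS–intron–CDS–UTR). This emulates what
the scanner and census need: motif composition, strandedness, region
structure. It does **not** emulate repeat families, GC isochores, soft-masked
repeats, alternative isoforms or minus-strand genes — so passing tests show
the computations are correct, not that any particular real genome's census
will look like the synthetic one.

`simulate_experiments()` draws F1 brood sizes Poisson(100), positives
Binomial(brood, e) with e = 0.3 by default, homozygotes Binomial(positives,
0.2), and phenotype classes Multinomial — the sampling structure the per-P0
and per-condition statistics assume. Real screens add over-dispersion
between injection days and injector effects that the simulator deliberately
omits; recovery tests (mean within 3 SE of truth at n_P0 = 200, F1 ≈ 100)
therefore validate the estimator arithmetic, not field variability.

## Numerical choices and degenerate inputs

Scores clamp to [0, 100]; the affine map is strictly increasing between
clamps. Site tables sort by (contig, start, strand) and off-target reports
by CFD descending then coordinates, so ties break deterministically. Empty
genomes, empty annotations, zero-entry models, zero-planted simulations and
edge-truncated sites (fewer than 6 flanking bases → unscored, flagged, not
an error) all have defined behaviour and tests. FASTA ambiguity codes other
than N become N with a warning; non-IUPAC characters are errors; duplicate
contig names are errors.

## Problem sizes

The test suite runs entirely on synthetic data: oracle-equality sweeps use
100 random genomes of 0.3–5 kb (six PAM classes, mismatch budgets 0–4, both
seed modes), scoring invariance uses 1000 random contexts over 20 random
models, Fisher agreement enumerates all 2×2 tables with cells ≤ 6 plus
random tables with margins ≤ 12, and quantification recovery uses 200 P0s
at ~100 F1s each. Genome-scale censuses of real assemblies run through
exactly the same code paths but are exercised here only via conservation and
monotonicity properties on synthetic genomes.

## Known limitations

No bulge (insertion/deletion) off-target model; no 5′-PAM (Cas12a-style)
enzymes; no thermodynamic oligo QC; no on-target model training; no
chromatin-aware off-target weighting. The CLI reads plain or gzipped text
but has no faidx/tabix random access, so it is suited to genomes that fit in
memory.
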