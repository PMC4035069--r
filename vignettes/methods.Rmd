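---
title: "Methods: models, parameters and design choices in ovamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ovamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

ovamir reimplements, at desk scale, the analysis shape of a two-library
small RNA sequencing comparison of ovarian tissue: single pooled libraries
per group, no biological replicates, and the statistical toolkit that era
used for that design. This vignette explains each stage's model and
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the choices made where the design was
genuinely open.

## 1. Read cleaning and the accounting identity

Reads pass a fixed filter cascade, and each read is counted in exactly the
first category it fails:

1. low quality — mean Phred < `quality_threshold` (default 20) or any
   non-ACGT base;
2. 3' adapter absent — no suffix-overlap alignment of the 3' adapter with
   at least `min_overlap` (6) nt and at most 1 mismatch per 10 nt of
   overlap;
3. empty insert — the adapter starts at position 1 (adapter dimer);
4. 5' adapter contaminant — the trimmed insert begins with an 8 nt prefix
   of the 5' adapter with at most 1 mismatch;
5. shorter than 18 nt;
6. polyA — at least 80 % A after trimming.

The order is fixed so that the per-category counts are well defined and
obey `high_quality = clean + Σ removed`, the identity the original
filter-accounting table is built on; the acceptance suite feeds that
table's printed removal counts through `filter_report()` and reproduces its
printed clean-read totals and percentages exactly (percentages are counts
over high-quality reads, rounded to 2 decimals).

The platform's internal definitions of "low quality" and of the adapter
alignment are not public; the defaults above are conventional for 36-cycle
fixed-length reads and are all exposed as arguments. One deliberate
extension: a read with no adapter hit is *kept whole* when it is no longer
than 30 nt (`keep_adapterless_max_len`). Raw 36-cycle reads are unaffected
— an insert in the library's 18–30 nt size range always leaves at least 6
nt of readable adapter — but this makes cleaning idempotent: re-cleaning
already-trimmed inserts removes nothing.

## 2. Annotation priority

Every unique tag receives exactly one category with precedence
`rRNA-class ncRNA > known miRNA > repeat > exon > intron > unann`. Within
the ncRNA block the subtype order is `rRNA > tRNA > snRNA > snoRNA > scRNA
> srpRNA` (the block's precedence is fixed by the emulated protocol, the
tie order inside it is not; ours is configurable). ncRNA and miRNA
membership are decided by sequence against the reference sets; repeat,
exon and intron by genomic hits overlapping features, taking the
best-priority annotation over *all* loci of a multi-mapping tag.
Exon/intron split into sense/antisense by the strand of hit versus
feature, sense winning when both occur. Genome mapping defaults to exact
matching (0 mismatches, the era's small-RNA practice; up to 2 via
`max_mismatch`), and the mapped fraction is reported read-weighted — the
emulated study does not say whether its mapped percentage counts reads or
tags, and read-weighting matches its read-denominated percentages
elsewhere.

## 3. Quantification

Tags annotated as known miRNA are credited to exactly one mature each:
exact matches first, then the nearest mature within tolerance (≤ 2
mismatches over the aligned overlap, ≤ 2 nt of 5'/3' end offset — the
emulated protocol says only "little mismatches"). Ties break by fewest
mismatches, then smallest total offset, then lexicographic id, making
crediting deterministic. A tag matching several matures is counted once
(toward its best match), so credited counts conserve the category total.
Normalized expression is `count / clean_reads × 10^6` (TPM), kept at full
precision internally and rendered half-away-from-zero when displayed —
the rounding mode is validated against all twelve printed values of the
emulated study's specific-miRNA table.

One internal inconsistency of the emulated protocol is resolved in favour
of its printed data:
the "specifically expressed miRNAs higher than 1000" table only matches
its own printed rows if the threshold applies to *raw counts* (all printed
counts exceed 1000 while most printed TPM values do not), so
`top_specific_report()` thresholds counts, not TPM.

## 4. Differential expression

With one pooled library per group there is no replicate variance to
estimate; the Audic–Claverie exact test treats the count pair directly:
`p(y|x)` is negative binomial with size `x+1` and probability
`N1/(N1+N2)`, tails are computed with `pnbinom`, and the two-sided p
doubles the smaller tail (capped at 1). p-values are computed on raw
counts with library totals; the 0.01 zero-revision affects only fold
changes, because the test is count-based by construction. No
multiple-testing correction enters the significance labels (the emulated
study applies none); a Benjamini–Hochberg column is emitted for reference.

Two properties deserve note:

* **Asymmetry.** The doubled-tail p conditions on `x`. It is *not*
  invariant under swapping the libraries, not even at `N1 = N2` (only the
  pointwise probability is symmetric there; our property suite asserts
  exactly that). This is inherent to the statistic, not an implementation
  artifact.
* **Orientation.** Library 1 (the multiple-kidding group) is the control /
  X axis by default, matching the emulated scatter plot; `control = 2L`
  flips it, since the study never names which group it treated as control.

Labelled miRNAs are clustered by average-linkage hierarchical clustering
of Euclidean distances between per-miRNA log2 TPM vectors, exported as
newick. The displayed "rounds of clustering" in the emulated figure is a
property of its plot, not an algorithm parameter, and is not enforced.

## 5. Novel miRNA prediction

Unannotated tags with ≤ 15 genomic loci spawn windows of tag ± 70 nt;
overlapping windows merge. Per window the most abundant tag is the mature
candidate, and precursor hypotheses place it on the 5' or 3' stem arm with
narrow and wide flanks, in both orientations. Each hypothesis is folded by
the built-in dynamic program and the best (lowest-energy, preferring
well-paired matures) is judged against Mireap-style criteria: energy ≤ −18,
≥ 0.6 of mature bases paired outside the mature (stem pairing with the
star arm), mature not spanning the loop, mature length 20–24 nt, ≥ 0.7 of
mature-arm reads sharing the modal 5' end (Dicer consistency), ≥ 3
supporting reads, and no overlap with known annotation. Dicer consistency
and support are computed over reads overlapping the mature span — reads
elsewhere in a merged window belong to other loci, but a read across the
mature with a shifted 5' end argues against precise processing. Windows
already failing the read-based criteria are reported unfolded
(`fold_all = TRUE` forces folding), which keeps large runs cheap without
changing any call.

**Folding model.** The default scorer is a Nussinov-style dynamic program
over non-crossing pairings with a minimum loop of 3, where each pair
contributes a Watson–Crick/wobble energy (GC −3, AU −2, GU −1) and each
directly stacked pair an extra −1 — Turner-like magnitudes without loop
penalties. It is deliberately simple enough to verify exhaustively: the
test suite enumerates *all* structures of random 12-mers and confirms the
DP attains the optimum. The −18 threshold is interpreted in this model's
kcal/mol-like units. Because the model omits destabilizing terms it is
more permissive than a full thermodynamic folder; the energy criterion
therefore does less discriminating work than in Mireap, and the read-based
criteria (support, Dicer consistency, annotation exclusion) carry more.
A plain base-pair-maximization model (`model = "pairmax"`) is included as
a fallback scorer.

## 6. Targets and enrichment

A target site is each exact occurrence of the reverse complement of the
miRNA seed (positions 2–8, U≡T) in a 3' UTR; no thermodynamic or
conservation scoring. (The emulated study attributes target prediction to
a hairpin-prediction tool, which cannot be what ran; the seed rule its
text states is what is implemented.) Enrichment uses the exact
hypergeometric upper tail computed with `lchoose` + log-sum-exp, checked
against both subset enumeration and `phyper`. GO ontologies are corrected
by Bonferroni *within each ontology* — matching the per-ontology
significance counts the emulated study reports — and pathways by
Benjamini–Hochberg (the study says only "FDR"; BH is the default
interpretation and is swappable). Genes, not sites, are the enrichment
unit.

## 7. qPCR validation

Relative expression is `2^-(CT_miRNA − CT_reference)` per replicate. The
group comparison is an ordinary linear model on log2 relative expression
with a two-level group factor — the equivalence class of the original
"GLM" on two samples — flagged at p < 0.01. A degenerate, zero-residual
fit (possible with synthetic noise-free CTs) is resolved by definition:
identical groups give p = 1, a zero-variance nonzero difference p = 0.
Concordance with sequencing compares signs of the qPCR log2 ratio and the
sequencing log2 fold change; zero-change miRNAs carry no direction and are
excluded from the agreement fraction.

## 8. What the generator emulates, and what it does not

The generator states the study's world: two 36-cycle libraries with
adapter read-through; insert lengths on 18–30 nt peaking at 22 nt; a
log-normal miRNA abundance skew (`abundance_sdlog = 1.5`) so a few miRNAs
dominate both libraries; technical contaminants at roughly the printed
filter-table rates (low quality 0.6 %, missing 3' adapter 0.02 %, adapter
dimers 0.01 %, 5' contaminants 0.16 %, short 0.1 %, polyA trace); ncRNA
contamination (rRNA 3 % dominating); genomic background including repeat,
exon, intron and unannotated reads; planted novel hairpin loci with
Dicer-consistent 5' ends (10 % jittered by 1 nt); a planted DE fraction
(10 % of miRNAs at 4-fold, half up, half down); and a CT table generated
from the same truth at 1 cycle per abundance doubling with 0.25 cycles of
Gaussian noise. Precursors are mature + 8 nt loop + mutated reverse
complement + 10 nt flanks, so hairpin folding holds by construction.

Not emulated: sequencing-error structure beyond uniform substitutions
(0.1 %/base), ligation and GC bias, isomiR ladders, real genome repeat
structure, and real database scale. A green test therefore establishes
that the pipeline recovers what was planted under the stated conditions —
not that it would reproduce the original study's dataset-dependent
headline counts, which depend on undeposited reads and on 2013-era
database versions and are explicitly out of reach. Test and demo depths
(10–100 k reads) are scaled down from the study's ~6 M for runtime; the
per-read model is depth-independent, and the DE recovery criterion is run
at 2 × 10^5 reads with 500 miRNAs.

Recovery criteria follow the module contract: ≥ 95 % `**` recall is
measured over planted DE miRNAs whose expected count reaches 50 in at
least one library (the abundance skew necessarily leaves some planted
miRNAs with single-digit expected counts, where no exact test could call
4-fold significant), and ≥ 95 % `None` over all DE-tested null miRNAs.

## 9. Numerical conventions

* Coordinates are 0-based half-open internally and in TSV truth tables;
  BED files follow the BED dialect; GRanges objects are 1-based closed.
* Displayed TPM rounds half away from zero; full precision is kept
  internally.
* The exact test and hypergeometric tail work in log space; oracle
  comparisons in the suite are at 10^-10 relative or better.
* Folding tie-breaks are fixed (3' base unpaired first, bifurcations by
  ascending partner, stacked inner structure preferred), so structures are
  deterministic.
* All simulation randomness derives from one integer seed via fixed child
  seeds (< 2^31); identical configurations are byte-identical, including
  FASTQ output and the manifest digests.

## 10. Known limitations

Single-library-per-group design throughout — no replicate-aware models, by
construction of the emulated study. The folding model ignores loop
penalties and dangles. Annotation requires exact ncRNA substring matches
(no BLAST-style gapped alignment). The CLI is a thin launcher over
`run_all()`, not a workflow engine. Enrichment does no GO-DAG propagation;
term maps are flat.
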