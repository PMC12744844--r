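---
title: "Methods and design of the sirmsd package"
author: "sirmsd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the sirmsd package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirmsd)
```

## The model

A guide strand loaded on Argonaute 2 presents its seed region
(nucleotides 2–8 from the 5′ end) in a near-A-form conformation that
the protein pre-organises, especially at positions 2–5. A 2′-ribose
modification can push the neighbouring nucleobases out of that
conformation, and the displacement itself — not any energy or
electronic property — is the quantity this package scores:

$$\mathrm{siRMSD}\;(\text{\AA}) = \sqrt{\tfrac{1}{K}\sum_{i=1}^{K}\delta_i^2}$$

with $\delta_i$ the Euclidean distance between nucleobase heavy atom
$i$ of the modified model and the same-named atom of the unmodified
model, both expressed in one fixed coordinate frame. Three consequences
of this definition drive the implementation:

* **No superposition.** Models produced by constrained optimisation
  against the same protein share a frame; superposing them would
  subtract exactly the rigid component of the distortion that matters.
  `pairByName()` therefore measures raw frame distances. A Kabsch
  superposition is available behind an explicit `superpose = TRUE` for
  exploratory comparisons of structures that do *not* share a frame,
  and is never the default.
* **Nucleobase heavy atoms only.** The atom sets are fixed by base
  identity (A 10, G 11, C 8, U 8, T 9 including the methyl carbon);
  sugar, phosphate and hydrogens never enter the score even when
  present. Atom names are normalised across PDB dialects (`C2*` ≡
  `C2'`; thymine `C5M` accepted as `C7`).
* **Windows.** For a modification at position N, single-nucleotide
  scores at N−1, N, N+1 and all their combinations are defined.
  Position 2's window legitimately reaches nucleotide 1 and position
  8's reaches nucleotide 9.

### Combining a multi-nucleotide window

Three combination rules are implemented. `POOLED` (default) applies the
RMSD formula once over the union of window atoms, so the result stays
in Å and equals the K-weighted quadratic mean of the per-nucleotide
values; `SUM_RMSD` adds per-nucleotide values (Å); `SUM_MSD` adds
per-nucleotide mean squared distances (Å²). The field's verbal
descriptions of windowed scores are ambiguous between these readings.
We made `POOLED` the default because it is the only rule that is
literally the defining equation applied to the window's atom set and
the only one whose units match the axis label of a distortion profile
in Å; the other two remain selectable, and per-nucleotide values are
always reported so any rule can be recomputed after the fact. This was
a genuinely open choice: resolving it empirically would require the
deposited quantum-chemistry coordinates, which are not shipped with
the package.

## Structure input

Two formats are read. Fixed-column PDB records are parsed with strict
contracts: malformed numeric fields fail with the offending line
number, insertion codes are rejected outright (silently guessing a
residue indexing is worse than failing), and alternate locations
resolve to the highest-occupancy copy with ties broken by the smallest
alt-loc code. Quantum-chemistry coordinate listings — bare
element/x/y/z rows with no residue labels — are bridged by a curated
annotation table assigning each row a guide position, base,
modification and atom name; row counts must agree and the element
implied by each atom name must match the coordinate row, so a
misaligned table cannot silently mis-score.

## Steric extent of a 2′ substituent

The size of a modification is measured as the distance from the ribose
C2′ to the farthest atom of the 2′ substituent, hydrogens included
(for 2′-deoxy the hydrogens *are* the substituent). Because coordinate
files carry no connectivity, bonds are inferred from Cordero covalent
radii with a 0.45 Å tolerance — wide enough for DFT-relaxed bonds,
narrow enough not to bridge 1–3 contacts at tetrahedral angles — and
the substituent is the breadth-first closure from C2′ with the ring
neighbours C1′/C3′ blocked. Reaching the phosphate backbone is
reported as a corrupted bond graph, never silently truncated.

## Reporter assays

Relative activity is the replicate-mean Renilla/firefly ratio as a
percentage of the control siRNA's mean ratio. SOA rescales the
modified siRNA's off-target reporter activity against the unmodified
siRNA's; it is 0 when nothing changed, 100 at full derepression, and
deliberately unclamped outside that range so aberrant assays remain
visible. IC50 uses bracketing interpolation on the log-concentration
scale, not a four-parameter logistic fit; an exact 50% hit returns the
tested concentration, a curve that never crosses 50% returns an
explicit not-estimable sentinel, and non-monotone curves use the
lowest-concentration crossing (the conservative potency estimate).
Modified-vs-unmodified replicate comparisons use Welch's t test — the
equal-variance assumption buys nothing at triplicate scale.

## Melting temperature

Tm is the temperature at which the second derivative of the A260
melting curve changes sign nearest the extremum of the first
derivative, refined by linear interpolation between grid points. Raw
(smoothed) absorbance is differentiated directly; no fraction-folded
baseline normalisation is applied, and the estimate is invariant under
affine transformation of the absorbance. Smoothing is a centered local
quadratic (Savitzky–Golay) filter whose derivative filters supply the
derivatives on uniform grids. The default window is 21 points (10 °C
at 0.5 °C spacing): on a synthetic two-state transition of width 2.5 °C
with 0.002 AU Gaussian noise an 11-point window locates the inflection
to ±0.3 °C in only about three quarters of seeded replicates, while 21
points achieves essentially complete recovery without measurable
midpoint bias (the filter is symmetric and the logistic transition is
symmetric about its midpoint). Curves with no detectable curvature —
e.g. strictly linear absorbance — yield a not-estimable sentinel
rather than a spurious inflection; the guard compares the maximum
second derivative against the absorbance range at the observed
temperature span. When an instrument trace contains both a heating and
a cooling ramp, `splitRamps()` separates them and the heating ramp is
the conventional input. ΔTm is a plain difference against an
unmodified reference duplex, 74.5 °C by default.

## Seed-match expression analysis

A transcript is seed-matched (SM) iff the exact DNA reverse complement
of guide positions 2–8 occurs in its 3′UTR — no G:U wobble, no
mismatches, U/T encoding normalised on both sides. Records must pass
all six array feature-extraction QC flags and a RefSeq-mRNA identifier
pattern. Intensities are quantile-normalised (ties averaged) before
fold changes; the effect statistic is the difference between the SM
and non-SM mean log2 fold change (treated over mock), tested with a
two-sided Wilcoxon rank-sum — exact enumeration when the larger group
has at most 20 transcripts and the data are tie-free, otherwise the
normal approximation with continuity correction. MA tables (M = log2
fold change, A = mean log10 intensity) and per-group cumulative
fraction curves accompany the summary.

## Correlation machinery

Pearson r with the two-sided p from the t statistic on n−2 degrees of
freedom and a 95% interval by the Fisher z transform (defined from
n = 4). Zero-variance inputs return an undefined-correlation sentinel,
as do groups with fewer than 3 points in grouped reports — sentinels,
never silently dropped rows. Regression bands are confidence bands for
the mean response (the shaded band of a scatter plot), not prediction
bands. Grouped correlation reports evaluate each window combination
over positions 2–8 and the mechanistic split 2–5 / 6–8, one point per
(modification, position) condition using mean SOA, matching how such
dot plots are conventionally drawn.

## The synthetic-fixture generators

Every analysis input can be generated with known ground truth:

* **Structures.** Idealized helical placement (defaults rise 2.8 Å,
  twist 32.7°, A-form-like) of full nucleotides with standard atom
  names, built from standard bond lengths and angles by internal-to-
  Cartesian placement, including the complete 2′ substituent of each
  of the seven chemistries and a declared bond topology that the
  covalent-bond inference is validated against. The geometry is an
  idealized stand-in, not physically accurate RNA: the distortion
  statistic depends only on displacement fields between two models in
  one frame, so helical realism is irrelevant to what the tests
  demonstrate. Substituent chains are built anti with two
  stereoelectronically motivated exceptions (gauche OCCO in 2′-MOE,
  gauche anomeric torsions in the 2′-MTMM acetal). Consequently the
  anchored extents of the conformationally flexible chains (2′-FA,
  2′-MOE, 2′-MTMM) are properties of these idealized conformers, not
  of any deposited DFT structure, and the validation suite asserts the
  size *ordering* of the seven chemistries plus the exact extents only
  where local bond geometry determines them (2′-H, 2′-F, 2′-OH,
  2′-OMe).
* **Distortions.** `perturbStructure()` displaces window nucleobase
  atoms with isotropic Gaussian noise or a rigid shift and returns the
  expected score of every mode computed from the *realized*
  displacements — the manifest the scoring path must reproduce.
* **Reporters.** Log-normal multiplicative noise (default CV 0.1)
  around declared true activities, triplicate by default, with control
  rows at 100%.
* **Melting curves.** Sloped baselines joined by a logistic transition
  (defaults: amplitude 0.18 AU, width 2.5 °C, 30–90 °C at 0.5 °C,
  noise 0.002 AU) — the two-state approximation of a duplex melt.
* **Expression.** Log-normal abundances (log2 mean 8, sd 1.5) with
  per-sample log2 noise (default 0.25) and a declared SM fraction
  (default 10%) receiving the planted effect in the treated column;
  the seed-complementary 7-mer is planted in every SM 3′UTR and
  scrubbed from every non-SM UTR so sequence classification recovers
  the truth exactly.

All generators are pure functions of their parameters and seed and
leave the global RNG stream untouched. What passing these recovery
tests shows is that the estimators are calibrated under the generative
model's assumptions (two-state melts, log-normal noise, exact seed
matches, one probe per transcript); real data add baseline drift,
probe-level structure, wobble pairing and annotation error that the
generators deliberately do not emulate.

## Validation problem sizes

The test suite and the acceptance script run at fixed, modest sizes
chosen to make the statistical checks sharp: 100 random atom fixtures
against a brute-force loop oracle (agreement to 1e-12 relative), 100
seeded melting replicates per recovery rate, 2,000-transcript
expression matrices (the scale at which 3 standard errors ≈ 0.08 log2
units), 200 null replicates for the rank-sum p uniformity check, and
10,000 bivariate-normal replicates at n = 35 for the Fisher interval
coverage (nominal 95% ± 2%).

## Known limitations

* The package scores coordinates; it does not produce them. Quality of
  the siRMSD value is bounded by the quality and frame-consistency of
  the structural models supplied.
* Seed-match classification is exact 7-mer complementarity; transcripts
  repressed through wobble or offset sites are out of scope by design.
* IC50 bracketing assumes the tested concentrations straddle 50%
  inhibition; it refuses to extrapolate.
* The not-estimable sentinels (IC50, Tm, correlation) are values, not
  errors: downstream code must check `isEstimable()`.
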