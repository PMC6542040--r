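---
title: "Methods: paired-fluid endogenous peptidomics with peptidome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-fluid endogenous peptidomics with peptidome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptidome)
```

## The problem this package addresses

Pulmonary exposure to nanomaterials such as multi-walled carbon nanotubes
triggers matrix-protease activity in the lung; the resulting endogenous
peptide fragments appear both in bronchoalveolar lavage fluid (BALF) and,
after translocation, in serum. Characterizing this circulating peptidome by
data-independent acquisition (DIA) mass spectrometry poses a chain of
analysis problems that this package implements as a tested, reusable
pipeline:

1. **Feature definition.** DIA ion events (retention time, ion-mobility
   drift bin, charge-reduced protonated mass MH+, intensity) from all
   samples of both fluids are clustered jointly into cross-sample features.
2. **Reproducibility filtering.** Only features detected in at least
   two-thirds of the biological replicates of some (fluid × dose) group are
   kept.
3. **Quantitation.** Group-wise absent features are imputed at the group's
   limit of quantification; the matrix is median centered and log2
   transformed; fold changes are taken against the vehicle (dispersion
   medium) group.
4. **Differential statistics.** Per-feature one-way ANOVA across dose
   groups with Benjamini–Hochberg control at 5% FDR; detection-based
   classification into exposure-exclusive / lost / modulated / null;
   paired serum–BALF regression per dose group.
5. **Identification.** No-enzyme peptide–spectrum matching restricted to a
   protease-substrate / secreted-protein database (MEROPS- and
   SignalP-tagged records), at 6 ppm precursor and 12 ppm product
   tolerance, with shuffle-decoy FDR control at 10%.

Because no raw instrument data are publicly deposited for the motivating
study, a first-class synthetic-data module generates paired-fluid ion-event
tables, design tables and fragment spectra with the statistical structure
the analysis assumes; every downstream stage is tested against that planted
ground truth.

## Mass arithmetic

Peptide masses are residue sums over CODATA-consistent monoisotopic residue
masses (≥ 6 decimals); the protonated species is
`MH+ = residue sum + 18.010565 (water) + 1.007276 (proton)`.
Carbamidomethylation (+57.02146 Da on Cys) is a fixed modification, always
on: the iodoacetamide alkylation step in the sample preparation modifies
every reduced cysteine, and the printed masses of all cysteine-containing
identifications agree with the computed values only under this delta (the
bundled table reproduces to < 1 mDa across all 82 rows, ~0.3 ppm at 2 kDa).
No variable modifications are modeled; glycosylated and otherwise modified
species are out of scope.

Fragment ladders are singly protonated b ions (prefix sum + proton) and
y ions (suffix sum + water + proton), indices 1..n−1, satisfying
`b_i + y_{n−i} = MH+ + proton` exactly. Ladders are singly charged: the
annotated spectra the pipeline emulates label charge-reduced (effectively
1+) species. I and L are distinct residues of identical mass and are never
collapsed; identifications report the database sequence as stored.

## The synthetic world

The generator's defaults are the study's stated conditions wherever the
study states them, and a single declared choice everywhere else. They are
**not** tuned to test outcomes.

* **Design**: 3 doses (0, 10, 40 µg) × 6 animals, each animal contributing
  one serum and one BALF sample (36 samples).
* **Fluid overlap**: features are serum-only / BALF-only / common with
  probabilities 0.75 / 0.14 / 0.11. These are back-derived from the study's
  reproducible-measure counts (12,972 serum, 3,767 BALF, 1,712 common),
  which give the reported BALF/serum detection-depth ratio of 0.29 and the
  "nearly half of BALF measures seen in serum" overlap (0.45).
* **Classes**: null 0.40, modulated 0.30, exposure-exclusive 0.20,
  lost 0.10 — approximating the observed mix among common measures
  (613 exclusive and 259 lost of 1,712). Exclusive features have zero true
  abundance in every vehicle animal; lost features in every dosed animal.
* **Abundance model**: log2 baselines ~ N(14, 1.5²), per-animal deviations
  ~ N(0, 0.5²), multiplicative measurement noise at 30% CV, BALF
  concentrations scaled by 0.3 (the stated 3–4-fold serum/BALF peptide
  concentration difference). Dose effects are ±1.0 log2 at the top dose,
  scaling linearly with dose. None of these is stated by the study; they
  are standard label-free error structure, declared once here.
* **Cross-fluid correlation**: every variance component (baseline, animal
  deviation, dose effect) is drawn as a bivariate pair across fluids with
  correlation `cross_fluid_r` (default 0.5, the neighborhood of the
  reported per-dose regressions R = 0.49/0.48). The pooled serum–BALF
  log-intensity correlation therefore equals the planted value by
  construction, attenuated slightly (~5–10%) by the uncorrelated
  measurement noise.
* **Jitter**: RT σ 0.4 min, drift σ 1 bin, mass σ 3 ppm — each one third of
  the corresponding clustering tolerance, so true co-cluster membership is
  a ≈3σ event: recoverable, not trivial.
* **Censoring and noise**: events below the LOD (default 512 intensity
  units, an arbitrary instrument floor) are dropped; unclusterable noise
  events are added uniformly over the acquisition box at 20% of the
  true-event count.

What the generator does **not** emulate: chromatographic peak shapes,
isotope envelopes, charge-state deconvolution errors, retention-time drift
across runs, inter-batch effects, and real biological covariance among
peptides of one parent protein. A green test therefore establishes that the
pipeline recovers planted structure under idealized DIA error models — not
that it would reproduce any particular instrument's output.

## Numerical and procedural choices

* **Clustering** is greedy and seeded (the published workflow's internal
  algorithm is unpublished): events sorted by descending intensity; the
  most intense unassigned event seeds a feature and captures unassigned
  events within ±2 min / ±4 bins / ±12 ppm **of the seed** (not a running
  centroid — this avoids drift-dependent chaining), keeping at most one
  event per sample, nearest in tolerance-normalized Euclidean distance.
  Intensity ties break by (mass, rt, drift, sample) for determinism. A
  mass-sorted index makes the sweep linearithmic (50,000 events in ~12 s on
  one CPU).
* **Two-thirds rule**: `ceiling(2/3 × group size)` detections within at
  least one (fluid × dose) group — group-wise, because the downstream
  exclusivity classes require group-wise presence calls. For n = 6 this is
  4 of 6.
* **LOQ**: operationalized as the 5th percentile of a group's observed
  intensities (the source method states no formula); its CV is pooled from
  features in the lowest decile of group means, falling back to 0.3 when
  undefined. Imputation fills **only** feature×group cells with zero
  detections in the group, drawing from a zero-truncated normal
  (mean = LOQ, sd = CV × LOQ). Cells in groups with ≥1 detection stay
  missing and are handled pairwise downstream.
* **Median centering** computes per-sample medians over genuinely observed
  cells only. Imputed LOQ fills are group-absence markers, not sample
  loading; including them shifts medians of exactly the groups that carry
  them (vehicle samples carry the exclusive features' fills, dosed samples
  the lost features') and biased every fold change by ≈ −0.5 log2 units in
  the default world. Imputed values **do** participate in the ANOVA — that
  is their stated purpose (making categorically absent groups testable).
* **ANOVA**: classical fixed-effects one-way F across dose groups on log2
  intensities; features without ≥2 groups of ≥2 observations are untestable
  and assigned p = 1; all-constant features get p = 1 by convention. Both
  stay in the BH denominator m (conservative).
* **Cross-fluid regression** pools one point per (significant feature,
  animal) pair within a dose group — OLS of serum on BALF log2 intensity,
  reporting R with the slope's sign, F and p. Imputed cells are excluded
  (uncorrelated LOQ noise would shrink R toward zero); only genuinely
  observed pairs enter.
* **Identification**: candidates are all database substrings of length
  6–80 within ±6 ppm of the precursor MH+, found by binary search on
  per-protein cumulative residue-mass prefix arrays. The proprietary
  vendor "peptide score" is replaced by a reproducible hyperscore-style
  surrogate `S = Nb·log2(1+Ib) + Ny·log2(1+Iy)` (matched b/y counts,
  summed matched relative intensities); printed score values are therefore
  not reproduction targets. Decoys are seeded per-protein residue shuffles
  (length- and composition-preserving); sequence reversal was rejected
  because palindromic substrings inflate target–decoy overlap in no-enzyme
  search. Best match per spectrum per database; q value is the monotonized
  decoy/target tail ratio; acceptance at q ≤ 0.10.
* **Determinism**: one master seed fans out to stage seeds through a string
  hash (`derive_seed`), so any stage re-runs identically in isolation;
  full-pipeline outputs are byte-identical for a fixed configuration.

## Open questions resolved

* Whether fluids were clustered jointly or per-fluid-then-matched: joint,
  following the stated processing ("ion tables for matched BALF and serum
  samples were clustered together").
* Whether median centering was per fluid or across all samples: across all
  samples (the matrix is one joint clustering); a per-fluid restriction
  would only change results if fluid loadings differed non-multiplicatively.
* FDR level of identification competition: best-match (spectrum) level,
  with the sequence merge in candidate generation providing peptide-level
  provenance.

## Limitations

The synthetic substrate database embeds authentic identified peptide
sequences in random flanking residues (records are labelled synthetic);
absolute search-space statistics (e.g. decoy hit rates per Da) do not match
a real proteome's. Concentration estimates are single-point
(intensity / response factor) approximations with no calibration curve.
The pipeline assumes charge-reduced MH+ inputs; raw-signal processing
(peak detection, deconvolution, ion-mobility calibration) is out of scope.
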