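---
title: "Methods and design choices in aptacycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in aptacycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptacycle)
```

# Scope

`aptacycle` implements the computational side of a droplet-digital-PCR
(ddPCR) monitored SELEX campaign: turning per-cycle deep-sequencing
reads into family-level enrichment trajectories and candidate aptamers,
quantifying ddPCR wells, doing the oligonucleotide concentration
bookkeeping, and estimating dissociation constants from
thermofluorimetric melt curves.  A seeded synthetic-data generator
reproduces the statistical structure every stage assumes, so the whole
pipeline is testable without instrument data.

# The selection model behind the simulator

The pool is represented as a table of unique full-length reads with
counts.  The starting pool is `readsPerCycle` i.i.d. draws from the
library design — two 20-nt fixed flanks around a 30-nt random region
with base composition A:C:G:T = 29:29:20:22% — plus each planted
binder's seed at its `initialCopies`.  Each scheduled cycle resamples
`readsPerCycle` reads by a multinomial whose weights multiply binder
counts by `targetAffinity` in positive rounds and `matrixAffinity` in
counter rounds; background reads keep weight 1.  Branch splits (the
positive/counter fork after C8+) fall out of the schedule's `source`
column, which names the pool each cycle draws from.

Three generator parameters deserve comment:

* **`initialCopies` (default 5).**  A specific 30-mer is essentially
  absent from 2 × 10^5 draws out of a 4^30 library, so a planted binder
  must be seeded explicitly.  Five copies with the default
  `targetAffinity = 2` end near 2–3% of a 200,000-read pool after ten
  rounds — the scale at which strongly enriched families are observed
  in real campaigns (roughly 0.1–2.7%).  Larger multipliers saturate
  the pool within a few rounds and suppress the background diversity
  the clustering stage needs.
* **`variantRate` (default 0.005 per base).**  Binder reads are emitted
  as seed variants: per-base substitutions (capped at 5) plus at most
  one single-base indel, so every variant stays within edit distance 6
  of its seed.  The cap mirrors the clustering radius by construction —
  simulated families are recoverable by design, which is exactly what
  the planted-recovery tests exercise.
* **Seeding.**  One scenario seed is expanded into per-cycle child
  seeds, so identical scenarios are byte-reproducible and stages can be
  re-run independently.

The generator deliberately does **not** model PCR amplification bias,
polymerase error spectra beyond the fitness multipliers, sequencing
quality, chimeras, or cross-hybridization.  Passing tests therefore
demonstrate that the analysis recovers structure *of the kind the model
emits*; they do not certify behaviour under amplification artifacts
that real libraries can contain.

# Read processing

Flanks are located as an anchored prefix and suffix, each tolerating up
to 2 substitutions (configurable) and no indels; synthesis or
sequencing indels are instead absorbed by the 25–32 nt window on the
interior length (both bounds inclusive).  Reads with `N` in the
variable region are rejected with a reason code, since the downstream
edit distance has no principled cost for ambiguity codes.  Input is
assumed in library orientation; reverse-complement rescue is not
attempted, matching what the simulator emits.  Rejections are data,
tallied per reason in the `FrequencyTable`, never exceptions.

The abundance filter retains a sequence if its frequency is **at least**
0.01% in at least one cycle — boundary values are kept, and the
threshold is configurable on the fraction scale.

# Family clustering

Retained sequences are clustered in a single sequential pass at
Levenshtein radius 6 (inclusive).  Two choices the procedure needs that
a one-line description leaves open:

* **Processing order** — decreasing maximum per-cycle frequency, ties
  broken lexicographically.  Fixed ordering makes the clustering
  deterministic and puts the most abundant variant of each family
  first, where it founds the family and becomes its seed.
* **Linkage** — a sequence joins the earliest-founded family whose
  *seed* is within the radius (`linkage = "seed"`).  Any-member linkage
  (available as `linkage = "any"`) lets families chain and makes their
  radius unbounded, which defeats the purpose of a fixed radius in a
  single pass.

Sequences of different lengths (25–32 nt) are compared directly by edit
distance with no length normalization.  The distance kernel is a banded
dynamic program with an early-exit cutoff (`cutoff + 1` is returned as
soon as the distance provably exceeds the cutoff); tests verify it
against `utils::adist` as an independent full-DP oracle, and verify the
clustering against a brute-force full-matrix implementation of the same
rule.

# Enrichment ranking

Families are ranked by frequency in the last positive cycle and
annotated with the ratio of the last positive to the last counter
cycle, `(f+ + p) / (f- + p)`.  The additive pseudo-frequency `p`
defaults to the retention threshold (10^-4) rather than one read's
worth: frequencies at or below the detection limit are not
distinguishable from it, and shrinking their ratios toward 1 keeps the
false-flagging rate of neutral families low.  Under a fully neutral
200,000-read simulation, about 7% of families exceed ratio 2 with a
one-read pseudo (boundary families retained because of a lucky
final-cycle draw), versus about 0.1% with the detection-limit pseudo —
while genuinely enriched planted families, sitting 10–100 times above
threshold, are unaffected.  The flagging threshold (ratio ≥ 2) is an
operational default for "enriched with the target, depleted without
it", configurable per run.

# ddPCR quantification

Each droplet is scored positive if its amplitude exceeds the threshold.
The automatic threshold is the exact two-group split of the 1-D
amplitude distribution minimizing within-group variance, with the
threshold midway between the group means; a well whose two groups are
separated by less than 3 pooled SDs is treated as unimodal (a
no-template control, or fully saturated) and thresholded at mean + 5 SD
with a warning.  The proprietary instrument algorithm is not
reproduced, so thresholds may differ slightly from vendor software on
real exports.

Occupancy follows the Poisson partition estimate `lambda =
-ln(n_neg / n_total)`; concentration is `lambda / dropletVolumeUl` with
the droplet volume defaulting to 0.85 nL (the common instrument
standard; configurable because the concentration scales inversely).
The 95% CI is the exact Clopper–Pearson interval on the negative
fraction pushed through `-ln`, which round-trip tests show covers the
simulated truth in ≥ 95% of wells across occupancies 0.05–1.5.  The
droplet-count QC is strict (`> 10,000`), and a positive fraction
≥ 0.999 raises the saturation flag; a well with no negatives yields an
infinite-concentration sentinel rather than an estimate.

# Oligonucleotide bookkeeping

Molar concentration is Beer–Lambert, `A260 / (eps * l)`; mass
concentration is `c * MW * 1000` in ng/uL.  The expected molecular
weight of a library design sums exact flank masses and
composition-weighted random positions using the anhydrous
nucleoside-monophosphate convention with a −61.96 g/mol 5'-OH end
correction; vendor conventions differ at the per-mille level, so
comparisons against quoted constants use a 0.5% tolerance rather than
equality.  GC content of candidates is conventionally computed on the
variable region, not the full 70-mer — only that reading reproduces the
rounded 60/53/50% figures of the bundled candidates.

Ion totals of the artificial-urine recipe assume complete dissociation
of the 13 components (urea, creatinine and uric acid contribute no
ions).  Direct summation gives Mg²⁺ = 4.4 mM and Na⁺ = 89.3 mM; quoted
effective sodium values for artificial urine are sometimes lower,
depending on which components are counted, so the package always
reports the full stoichiometric total.

# Thermofluorimetric analysis

Melt curves are modelled as a two-state logistic mixture: the free and
bound aptamer each melt with midpoint `tmFree` / `tmBound` and width
2.5 °C (a typical transition sharpness for short structured ssDNA; the
true curve model of any given aptamer is unknown).  The bound fraction
comes from the single-site ligand-depletion quadratic, so the
generator's concentration response is exact.

* **Differentiation.**  `-d(RFU)/dT` is a Savitzky–Golay degree-2
  derivative.  For *peak location* the default window is 11 points
  (5.5 °C at the 0.5 °C cadence) — about half the transition FWHM, the
  usual compromise between noise and peak distortion; located Tm values
  land within one grid step of the generating midpoint.  For the
  *binding-curve readout* the default window is 41 points: the readout
  is an amplitude, its smoothing attenuation is uniform across
  concentrations and cancels into the fitted span, and the derivative's
  noise variance falls roughly as the cube of the window length.
  Narrow it for instruments with drifting baselines.
* **Analysis window** 10–85 °C by default, avoiding endpoint artifacts
  of the 4–90 °C ramp.
* **Blank subtraction** is pointwise on identical grids (optional
  linear interpolation); the blank is the 0 nM well of the same
  replicate, so the binding curve is zero-anchored by construction.
* **Bound-state Tm** defaults to the blank-subtracted peak of the
  highest-concentration well; known values can be passed directly.

`fitKd()` offers three response models with multi-start
Levenberg–Marquardt (log-spaced Kd grid, best residual sum of squares
wins): the 4-parameter Hill sigmoid, its hyperbolic (h = 1) special
case, and a single-site *ligand-depletion* model in which the signal is
proportional to the quadratic bound fraction at known total aptamer.
The distinction matters at the concentrations used here: with 100 nM
aptamer, the midpoint of bound fraction versus total protein sits near
`Kd + A/2`, so a free sigmoid reports an *apparent* constant roughly
50 nM above the underlying Kd.  The depletion model recovers the
underlying constant itself; a property test asserts both behaviours.
Uncertainty is the fit SE from the covariance, optionally augmented by
a residual-resampling bootstrap percentile CI.  Degenerate input
(fewer than 5 distinct concentrations, constant signal) or optimizer
failure returns a flagged, non-converged result rather than an error.

# Problem sizes and determinism

The shipped tests and the acceptance script run at the scales the
analysis is designed for: 200,000 reads over 12 scheduled cycles with
three planted binders among >1,000 background families; a
2,000-sequence planted clustering; 100 ddPCR wells of 20,000 droplets
per occupancy; and 50 melt-curve pipelines per reference affinity
(100 nM aptamer, 0–800 nM protein, three replicates, 5% fluorescence
noise).  Every stochastic step flows from one explicit seed, and
`runPipeline()` hashes its outputs into a manifest so a rerun with the
same configuration is byte-identical.

# Known limitations

* Counts of retained sequences and families from any *real* campaign
  depend on the actual reads; the package's planted-recovery guarantees
  hold for data within its generative assumptions.
* The clustering is single-pass and order-dependent by design; a
  different visiting order can split borderline families differently
  when seeds lie 7–12 edits apart.
* The Kd from the depletion model is still conditional on the nominal
  aptamer concentration and on the two-state melting assumption; dye
  photophysics, multi-site binding and matrix interference are out of
  scope.
* Droplet "rain" (intermediate amplitudes) and multichannel chemistry
  are not modelled; the auto-threshold assumes two clusters.
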