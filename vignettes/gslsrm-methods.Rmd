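---
title: "Methods: in-silico SRM design and semi-quantitative GSL analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico SRM design and semi-quantitative GSL analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(gslsrm)
```

## The model

An acidic glycosphingolipid (GSL) is a glycan headgroup glycosidically
attached to a ceramide. The package treats a species as a pair

* **glycan**: residue counts over four monosaccharide classes — Hex
  (glucose/galactose), HexNAc (GlcNAc/GalNAc), NeuAc (sialic acid) and dHex
  (fucose). Residue compositions are the *dehydrated* forms (Hex C6H10O5,
  HexNAc C8H13NO5, NeuAc C11H17NO8, dHex C6H10O4), i.e. the mass added per
  glycosidic bond, so the headgroup mass is a plain sum and attaching it to
  a ceramide needs no further water correction. Glc/Gal and GlcNAc/GalNAc
  are mass-degenerate, so only class counts are stored; structural identity
  (which the mass spectrometer cannot see) is an annotation.
* **ceramide**: a sphingoid base (default d18:1 sphingosine, C18H37NO2,
  the dominant base in human GSLs) amide-linked to a fatty acyl chain `c:d`
  with free-acid composition C~c~H~2c−2d~O2, minus one H2O for the amide
  bond. d18:1/16:0 is C34H67NO3 (537.5121 Da).

In negative-mode electrospray the sialic acids deprotonate, so the charge
state is tied to the NeuAc count: one NeuAc gives `[M−H]⁻` (z = 1), two or
more give `[M−2H]²⁻` (z = 2). The precursor set-mass is

$$Q1 = \frac{M - z \cdot 1.00727646}{z}$$

with the proton mass 1.00727646 Da and the electron mass neglected — a
0.00055 Da/charge simplification invisible at the one-decimal reporting
used throughout. Collision-induced dissociation of any sialylated species
releases the sialic-acid residue anion, `[NeuAc−H2O−H]⁻` at 290.0881
(nominal m/z 290), which is therefore used as the single common product
ion: Q3 is species-independent, and selectivity comes from Q1 plus LC
retention.

### Rounding conventions

Reported m/z values are rounded to one decimal (`round_mz()`), matching
how such tables are printed. The *nominal* (unit-resolution) value
(`nominal_mz()`) is the one-decimal value rounded half-up: the infusion
spectrum of GD1a (d18:1/18:0) has exact Q1 917.4788, reported 917.5,
nominal 918. Rounding the exact value directly to an integer would give
917 and would not match how unit-resolution spectra are labeled.

## The transition grid

`transition_config()` bundles the enumerable world: the glycan catalog, the
fatty-acyl list, the sphingoid base, a CE lookup keyed by NeuAc count, the
common Q3, source-parameter placeholders and the retention-time window.
`build_transitions()` emits one transition per (glycan, acyl) pair in
deterministic order (catalog-major, acyl-minor).

The default catalog holds 10 acidic glycans: GM3 (Hex2 NeuAc1), GM2
(Hex2 HexNAc1 NeuAc1), GM1 (Hex3 HexNAc1 NeuAc1), GD1a
(Hex3 HexNAc1 NeuAc2), MSGb5 (Hex4 HexNAc1 NeuAc1), DSGb5
(Hex4 HexNAc1 NeuAc2), DSLc4 (Hex3 HexNAc1 NeuAc2), GalNAcDSLc4
(Hex3 HexNAc2 NeuAc2), DUPAN-2 (Hex3 HexNAc1 NeuAc1) and CA19-9
(Hex3 HexNAc1 NeuAc1 dHex1). The DUPAN-2 and CA19-9 counts follow the
standard antigen definitions and are flagged as assumptions in the shipped
catalog file. Two isomeric pairs exist by construction — GD1a/DSLc4 and
GM1/DUPAN-2 share residue counts, hence masses, for every ceramide. They
are kept as distinct analytes (LC retention resolves them), deliberately
producing duplicate (Q1, Q3) pairs annotated by a shared `isomer_group`
label.

The default fatty-acyl list is a *reconstruction*: the exact published
24-chain list is not available, so the package ships 24 chains preserving
the published count and C14–C30 range — even saturated 14:0–30:0 (9), odd
saturated 15:0–29:0 (8) and monounsaturated 16:1–28:1 (7), the chain types
actually observed in mammalian ceramides. Likewise, the optimized CE/DP/CXP
values are unpublished; the shipped CE values (50 V for 1 NeuAc, 40 V for
2, reflecting that doubly charged precursors fragment at lower energy) are
placeholders keyed by the stated dependency (NeuAc count). Both are plain
text config and fully overridable; none of the acceptance-grade mass
arithmetic depends on them. Retention windows default to the full 0–45 min
gradient because per-analyte retention times are not published.

## Peak integration

The vendor integration algorithm is unpublished, so the package uses the
simplest defensible stand-in, testable against closed forms: within a
user-supplied window, the apex is the intensity maximum; the baseline is
the straight line through the local intensity minima nearest each window
edge (falling back to the edge points on monotone flanks); the area is the
trapezoidal integral of the baseline-subtracted, zero-clamped trace. A peak
is *not detected* when its baseline-corrected apex height falls below 3×
the median absolute deviation of the out-of-window trace (all three
choices — trapezoid, edge-minimum baseline, 3×MAD floor — are parameters,
not claims about the vendor algorithm). On noise-free Gaussians the
integrator recovers $A\sigma\sqrt{2\pi}$ to well under 1% (2% on sloped
baselines); a known limitation is that a strongly drifting baseline
inflates the MAD noise estimate and hence the detection floor, since the
out-of-window trace is not detrended.

Not-detected cells propagate through `peak_area_table` as markers, never as
zeros: `area_ratio_table()` returns `NA` (undefined) where the denominator
is ND or zero, so ratios are never silently inflated. Ratios are reported
at 3 significant figures (hence the mixed 459 / 96.4 style), recovery at
its conventional two decimals.

### Matrix factor

The source formula's fraction bar is typographically ambiguous. The default
follows standard bioanalytical practice,

$$MF\% = 100 \cdot \frac{A_{spiked} - A_{matrix}}{A_{standard}},$$

which is 100% for exactly additive spiking and 0% for complete ionization
suppression and is invariant to common scaling of all three areas. The
alternate reading $100\,(A_{spiked}-A_{standard})/A_{matrix}$ is selectable
by the `formula` argument; the single published percentage cannot
distinguish the two without the underlying raw areas.

## Biomarker evaluation

Urinary intensities are divided by urinary creatinine to normalize urine
dilution (`creatinine_correct()`, a plain unit divisor). The two-group test
is Mann–Whitney U, chosen because semi-quantitative intensities are
non-negative and right-skewed and no normality claim is warranted: exact
p by enumeration of all label arrangements when both groups have ≤ 10
observations, otherwise the normal approximation with tie correction; a
Welch t-test is available by flag. ROC orientation is fixed to "elevated
marker ⇒ case", the direction of the effect under study. The AUC is
computed by pair counting, `(concordant + 0.5·tied)/(n₁n₂)`, which equals
the trapezoidal area under the empirical curve exactly and equals
U/(n₁n₂) — both identities are asserted on random inputs in the test
suite as a dual-route check. The Youden-optimal cutoff breaks ties toward
higher specificity. Because a point AUC from a small cohort is fragile, a
stratified bootstrap CI (2000 seeded resamples by default) is reported
alongside it.

## What the simulators emulate — and what they don't

`simulate_chromatogram()` produces a Gaussian peak on a linear baseline
with seeded Gaussian noise, clamped at zero, on a 0.01-min grid over the
0–45 min gradient (≈ the dwell cycling of a few-hundred-transition SRM
method). Default peak width 0.05 min (~7 s FWHM) is a typical UHPLC peak.
It does *not* model Poisson ion statistics, retention drift, tailing,
carryover or co-elution — so a green integrator test establishes correct
arithmetic on well-formed peaks, not robustness to pathological
chromatography.

`simulate_cohort()` draws control creatinine-corrected intensities from
lognormal(μ, σ) and cases from lognormal(μ + ln FC, σ) — a pure
multiplicative shift, the natural model for non-negative, right-skewed
semi-quantitative data. Creatinine is an independent lognormal and the raw
intensity is stored as corrected × creatinine, so creatinine correction
recovers the generative value exactly; the theoretical AUC of the model is
the binormal closed form $\Phi(\ln FC / (\sigma\sqrt2))$, the oracle the
empirical AUC is tested against. Defaults state the emulated world once:
fold change 5 (the elevated-marker effect size observed in conditioned
tumor-cell medium), σ = 0.5 (~65% geometric CV), 50 subjects per group
(the property-test scenario; real cohort sizes are unpublished),
creatinine around 100 mg/dL. Real urine brings age/sex structure,
measurement truncation at the detection floor, and non-independent
creatinine — none of which are modeled, so a green cohort test validates
the statistics pipeline, not clinical performance.

## Numerical and design choices

* Atomic monoisotopic masses: C = 12 (exact), H = 1.00782503,
  N = 14.00307401, O = 15.99491462; mass additivity holds to < 1e−9 Da.
* Published figures of merit (linearity r = 0.99937, recoveries, MF = 106%,
  urinary AUC = 0.8810, detected/ND tallies) depend on raw data that were
  never deposited; the package therefore reproduces the *mass arithmetic
  and ratio table* exactly and covers the rest with property-based tests
  (closed-form Gaussian recovery, MF endpoints, AUC identities, seeded
  parameter recovery at fold change 5).
* mzML support is a minimal chromatogram-list reader/writer (64-bit float,
  none/zlib) built on `xml2`, because no mzML library exists in the target
  R stack; spectra and indexed mzML are out of scope.
* All generators are seed-deterministic; identical specs give bit-identical
  output.
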