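---
title: "Growth phenotypes, cofactor remediation, and stability thresholds for CBS variants"
author: "cbscofactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth phenotypes, cofactor remediation, and stability thresholds for CBS variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbscofactor)
```

## The assay and the data model

Human cystathionine β-synthase (CBS) consumes homocysteine in the
trans-sulfuration pathway and needs two cofactors: pyridoxal
5′-phosphate (PLP, the active form of vitamin B6) and heme. A yeast
strain deleted for *CYS4*, the CBS ortholog, grows on minimal medium
only when a functional human CBS allele complements it, which turns
growth rate into a quantitative readout of enzyme function. Because the
medium's pyridoxine content can be titrated — and, in a *hem1Δ*
background, intracellular heme can be set through δ-aminolevulinate
(δ-ALA) supplementation — the same readout also measures how much a
variant's deficit is remediated by extra cofactor.

`cbscofactor` models this assay end to end. A `VariantPanel` holds one
record per single amino-acid substitution (token such as `I278T`,
NP_000062 numbering, an optional Rosetta ΔΔG prediction in kcal/mol, a
phenotype category) together with long-format per-condition relative
growth rates. Two bundled panels transcribe the published tables: the
58-substitution pyridoxine titration in the HEM1 background and the
9-variant pyridoxine × δ-ALA titration in *hem1Δ*. Both load with all
invariants checked; `validatePanel()` reports violations as data so
broken inputs stay inspectable.

```{r}
panel <- loadTable1()
panel
```

## Growth-rate estimation

Raw kinetic OD~595~ reads (one per well every 30 min for 72–96 h,
starting near OD 0.01) are processed in four steps:

1. **Endpoint normalization** — each well's trace is rescaled so its
   final read equals the endpoint read taken after resuspension. This
   per-well scaling cancels any multiplicative gain. A well whose final
   kinetic read is not positive cannot be scaled; in batch mode such
   dead wells are reported as window-not-attained.
2. **Log-transform and windowed slope** — normalized ODs are log10
   transformed and the growth rate is the least-squares slope over all
   reads inside a fixed density window, inclusive at both bounds:
   OD 0.05–0.1 for HEM1 strains and 0.1–0.2 for *hem1Δ* strains (the
   higher window reflects the slower, later-rising *hem1Δ* curves).
   OLS over all in-window points is used rather than a two-point
   difference because it uses every read and damps read noise; the
   two-point slope remains available (`method = "two_point"`) for
   sensitivity analysis, and the two coincide exactly when only two
   reads fall inside. Fewer than two in-window reads means the window
   was not attained and no rate is reported — that state, not an error,
   is what ultimately renders as "n/d".
3. **Plate normalization** — each plate's factor is the grand mean of
   the major-allele (reference) rates across plates divided by that
   plate's reference mean, applied multiplicatively to every rate on
   the plate. No formula is published for this step; anchoring to the
   reference strain is chosen because it preserves the convention that
   the major allele's relative rate is 1 and makes reference plate
   means exactly equal after correction.
4. **Relative rate** — every variant rate divided by the per-condition
   reference mean, then summarized over replicate transformants
   (mean, SD, n).

On a noise-free exponential the recovered rate equals the generating
rate to better than 1e−9 regardless of window choice, and a uniform
plate gain cancels exactly. With the default synthetic noise
(additive SD 0.005 OD) a variant at 60% of the reference rate is
recovered from three replicate wells with a median absolute relative
error of about 4%.

## Phenotype categories and cofactor sensitivity

Variants fall in three categories. *Nonfunctional*: no growth at the
highest pyridoxine dose (400 ng/mL). *Sensitive*: growth, but a
relative rate significantly different from the major allele at one or
more doses. *Benign*: growth with no significant difference anywhere.
Significance uses a two-sided Welch (unequal-variance) two-sample
t-test on replicate values with the published cuts, P < 0.01 (`*`) and
P < 0.001 (`**`). Welch is chosen because replicate counts are small
(three transformants) and the printed SDs are visibly unequal; at
n = 3 vs 3 the Satterthwaite approximation is conservative, so the
realized type-I rate at the 0.01 cut sits below 1% — flags err toward
caution. When both samples are constant the p-value is 1 for equal
means and 0 otherwise, by convention.

For the bundled tables no raw replicates exist, so `classifyPanel()`
treats the printed flags as authoritative (direction from the sign of
rate − 1); `classifyFromReplicates()` recomputes flags from
replicate-level ratios and is exercised on synthetic data. A sensitive
variant is *faster than wild type* only if every flagged condition
points faster; on the bundled panel this yields exactly I127V, I188V
and V371A.

Dual-cofactor sensitivity is read off the *hem1Δ* table at high
pyridoxine and low δ-ALA (400 ng/mL, 5 µg/mL): a variant is called
dually sensitive when its relative rate there is absent or below a
floor of 0.1. The floor operationalizes "extremely sensitive": the two
known dual responders sit at n/d (K267E) and 0.07 (L345P), while the
next smallest value in that column is 0.58, so any floor in
(0.07, 0.58] separates them; 0.1 is used and is an argument.

Heme incorporation of a purified protein is summarized by
`hemeSaturation()`, the 430 nm/280 nm absorbance ratio clipped to
[0, 1] under the one-to-one calibration at which the major-allele
protein is fully loaded.

## Structural features

Five per-residue characteristics feed the association analysis:

- **Distance to heme / to PLP** — minimum Euclidean distance over all
  (residue heavy atom, ligand heavy atom) pairs. The metric is not
  specified in print; minimum heavy-atom distance is the field default.
  CBS is oligomeric, so all chains' ligand copies are searched by
  default, with `scope = "same_chain"` for monomer-level analysis.
- **Relative solvent accessibility** — Shrake–Rupley rolling-probe
  area (probe 1.4 Å, 960 points per atom), summed over the residue and
  divided by the Tien et al. theoretical tripeptide maximum for its
  type. The sphere lattice is anchored to a molecule-fixed local frame
  built from each atom's nearest neighbors, which makes the
  discretized area exactly invariant under rigid-body motion instead
  of only approximately so. An isolated atom reproduces the closed
  form 4π(r + probe)² to well under 1% at 960 points. Residues with
  RSA ≤ 0.05 are considered buried; downstream use is rank- and
  threshold-based, so the choice of reference set is not critical.
- **Regular secondary structure** — HELIX/SHEET records when the file
  has them; otherwise a backbone-dihedral fallback (helix:
  φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°]; strand: φ ∈ [−180°, −80°] with
  ψ ∈ [80°, 180°] or [−180°, −170°]), keeping runs of ≥ 3 residues.
  This is deliberately not a DSSP reimplementation.
- **B-factor** — unweighted mean over the residue's heavy atoms.

Structures are read from PDB files via `bio3d`; hydrogens are dropped,
alternate locations resolve to the highest-occupancy conformer, and
insertion codes are rejected. File numbering maps to NP_000062
numbering through an explicit integer offset rather than an alignment
— deterministic and auditable. No specific deposited structure is
assumed; any CBS model can be supplied, and the test surface uses
synthetic helices. On the bundled panel, any model covering the
ΔΔG-predicted span maps 44 distinct mutated residues and leaves the 7
substitutions outside the solved structure unmapped. (The bundled
table's caption places those 7 in the N-terminal region, but their
positions, 408–559, are C-terminal; the package follows the rows.)

## The randomization analysis

Alleles are grouped by phenotype — optionally crossed with construction
method (directed vs random; six groups) — and each group's mean of each
feature is compared with an empirical null built by randomly
reassigning alleles to groups 10,000 times, preserving group sizes.
One reassignment is shared across all groups and features, so the
covariance among the five measurements is preserved. Both one-sided
tails are reported with the add-one correction,
p_high = (1 + #{null ≥ observed})/(n_perm + 1), making the smallest
attainable p equal to 1/(n_perm + 1). No multiplicity correction is
applied by default, matching the published analysis, which reported
none. `exhaustiveTest()` enumerates all assignments exactly for small
instances and serves as the oracle; the sampled test converges to it
within binomial Monte-Carlo bounds. Construction labels are not
printed for the bundled variants, so the six-group design runs only on
synthetic panels; the published solvent-accessibility associations
carry no printed p-values or feature values, so this module's
correctness is established by properties (exact-oracle agreement,
null uniformity, planted-shift power) rather than value reproduction.

## The ΔΔG threshold sweep

For the alleles with a prediction, a cutoff t classifies correctly the
growing alleles with ΔΔG < t plus the non-growing alleles with
ΔΔG ≥ t ("below" strict, "above" inclusive; the 0.5 kcal/mol grid is
offset from the one-decimal predictions, so the convention rarely
binds). `thresholdSweep()` evaluates the grid and reports the argmax,
resolving ties to the smallest cutoff (the most inclusive impaired
class). The bundled panel has 51 records with predictions (58 minus 7
n/a); the published scatter counts 52 alleles, a discrepancy that
cannot be resolved from the text, so the package reports the
fixture-derived count rather than asserting either number.

```{r}
thresholdSweep(panel)
```

All 11 scored alleles above 4 kcal/mol are impaired (9 nonfunctional,
2 sensitive), and the sweep peaks at the 3.5 kcal/mol grid point —
consistent with a functional-impairment threshold in the 3.5–4
kcal/mol band.

## The synthetic generators

No raw plate-reader curves are deposited, so `simulateCurve()` emulates
them: a lagged logistic trajectory (default start OD 0.01, capacity
1.0, rate 0.05 log10/h, lag 5 h, reads every 0.5 h for 84 h) with
additive Gaussian read noise (SD 0.005 OD, floored at 0) and an
optional multiplicative plate gain on the kinetic reads only; the
endpoint read is the noise-free final density. The defaults mirror the
stated assay conditions; the rate and lag are chosen as realistic for
slow growth on minimal medium without shaking. Additive noise is used
because plate-reader noise is approximately signal-independent at low
OD. A logistic-with-lag was chosen because only the windowed slope
matters downstream and logistic curves traverse both density windows;
`carrying_capacity = Inf` degenerates to the exact exponential used in
closed-form tests. `simulatePanel()` assembles whole panels (default:
58 alleles in 19/14/25 proportions, three replicate plates,
major-allele wells on every plate and dose) with sensitive-allele true
ratios declining monotonically across the discrete doses — the assay
design has no dose–response model, so none is imposed — plus a
true-parameter ledger sufficient to score every downstream estimate.
`simulateStructure()` writes an ideal poly-alanine helix (φ = −57°,
ψ = −47°, built from standard internal coordinates) with planted
single-atom HEM and PLP ligands as a PDB file.

What the generators do *not* emulate: evaporation and edge-well
effects, signal-dependent noise, condensation artifacts, diauxic
shifts, or real protein geometry beyond an ideal helix. Passing the
recovery and association tests therefore shows the estimators are
correct for curves with the assumed structure, not that the assay
itself is free of systematic error.

## Numerical choices and degenerate inputs

- Window membership is inclusive at both bounds; non-positive ODs are
  dropped before the log transform with a warning.
- A dead well (final kinetic read ≤ 0) cannot be endpoint-normalized:
  an error for a single curve, reported as not-attained in batch mode.
  With default noise a flat well can occasionally scatter reads into
  the density window after normalization inflates its noise; such
  spurious well-level rates are rare and are absorbed at the replicate
  aggregation stage.
- Permutation p-values use the add-one correction and a relative
  tie tolerance of 1e−12 when comparing null means to the observed
  mean.
- Ties at the sweep argmax go to the smallest threshold.
- The category allocation of synthetic panels uses floor() with a tiny
  epsilon so exact proportions survive floating-point division.

Test problem sizes: recovery uses 100 replicate simulations of
three-well pairs; null-uniformity uses 300–500 whole-test repetitions
at n_perm ≈ 500; power uses 60–100 repetitions at n_perm = 999; the
structural suite uses helices of 12–321 residues with 120–960 sphere
points. These sizes give stable Monte-Carlo margins while keeping the
default suite fast.

## Limitations

ΔΔG values are consumed as inputs; the package does not compute
stability predictions. The t-test contract for recomputation mode
(Welch on replicate ratios) is one admissible reading of "pair-wise
t test" and is validated only on synthetic data, as is the per-well
endpoint normalization. Secondary-structure fallback is a
dihedral-window heuristic, not DSSP. The bundled growth rates are
experimental measurements transcribed as fixtures — the package
classifies and analyzes them but cannot re-derive them.
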