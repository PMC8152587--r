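---
title: "Methods: multi-label functional-group prediction from FTIR and EI-MS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-label functional-group prediction from FTIR and EI-MS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A molecule's functional groups — carbonyls, nitriles, aromatic rings, and
so on — determine its reactivity and leave characteristic fingerprints in
two cheap, fast measurements: the mid-infrared absorption spectrum (FTIR)
and the electron-ionisation mass spectrum (EI-MS). `specfg` treats the
assignment of a molecule's *set* of functional groups from these two
spectra as a single multi-label classification problem: one model, one
sigmoid output per group, every group decided simultaneously. This differs
from rule-based peak matching (which needs curated correlation tables) and
from per-group binary classifiers (which are sensitive to class imbalance
and cannot share representation across groups).

# Spectral standardization

**FTIR.** Instruments record transmittance (or absorbance) at
instrument-specific wavenumber samplings. We standardize to a fixed grid of
half-open bins, by default 400–4000 cm⁻¹ at 4 cm⁻¹ (900 bins) — the span of
routine mid-IR benches at a common instrument resolution; both are
configurable. Absorbance is converted to transmittance (T = 10^−A) first,
because all downstream normalization is defined on the transmittance
scale. Each bin covered by data receives the mean of its in-bin ordinates;
the covered means are then min–max normalized to [0, 1]. Bins that lie
*inside* the recorded range but received no sample are filled with a cubic
interpolating spline evaluated at the bin centers and clipped to [0, 1]
(linear interpolation, with a warning, when fewer than 4 bins support the
fit). Bins *outside* the recorded range are set to 1.0 — the physical
full-transmittance baseline, not 0, which would look like total absorption.

One ordering choice matters: normalization is applied to the *binned
means*, not to the raw ordinates. Normalizing first and binning second can
leave the binned minimum above 0, so that a second pass through the
pipeline would re-stretch the values; with the order used here
standardization is idempotent bin-for-bin, which the tests assert.

**EI-MS.** Unit-resolution abundances are summed into integer m/z bins
(1–650 by default; fractional m/z values are floored, a convention the
printed "1 m/z resolution" of typical reference data leaves open), scaled
so the base peak equals 1.0, with no interpolation — a mass spectrum is a
discrete fragment population, and inventing intensity between observed
fragments has no physical meaning. Constant spectra map to 1.0 everywhere
(max = min convention); an all-zero mass spectrum is an error, since no
base peak exists.

In combined mode the feature vector is the concatenation [FTIR ‖ MS]
(900 + 650 = 1550 features), with named blocks retained so downstream
tools (e.g. saliency maps) can address each technique's range.

# Label assignment

Ground truth comes from the molecular structure, not the spectrum: each
functional-group definition is a SMARTS pattern matched independently
against the molecule (OpenBabel via ChemmineOB; structures given as SMILES
or InChI). A molecule therefore carries as many labels as patterns that
match, and a molecule matching none keeps an all-zero label rather than
being dropped — spectra of such compounds are still legitimate negative
evidence. Two catalogues ship with the package: the original 13 groups,
and an extended 16-group set in which the alkane definition is narrowed to
`[CX4;H0,H1,H2]` (excluding methyl carbons) and ether, nitro and methyl are
added.

Two definitional subtleties are worth recording. First, the alkene
definition is genuinely ambiguous in its printed source; the package
defaults to the chemically standard `[CX3]=[CX3]` (alkene carbons are
three-connected) and exposes the literal two-connected reading
`[$([CX2]=[X2])]` behind `alkene_variant = "two_connected"` — the two
differ only on cumulated double-bond systems, and the package refuses to
silently collapse the choice. Second, SMARTS hydrogen-count semantics are
strict: `[CHX4]` means *exactly one* hydrogen, so the alcohol pattern
`[CHX4][OX2H]` matches isopropanol but not ethanol. This is the behaviour
of every major substructure engine and the package follows it; the test
suite freezes label sets verified against two independent engines. An
optional aldehyde group (`[CX3H1](=O)[#6]`, default off) is available for
users extending the catalogue.

Mixtures are labeled by the union (element-wise OR) of the component
molecules' label vectors; a *measured* mixture spectrum is scored like any
single spectrum — the union applies to the truth, not the prediction.

# The classifier

The model is a feed-forward network: input → [dense → batch-norm → ReLU →
dropout] × 3 → dense → sigmoid, one output per group, trained with the
Adam optimizer on binary cross-entropy, which factorizes over groups and
therefore supports multi-label output natively. Defaults: hidden sizes
(512, 256, 128), dropout 0.3, learning rate 10⁻³, batch size 64, at most
50 epochs with early stopping (patience 5) on a 10% slice of the training
rows. These are the package's own desk-scale defaults — stated as
configuration, not as claims about any particular reference dataset.
Training is fully seeded: weight initialization, shuffling and dropout all
draw from one R RNG stream, so a (data, config) pair reproduces bitwise.

Numerical conventions: batch-norm uses ε = 10⁻⁵ and momentum 0.9 on
running statistics; batches of size 1 are skipped (batch statistics are
undefined); sigmoid outputs are clipped to [10⁻¹², 1 − 10⁻¹²] inside the
loss; a non-finite loss aborts with diagnostics rather than continuing.

**Dynamic thresholds.** A sigmoid score must be cut at some value to
declare a group present, and 0.5 is rarely optimal for imbalanced groups.
After training, each group receives the cutoff on the grid
0.01, 0.02, …, 0.99 that maximizes its F1 *on the training rows*, ties
broken toward the smallest threshold. The grid resolution and the
`score ≥ t` boundary convention are package choices made for exact
testability: the suite checks grid search against a brute-force scan over
every distinct cutpoint. By construction the optimized training F1 of
every group is at least its F1 at the fixed 0.5 cutoff. Groups absent from
the training labels keep 0.5, with a warning.

**Autoencoder variant.** A single-layer autoencoder (256-dimensional
rectified embedding, linear decoder, mean-squared error) can compress the
spectrum before classification. Inputs are centered by the training mean
spectrum, and the decoder bias starts at that mean: without centering, the
common baseline dominates every pre-activation, whole rectifier units
start dead, and the encoder can collapse onto the decoder bias (we
observed exactly this failure mode). The decoder-bias initialization also
makes the initial reconstruction error equal the variance baseline, so any
training progress is an improvement over predicting the mean — the
contract the tests assert on held-out rows. The encoder is fitted on the
pooled training folds only, so no validation spectra leak into the
representation used to evaluate validation metrics.

# Molecule-level metrics

Per-group precision/recall/F1 (pooled TP/FP/FN over molecules) describe
each group in isolation. For chemistry the molecule is the unit of
success, so two molecule-level metrics are used:

* **Molecular F1 (MF1)**: for one molecule, count TP/FP/FN over its
  groups; MF1 is the harmonic mean of molecular precision TP/(TP+FP) and
  molecular recall TP/(TP+FN). The validation summary is the arithmetic
  mean over molecules.
* **Molecular perfection rate (MPR)**: the fraction of molecules whose
  predicted set equals the true set exactly.

Edge conventions are chosen so that *perfection ⟺ MF1 = 1* holds
universally: two empty sets score 1.0 (correctly predicting "no groups"),
one empty set against a non-empty one scores 0.0. With any other
convention the equivalence breaks on group-free molecules. For per-group
F1, a group that neither occurs nor is predicted anywhere is reported as
1.0 with a `degenerate` flag, and as 0 whenever it occurs or fires but is
never correct. Fold aggregation is the arithmetic mean (± SD) of
fold-level metrics.

One documented discrepancy: the source worked example for a
five-group mixture quotes an MF1 of 0.65, which no (TP, FP, FN) reading of
its own truth/prediction table produces under the formula above (2 correct
of 3 predicted and 2 of 4 present gives 4/7 ≈ 0.57). The package
reproduces the two self-consistent worked examples (0.80 and 0.67) exactly
and treats the third as a typographical inconsistency.

# The accuracy-matched synthetic baseline

MPR necessarily decays as the catalogue grows, even when every individual
group is predicted well. The synthetic baseline makes this quantitative:
flip each group's truth bit independently with probability 1 − a_g.
Then a molecule is perfect only if all G bits are copied, so
E[MPR] = ∏ a_g — at a uniform 95% accuracy, 8 groups already cap MPR at
0.66. The symmetric bit-copy form is used because only per-group
accuracies parameterize it; an asymmetric (sensitivity, specificity)
variant is available for class-conditional error models. Tests verify the
empirical MPR against the product law within 3 binomial standard errors at
n = 10⁵ and its monotone decay in G.

# Guided backpropagation

To ask *where* the model looks, the gradient of the chosen group's
pre-sigmoid output with respect to the input is propagated with the guided
rule: at every rectifier, the gradient is zeroed where the unit was
inactive in the forward pass and where the incoming gradient is negative —
only evidence that increases the activation flows back. Batch-norm layers
are frozen affine maps (inference statistics). At the input, the absolute
value of the surviving gradient is taken: on transmittance spectra the
informative evidence is a *dip*, i.e. a negative input gradient, and its
magnitude is what localizes a band — keeping only positive input gradients
would discard precisely the absorption features (a failure we measured: 0
of 8 generator bands localized under the positive-only convention, 8 of 8
under the magnitude convention). In the degenerate rectifier-free linear
model the rule acts at the output unit instead, and the profile reduces to
the positive part of the group's weight row. Profiles are max-normalized
to 1 for cross-molecule comparability (raw magnitudes are also returned);
an identically zero gradient yields a flagged flat profile.

Exemplar molecules for saliency are chosen as in the interpretability
literature for this task: among validation molecules predicted perfectly
and containing the group, take the top-k by that output neuron's
activation.

# The synthetic generator

The generator emulates what the method needs from real reference data, at
band positions taken from standard FTIR correlation charts: alkane C–H
near 3000 cm⁻¹, arene ring modes at 1400–1600 cm⁻¹, the alkene bend near
900 cm⁻¹, C–O stretching near 1120–1150 cm⁻¹, carbonyl stretching near
1700 cm⁻¹, O–H near 3500 cm⁻¹, the nitrile band at 2210–2260 cm⁻¹, and
the twin nitro bands near 1520/1350 cm⁻¹. An FTIR curve is a unit baseline
minus one Gaussian dip per band of each present group (Gaussian rather
than Lorentzian line shapes — simpler and sufficient for testing; the
table is data, so shapes and positions are pluggable), plus Gaussian noise,
clipped to [0, 1]. The EI-MS side is a pseudo-molecular ion plus
group-characteristic fragments (absolute m/z or neutral losses from the
molecular ion) with log-normal abundance jitter; halide groups add the
M+2 isotope companion at a configurable ratio (default 0.32, the chlorine
signature). Groups are sampled independently at requested prevalences
(default 0.5); overlap between the nitro band at 1520 cm⁻¹ and the arene
ring mode at 1500 cm⁻¹ is deliberately retained as a realistic confound.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: band intensities do not depend on
concentration or neighbouring substituents; fragmentation is not
rearrangement chemistry; co-occurrence of groups is independent rather
than reflecting synthetic accessibility; and noise is white rather than
baseline-drifting. Results on the benchmark bound what the architecture
can recover under known conditions; they do not certify performance on
laboratory spectra.

**Benchmark conditions.** The package's standard benchmark generates
2 000 compounds over an 8-group catalogue (alkane, arene, alkene, ether,
carbonyl, alcohol, nitrile, nitro) at noise SD 0.02, evaluated under
5-fold cross-validation in combined FTIR+MS mode; the autoencoder parity
run uses the same data with a 256-dimensional code (20 encoder epochs).
These sizes keep a full run in the minutes range on a single CPU while
leaving every statistical margin comfortably testable; they are the sizes
the acceptance tests use.

# Known limitations

* SMARTS matching follows OpenBabel semantics; engines differ on rare
  constructs (tautomers, aromaticity perception of exotic rings), so a
  custom catalogue should be validated on the user's own structures.
* The JCAMP-DX reader supports the AFFN `XYDATA` and `PEAK TABLE`
  dialects; compressed ASDF encodings (SQZ/DIF/DUP) are rejected
  explicitly rather than parsed.
* Thresholds are optimized on training data; for small training sets they
  can overfit the training score distribution.
* Duplicate compound ids in a manifest keep the first spectrum; no attempt
  is made to merge replicate measurements.
* The random-forest comparison baseline is deliberately unoptimized
  (default ranger settings, one forest per group); it is a reference
  point, not a tuned competitor.
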