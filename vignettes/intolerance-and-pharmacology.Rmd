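---
title: "Methods: 3D missense tolerance ratios and GluD receptor quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D missense tolerance ratios and GluD receptor quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intol3d)
```

This vignette is the package's own account of its models, parameter
choices, numerical decisions and limitations. It states no empirical
result that the test suite or the acceptance script does not itself
compute.

# The missense tolerance ratio

## Model

For a set of codons, let `obs_mis`/`obs_syn` be observed missense and
synonymous variant counts from a population database, and
`exp_mis`/`exp_syn` the number of distinct single-nucleotide substitutions
of each codon that would be missense or synonymous under the standard
genetic code. The MTR is

$$\mathrm{MTR} \;=\;
\frac{\sum \mathrm{obs}_{mis} \,/\, (\sum \mathrm{obs}_{mis} + \sum \mathrm{obs}_{syn})}
     {\sum \mathrm{exp}_{mis} \,/\, (\sum \mathrm{exp}_{mis} + \sum \mathrm{exp}_{syn})}.$$

It equals 1 when the observed missense fraction matches the substitution
opportunity, and approaches 0 under missense depletion. Assumptions worth
stating plainly:

* **Unweighted expectations.** Each of the nine single-nucleotide
  substitutions of a codon counts equally. Mutation-rate context (CpG
  transitions, trinucleotide signatures) is deliberately not modeled; the
  `codon_counts` container keeps the per-codon expectation fields so a
  weighting hook could be added, but none is used.
* **Stop handling.** Stop-gaining substitutions are excluded from both
  expectation classes (the statistic is a missense-vs-synonymous
  contrast, and nonsense variants experience different selection).
  Consequently `exp_mis + exp_syn <= 9`, e.g. tryptophan's TGG has only 7
  countable substitutions. A terminal stop codon is trimmed from the CDS
  before accounting.
* **Undefined is not zero.** A window with no observed variants, or with
  zero expected missense fraction, has an *undefined* score (`NA`), which
  propagates as missing. Zero is reserved for the meaningful "fully
  depleted" outcome (variants observed, none missense).

## The 3D window

`knn_window()` takes the focal residue plus its `k - 1` nearest residues
by Euclidean distance between representative coordinates. "Window of 31"
is read as focal + 30 nearest; the paper-style figure legends leave
inclusivity unstated, so it is documented here and configurable.
Distance ties break by ascending `(chain_id, residue_number)`, making the
window deterministic. The representative coordinate is the C-alpha by
default; a side-chain-centroid mode exists because contact-mediated
constraint (e.g. at a ligand interface) is side-chain borne, with glycine
falling back to C-alpha. Residues without density are neither scored nor
used as neighbors.

On a uniformly spaced collinear structure the spatial window coincides
with the classic 1D sliding window, which the test suite asserts exactly;
the 3D construction is a strict generalization.

## Cross-gene projection, chain averaging, complexes

A gene is tied to structure residues by `map_gene_to_structure()`: either
identity (author numbering equals coding position) or through a global
Needleman–Wunsch alignment (BLOSUM62, gap open 11 / extend 1, Gotoh
affine recursion, deterministic diagonal-up-left tie-breaking). Scoring a
homolog on a better-resolved relative's structure is the same mechanism:
align the homolog's sequence to the chain sequence and project. Aligned
mismatches map; gap columns do not.

With several identical chains in a structure, each position receives the
unweighted arithmetic mean of its defined per-chain scores
(`average_chains()`), missing where no chain resolves it.

For protein–protein complexes (`score_complex()`), windows are taken over
the pooled residue cloud of all genes, so interface windows mix residues
from both proteins. By default the window's tallies are pooled across
genes — the interface is described by one joint intolerance surface —
because separated partners then reduce *exactly* to independent
single-protein runs (asserted at tolerance 0). A `pool = FALSE` flag
restricts tallies to the focal gene while keeping the spatial window;
whether the original analysis pooled denominators across genes is not
recoverable, so both are offered with pooled as default.

## Color scale and PDB export

`assign_colors()` maps scores piecewise-linearly blue → white → red with
anchors at track minimum / median / maximum by default (mirroring
per-structure scaling of published figures, whose exact anchors are not
recoverable — nothing downstream depends on them); a fixed mid anchor at
1.0 is available and the chosen policy is recorded in the output
attributes. Missing scores are grey. `write_bfactor_pdb()` writes
`100 * score` into the B-factor column (sentinel 999.00 for unscored
residues) and is tested to leave every other byte of the file untouched.

# Electrophysiology and pharmacology

## Difference current and percent-of-maximum

Constitutive activity is `I_NMDG − I_Na` (positive for inward Na⁺ leak);
an outward difference is returned signed, with a warning. A drug effect
is normalized as `100 (I_base − I_drug) / (I_base − I_NMDG)`: 100% is
full block to the NMDG⁺ floor, negative is potentiation. The quantity is
affine-invariant under common rescaling of the three currents and
undefined when baseline equals the NMDG⁺ current (no window to normalize
by).

## Hill fits

Activation: `R(%) = 100 / (1 + (EC50/[A])^nH)`; inhibition:
`R(%) = (100 − minimum) / (1 + ([C]/IC50)^nH) + minimum` with `minimum`
constrained to (0, 100), flagged when driven to the small positive lower
bound (1e-3%). Numerical choices:

* Midpoints are optimized as log10(molar) — group statistics are on
  logEC50/logIC50, and the likelihood surface is far better conditioned
  in log space.
* Least squares by L-BFGS-B from three starts spanning the tested
  concentration range (midpoint at the low end, center and high end of
  the ladder; nH starting at 1, minimum at 5%), followed by a tight
  polish. Non-convergence from every start is an error.
* 95% CI on the log midpoint from the Gauss–Newton curvature
  approximation at the optimum (vcov = 2 s² H⁻¹), or — when at least 5
  cells are present (`ci = "auto"`) — from the t-based spread of
  per-cell midpoints, since oocyte work reports n as cells. Both routes
  are explicit options; which was used is recorded in the fit object.
* A midpoint outside the tested span is flagged, not rejected.

Potency ratios follow the summary-table convention
`midpoint(reference) / midpoint(variant)` and are displayed at two
significant figures; reciprocal ratios multiply to 1 exactly. Censored
potencies (e.g. "> 10 mM") should not enter ratio arithmetic; the fitting
layer flags out-of-span midpoints for exactly this reason.

## Group comparisons

`compare_log_potency()` offers the two published testing schemes. The
Dunnett route runs a one-way ANOVA and then many-to-one comparisons
against the control with the exact joint null (common control term,
pooled error variance) evaluated by Monte-Carlo: 10⁵ draws of the
max-|T| statistic, fixed internal seed, caller RNG restored. No
multivariate-t quadrature library is assumed. The adjusted p is floored
at the unadjusted p so the monotonicity property holds despite MC noise.
The Welch–Bonferroni route is pairwise Welch t against the control with
multiplication by the number of comparisons (capped at 1), which also
handles degenerate n = 2 groups through the Welch df.

# Assay quantification

Surface expression: per-well OLS slopes of the linear nitrocefin
absorbance ramp (0–30 min, 1/min); the variant's
`mean(surface)/mean(total)` slope ratio is normalized to the same-plate
wild-type ratio (×100), with delta-method SEM from replicate spread over
all four means. Normalization is within-plate only — no cross-plate
batch correction is attempted.

Adhesion: Pₐ = events/contacts per bead–cell pair; the Wilson interval
is reported per pair (an addition — source figures show only means ± SEM
across pairs, and the between-pair SEM remains the plotted quantity).
Condition comparisons use one-way ANOVA + Tukey HSD on untransformed
frequencies (whether an arcsine transform was used originally is
unstated; untransformed is the default here), with the star tiers
0.05/0.01/0.001/0.0001.

# The synthetic world

The generators state the world the tests live in:

* **Structures**: ideal α-helix (rise 1.5 Å, radius 2.3 Å, 100°/residue),
  cubic lattice, two chains 50 Å apart (guaranteed separable), or a
  two-helix "complex" with axis separation 7 Å so surface residues
  approach within 8 Å. Geometry only needs to create meaningful 3D
  neighborhoods; it does not emulate real fold topology, so a green test
  says the *statistic* behaves, not that a real structure was
  reproduced.
* **Variant counts**: `obs_syn ~ Poisson(rate · exp_syn)`,
  `obs_mis ~ Poisson(rate · exp_mis · d)` with depletion factor `d` on a
  chosen patch. The default `baseline_rate = 0.5` observations per
  possible substitution was chosen once: it gives a k = 31 window on the
  order of 10² observed variants, enough that the null track
  concentrates near 1 (large population cohorts resolve comparable
  per-window counts for well-covered genes), while leaving visible
  sampling noise. Poisson is the simplest model consistent with
  rare-variant tallies; real data are overdispersed and
  mutation-rate-heterogeneous, which this generator does not emulate.
* **Dose-response**: the Hill forward models plus i.i.d. Gaussian noise
  (default SD 3% of maximum, per-point), 3 cells, ladders spanning the
  midpoint; reference currents consistent with a 1300 nA difference
  current (the scale of a strongly constitutive variant). Real recordings
  add rundown, series-resistance and solution-exchange artifacts that are
  out of scope.
* **Plate/adhesion**: linear ramps + Gaussian noise; Bernoulli contacts.

Every generator runs in a private RNG stream (seed in, caller state out),
and identical seeds give byte-identical files — asserted in the suite.

# Acceptance targets and tolerances

`scripts/acceptance.R` regenerates three midpoint-recovery quantities at
the published potency values (d-serine EC50 360 μM, nH 1.3, 8-point
ladder 3 μM–30 mM; pentamidine IC50 9.6 μM and 36 nM, nH 1, minimum 5%,
9-point ladders), three replicate curves at 3% noise, derived seeds
`seed`, `seed+1`, `seed+2`. For the T649A pentamidine potency the
abstract's rounded "50 nM" conflicts with the table value 0.036 μM; the
table value is used. The recovery estimator is unbiased, but at the
prescribed design roughly one seed in eight lands outside 10% of the
generating value for the three-parameter inhibition fits — that spread is
a property of the stated world and is left as measured.

# Known limitations

* No mutation-rate weighting of expectations, no VCF consequence calling,
  no transcript-model selection.
* PDB parsing is first-model, ATOM-record only (HETATM ignored for
  sites); no mmCIF, symmetry expansion, or superposition.
* MTR tracks carry no significance/FDR machinery.
* Hill CIs are asymptotic (curvature) or per-cell t; profile-likelihood
  intervals are not implemented.
* No raw-trace processing (leak subtraction, filtering) — inputs are
  steady-state currents; no force-trace signal processing for the
  adhesion assay.
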