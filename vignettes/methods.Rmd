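---
title: "Methods: ensemble statistics for polyglutamine peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble statistics for polyglutamine peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqconf)
```

`polyqconf` characterises conformational ensembles of polyglutamine (polyQ)
and polyQ–polyproline peptides. This vignette documents the statistical
models, the tunable parameters and their defaults, the numerical choices, and
what the synthetic generator does and does not emulate.

## Data model

A `conformation_ensemble` stores, per conformation and residue, the backbone
dihedrals φ, ψ, ω in degrees within (−180, 180], plus optional backbone
coordinates (N, CA, C, O; Å). Undefined angles — φ of the first residue, ψ
and ω of the last — are `NA`, and every statistic excludes undefined cells
from its denominator rather than imputing them. The ω stored at residue *i*
is the peptide-bond torsion CA(i)–C(i)–N(i+1)–CA(i+1); the prolyl bond
preceding a proline at position *j* is therefore `omega[, j − 1]`. Torsions
follow the IUPAC sign convention (an ideal right-handed α-helix reads
φ ≈ −57°). Residue indices are 1-based in all user-facing input and output.

## Ramachandran regions

Four regions partition the (φ, ψ) torus. The default half-open rectangles are

| region | φ interval | ψ interval |
|---|---|---|
| αR | [−180, 0) | [−120, +50) |
| αL | [0, +180) | [−50, +120) |
| PPII | [−110, 0) | [+50, +180) ∪ [−180, −120) |
| β | [−180, −110) | [+50, +180) ∪ [−180, −120) |

with canonical centers αR(−63, −43), αL(+57, +47), PPII(−75, +150),
β(−140, +150). Points outside every rectangle take the region of the nearest
canonical center under wrapped Euclidean distance, so the assignment is
always a full partition (region percentages sum to 100). The rectangles and
centers are standard Zimmerman-style basins and can be overridden through
`region_boundaries()`.

Because real basins overlap at the hard borders, `assign_regions_cluster()`
offers a data-driven alternative: per residue, the defined (φ, ψ) points are
binned on the torus (default 5° bins; the bin width must divide 360) and
partitioned by wrapped k-means with k = 4 seeded at the canonical centers.
Circular means update the centroids; iteration stops when assignments are
stable (at most 100 iterations), so the procedure is deterministic given the
data. Final clusters are re-identified by their nearest canonical center.
Two degenerate situations fall back to hard assignment: fewer than 100
defined pairs in the whole ensemble (too little data to cluster), and two
clusters re-identifying to the same canonical center for a residue (the
four-basin model does not describe that residue's density; this happens, for
instance, when one basin's mass is split across two clusters). Residues
preceding prolines receive no special treatment — the data decide.

An **α̃ repeat** is two adjacent residues whose labels alternate between αR
and αL in either order; an α̃ strand is a maximal strictly alternating run.
Terminal residues use their single neighbour; `NA` neighbours never match.

## Secondary structure and motifs

Hydrogen bonds use the Kabsch–Sander electrostatic proxy
E = 0.084 · 332 · (1/r~ON~ + 1/r~CH~ − 1/r~OH~ − 1/r~CN~) kcal/mol, with a
bond declared below −0.5 kcal/mol, donors at least two residues from
acceptors, amide hydrogens placed 1.0 Å from N opposite the preceding C=O
(first residue and prolines have none), and distances floored at 0.5 Å
(floored pairs are flagged and never bonded). Missing carbonyl oxygens —
e.g. for ensembles built from dihedral tables — are rebuilt with ideal
geometry.

The DSSP subset is re-implemented rather than wrapped so that synthetic and
dihedral-only ensembles go through exactly the same code path as PDB input.
n-turns (i → i+3, 4, 5 bonds) produce G/H/I by the standard
two-consecutive-turn rule; remaining bracketed residues are T; bends (S) mark
a direction change above 70° between CA(i−2)→CA(i) and CA(i)→CA(i+2);
parallel and antiparallel bridges follow the standard patterns, with ladder
residues E and isolated bridges B. Code priority is H > E > I > G > B > T >
S > C. π-helices beyond the I code and chirality flags are not needed for
these analyses and are omitted.

Motifs are defined on top of labels and H-bonds:

* **β strand / PPII run**: a maximal constant-label run of length ≥ 3 (a
  stricter ≥ 4 variant is always reported alongside, as the two definitions
  bracket the printed populations).
* **α̃ strand**: a maximal alternating αR/αL run, same length variants.
* **isolated** strand: no residue of the run participates in any backbone
  hydrogen bond. For dihedral-only ensembles without reconstructed
  coordinates, isolation is `NA` rather than guessed.
* **hairpin**: two successive same-kind strands separated by a connector of
  1–8 residues containing at least one turn- or bend-coded residue and no
  third strand, with at least one hydrogen bond linking the two strands. The
  connector cap (`max_loop = 8`, settable to `Inf`) exists because unbounded
  connectors let distant strand pairs in collapsed globules register as
  hairpins; both H-bonded turns and plain bends are accepted in the
  connector.
* **turns**: an i → i+3 bond is a β-turn (type I when both middle residues
  are αR, otherwise "other"); an i → i+2 bond is a γ-turn; S-coded residues
  without a turn bond are bends.

Motif prevalence is the percentage of conformations containing at least one
instance entirely inside the polyQ portion (spans touching prolines are
excluded), which is deliberately not a per-residue average: rare extended
motifs are better summarised by how many conformations contain one at all.

## Odds-ratio correlation profiles

For a binary residue property X (region membership via `region_mask()`, or
α̃-repeat membership via `alpha_tilde_mask()`), the association of residues i
and i+r is the odds ratio OR = (n~00~·n~11~)/(n~01~·n~10~) of the 2×2 table,
mapped to a free-energy-like score k~B~T·ln OR (0.5962 kcal/mol per ln-unit
at the default 300 K) with asymptotic standard error k~B~T·√(Σ 1/n~xy~).
Positive scores mean positive association. Zero cells receive the
Haldane–Anscombe +0.5 correction (flagged in the output); without correction
a zero cell is an error in `delta_delta_g()` and ±∞/0 in `odds_ratio()`.

Profiles pool one table per separation r over all eligible pairs (i, i+r)
and conformations; conformations are treated as independent samples, which
matches ensembles subsampled at a fixed rate from equilibrium simulations.
Inverse-variance-weighted per-pair averaging is available
(`pooling = "per_pair"`) as a sensitivity check; pooling is the default
because single pairs at large r have sparse tables. To reduce end effects,
`trim` residues are dropped at each end before forming pairs — by default 5
for chains of at least 30 residues and 2 for shorter chains. Only glutamine
columns enter a profile when residue names are supplied.

The Pearson ψ profile cross-checks the OR route on the raw angles: ψ is
shifted by +100° under periodic boundary conditions — placing the wrap point
in the sparsely populated band between the αL and PPII basins so that the
linear correlation is not destroyed by wrap-around — and the pooled Pearson
correlation of (ψ′~i~, ψ′~i+r~) uses the same trimming.

Two diagnostics summarise a profile. `dominant_period()` linearly detrends
the values over r ≥ 2, computes a 4× zero-padded periodogram, and returns the
maximising period within [3, r~max~/2] together with its fraction of total
power (a flat profile yields a small fraction; the caller judges
significance). `long_range_flag()` raises its flag when |mean value over
r ≥ 10| exceeds twice the mean standard error over the same tail. The
magnitude is used deliberately: the score is a convex function of the
underlying latent correlation when one region dominates the marginals, so an
oscillating long-range correlation produces deeper troughs than peaks and a
signed tail mean can sit near zero even when the profile visibly fails to
decay. A two-sided criterion operationalises "does not decay to zero"
robustly; the signed tail mean is reported alongside for interpretation.

## Radius of gyration

Rg is the root-mean-square distance of glutamine Cα atoms from their
centroid; proline segments are excluded so polyQ stretches of different
constructs compare on equal footing. Histograms use left-closed bins of
width 0.5 Å aligned to zero (configurable). The mixture decomposition fits
Σ w~j~ N(μ~j~, σ~j~) to the bin densities by Levenberg–Marquardt
(`minpack.lm`), with three numerical choices that matter:

* residuals model the **bin-averaged** density (normal CDF differences over
  each bin divided by the width), since evaluating the density at bin
  midpoints biases components whose σ is close to the bin width;
* residuals are weighted by per-bin Poisson errors √max(count, 1) converted
  to density units, which makes the LM fit efficient near the maximum
  likelihood solution and makes the reported reduced χ² (dof = bins − (3k−1))
  directly interpretable — an unweighted variant is reported alongside;
* initialisation uses quantile-spaced means, pooled σ/k and equal weights;
  weights are renormalised to sum to 1 and components are sorted by mean;
  fits collapsing below σ = window/2 are refit at that floor and flagged.

`fit_gaussian_mixture_em()` provides an independent maximum-likelihood EM fit
on the raw values as a cross-check of the histogram route, which is
bin-width sensitive by construction.

Scaling exponents come from Rg ∝ N^ν: pairwise ν = ln(Rg~i~/Rg~j~)/ln(N~i~/N~j~)
plus a pooled log–log regression slope. Prolyl bonds are cis when |ω| < 90°
and trans otherwise; the boundary at exactly 90° goes to trans, a symmetric
convention between the two basins at ~0° and ~180°. The ensemble splits into
all-trans and cis-containing sub-ensembles for downstream Rg analysis, and
recombining the two preserves the overall histogram exactly.

## The synthetic generator

`sample_regions()` draws, per conformation, a latent Gaussian field over
residue index with stationary covariance

k(d) = a · exp(−d/λ) · cos(2πd/P) + (1 − a) · [d = 0],

a product of two positive-semidefinite kernels plus a nugget, then maps each
value through the standard-normal CDF and the per-residue cumulative
marginals (fixed order β, PPII, αL, αR) to a region label. A latent-Gaussian
copula was chosen over, say, a Markov chain because it controls the two
properties the correlation module must recover — decay length λ and
oscillation period P — directly and independently. The cosine term makes
same-phase residues (distance ≈ P) positively associated in the same region,
emulating an oscillatory odds-ratio profile; no claim is made that this is
the physical mechanism in real peptides. `sample_dihedrals()` then scatters
(φ, ψ) around the region centers with a wrapped Gaussian (default sd 15°,
small enough that hard assignment recovers ≥ 98% of generating labels), sets
ω to 180° ± 5° jitter for non-prolyl bonds, and draws prolyl bonds trans with
probability `omega_trans_prob` (default 0.85). `build_backbone()`
reconstructs coordinates by sequential torsion-driven placement with fixed
ideal geometry (N–CA 1.458, CA–C 1.525, C–N 1.329, C=O 1.231 Å; angles
111.0°, 116.6°, 121.7°); recomputing dihedrals from the coordinates
reproduces the inputs to below 1e−4°.

The `q40_like()` defaults emulate a 40-glutamine ensemble whose marginals are
80/5/7/8% over αR/αL/PPII/β — a dominant right-handed-helical basin with
minor PPII and β and rare αL occupancy — and `q40p6_like()` appends six
prolines pinned to the PPII basin with trans probability 0.85 per bond.

What the generator does **not** emulate: excluded volume and sterics (built
backbones can self-intersect for free generation; they are adequate for
H-bond pattern tests on engineered fixtures), side chains and their hydrogen
bonds, solvent, any force-field energetics, and coupling between region
labels and backbone compactness beyond what ideal geometry implies. Passing
tests therefore validate the statistical machinery — estimator correctness,
calibration of the standard errors, parameter recovery — not the physics of
real polyQ chains.

Engineered fixtures exercise every motif definition deterministically:
`ideal_helix()` (φ = −57, ψ = −47), `extended_beta()` (−140, 150),
`ppii_helix()`, `alpha_tilde_strand()` (alternating centers), and
`beta_hairpin()` — two 4-residue β strands around a loop whose angles were
chosen so that cross-strand Kabsch–Sander bonds form; the `"bend3"` variant
has a 3-residue bend-coded loop, the `"turn2"` variant a tight 2-residue turn
that yields an antiparallel E-coded ladder. Label-based fixtures carry one
bookend residue at each end because terminal residues, having an undefined
φ or ψ, never receive a region label; the designed motif occupies the
labelled interior.

## Problem sizes and tolerances used in validation

The test suite and `scripts/acceptance.R` use problem sizes chosen to make
the statistical assertions sharp while staying quick: 2×2-table arithmetic is
checked exactly (1e−12 relative) against independent evaluation on random
tables; standard-error calibration uses 1000 independent-mask replicates at
2000 conformations (expecting ≥ 93% coverage of |ΔΔG| < 2·SE); period and
correlation-range recovery uses Q40-like ensembles of 10,000 conformations
with (a = 0.8, P = 7) at λ = 50 vs λ = 3; mixture recovery uses 50,000 draws
from a three-component generator (expecting weights within ±0.03 and means
within ±0.1 Å); geometry round trips are checked at 1e−4° and closed-form Rg
values exactly. PDB round trips are asserted at 0.2°: fixed-width PDB
coordinates carry three decimals, which propagates to roughly a twentieth of
a degree in recomputed torsions.

## Limitations

* The DSSP subset covers the codes relevant to these peptides; solvent
  accessibility and π-helix bookkeeping beyond the I code are out of scope.
* The odds-ratio SE treats conformations as independent; for correlated
  trajectory frames an effective-sample-size correction would be needed.
* The histogram mixture fit depends on the bin width through the Poisson
  weights; the EM cross-check is the guard against binning artefacts.
* Hard region boundaries and canonical centers are conventions; populations
  near borders shift slightly between hard and clustered assignment, which
  is precisely why both are provided.
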