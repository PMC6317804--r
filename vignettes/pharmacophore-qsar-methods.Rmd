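---
title: "Pharmacophore-based 3D QSAR for safety profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacophore-based 3D QSAR for safety profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

PharmSafe3D builds ligand-based 3D QSAR models for liability targets and
uses them to pre-screen compound libraries before in vitro safety assays.
This vignette documents the models the package implements, the parameters
that matter, the numerical conventions, and what the synthetic test bed
does and does not establish.

## The modeling chain and its assumptions

The workflow assumes that compounds binding the same site share an
arrangement of a few interaction features — hydrogen-bond acceptors and
donors, hydrophobes, charged groups, aromatic rings — and that once ligands
are aligned on such a shared arrangement, the spatial distribution of their
atoms around it carries quantitative activity information. Both assumptions
fail gracefully rather than silently: a compound that does not present the
feature arrangement is reported as a "non hit" rather than receiving a
fabricated activity, and prediction confidence is stratified by chemical
similarity to the training set rather than asserted globally.

### Ligand preparation

Input SMILES are salt-stripped to the largest organic fragment, ionized by
a fixed rule table representing dominant states at pH 7 ± 2 (carboxylic
acids, tetrazoles and acyl sulfonamides deprotonated; aliphatic amines,
amidines and guanidines protonated; anilines, amides and phenols neutral).
A rule table, rather than a pKa engine, is a deliberate design choice: it
reproduces the dominant assignments for drug-like chemistry, is exactly
reproducible, and is editable in one place. Specified stereocentres are
retained; unspecified ones are enumerated to at most 8 isomers (the cap is
a package choice; enumeration order is deterministic), each isomer becoming
a child record with an `_s<i>` id suffix.

Conformers come from stochastic distance-geometry embedding followed by
MMFF94 minimization, both seeded and single-threaded so ensembles are
bit-reproducible. The ensemble contract is applied in R: at most
`10 × max(1, rotatable bonds)` and at most 100 conformers are requested
(caps are applied at generation, then the energy filter — the ordering the
package adopts where practice varies), conformers more than 10.0 kcal/mol
above the ensemble minimum are discarded, and the remainder are
deduplicated greedily in ascending energy so that all retained pairs are at
least 1.0 Å apart in heavy-atom best-fit RMSD. Relative energies, not
absolute ones, are all downstream stages consume, which is why a
general-purpose force field suffices here.

### Site perception

Feature perception is driven by a plain-text SMARTS table
(`inst/extdata/feature_definitions.tsv`) covering exactly the six
conventional types (A, D, H, N, P, R); users can substitute their own table
to mirror any vendor feature set. Placement conventions: atom-placed
features sit on the first pattern atom; charged features sit at the group
centroid; ring features at the aromatic ring centroid. Hydrophobe matches
are merged single-linkage within 2 bonds before taking centroids — the
merge radius is a documented approximation where common tools do not
publish theirs. Directions: donors get one site per donated hydrogen along
the X–H bond; acceptors get a single idealized lone-pair bisector (the
negated resultant of the bond vectors — one vector per site keeps the
vector score well defined; axially symmetric acceptors get none); ring
normals come from an SVD plane fit with a deterministic sign convention.
Ring normals are axial — defined only up to sign — so every consumer
(equivariance checks, the vector score) treats them by absolute cosine.

### Common-pharmacophore hypotheses

Every k-site combination (k = 3..7, distances restricted to 2–20 Å) of
every active conformer is canonicalized as its variant code (sorted type
letters, e.g. `AAAR`) plus its sorted intersite-distance vector. Per
variant, signatures are grouped by a deterministic leader pass in distance
space with Chebyshev radius 1.5 × the 1 Å bin width; a combination may
support several nearby leaders, which makes the grouping robust to clusters
straddling a partition boundary (the half-bin-offset failure mode of plain
binning, observed directly during development on jittered planted
geometries). A group survives when it covers at least the configured
fraction of active molecules (default 0.5); its representative is the
member combination closest to the group mean, so every hypothesis is
instantiated from a real conformer, its reference ligand. A final pass
re-counts matching actives with the production matcher and discards groups
that no longer reach the floor. `maxCandidates` (60) and `maxHypotheses`
(25) bound the verification work; they are throughput knobs, not science.

Matching a site set onto a hypothesis is a backtracking search over
type-compatible injective assignments, pruned by pairwise distance
compatibility (deviation at most twice the match tolerance — the widest
deviation two point sets can show and still superpose within tolerance),
followed by Kabsch superposition; a match requires every assigned pair
within the tolerance after the fit, prefers more matched sites, and breaks
ties by lower RMSD. The default tolerance of 2.0 Å per site is standard
practice for pharmacophore matching; it is exposed everywhere.

Scores follow the three-component convention: a site score
`1 − RMSD/tolerance` (clamped to [0, 1]), a vector score (mean cosine of
matched directed sites mapped to [0, 1]; absolute cosine for ring normals),
and a van-der-Waals volume-overlap Tanimoto against the reference pose,
estimated by 0.5 Å grid sampling with Bondi radii (validated against the
analytic two-sphere overlap in the tests). All weights default to 1. A
"selectivity"-style term is deliberately not implemented; the adjusted
score is `active − w·inactive_penalty`, where the penalty is the analogous
score over matching inactives. Survival filtering keeps the top 10–20% per
variant (default 0.2, minimum one).

### Atom-based cube-occupancy QSAR

Molecules matching the chosen hypothesis on at least `minSites` (default 3)
sites are posed into the hypothesis frame by their match. A rectangular
grid of 1 Å³ cubes covers the aligned training actives plus a 2 Å margin
(the margin is a package choice). Every heavy atom carries exactly one
class by the precedence positive > negative > donor > electron-withdrawing
(acceptor-type N/O and halogens) > nonpolar carbon > other, and
`bit(cube, class) = 1` iff the cube centre lies within the atom's
van-der-Waals radius. The cube-centre-within-atom-radius reading is the
package's interpretation for the atom-based descriptor family, which is
the variant whose coefficients decompose into per-class maps (donor,
hydrophobe, electron-withdrawing); a site-based variant would not have
atom classes to map. Columns constant across the training set are dropped
with reversible bookkeeping.

The regression is single-response NIPALS PLS with mean centring and no
variance scaling (the predictors are binary), deterministic initialization
(the first weight vector is the normalized covariance of X with y), default
3 factors. At full rank PLS reproduces ordinary least squares, which the
tests assert against a normal-equations oracle. The statistics panel:
R² = 1 − SSE/SST; SD = √(SSE/(n − A − 1)) with A the factor count (the
degrees-of-freedom convention the package adopts and exposes, where
reporting practice is not standardized); F = (SSR/A)/(SSE/(n − A − 1)) with
its upper-tail p-value (no multiple-testing correction — single model, a
priori factor count); test-set RMSE, Q² about the test mean, and Pearson R.
Stability is defined by resampling, anchored to its conventional maximum of
1: the mean Pearson correlation, over seeded rounds, between predictions of
a model refit on a random 80% of the training set and the full model's
predictions, evaluated on all training molecules; degenerate rounds are
skipped with a warning. Proprietary tools do not publish their stability
formula, so this resampling definition is the package's own, documented
stand-in.

Test compounds that fail to match the hypothesis are excluded from
RMSE/Q²/Pearson (no prediction exists) but count as predicted-inactive in
classification metrics — the "non hit" convention.

### Screening and stratified interpretation

Library compounds are matched over all conformers (best match: most sites,
then lowest RMSD), predicted, and called hits when predicted pIC50 ≥ 5.0 —
the `≥` is part of the convention, so a prediction exactly at threshold is
a hit. `predicted IC50 = 10^(−pIC50)` molar accompanies every prediction.
Hit rate is 100 × hits/library size, reported to one decimal.

Confusion metrics are percentages with exact complements
(sensitivity + FNR = 100, specificity + FPR = 100); a zero denominator
yields an undefined (NA) metric, never 0. One published table this package
mirrors prints 72%/77% where its own footnote counts (TP 5, TN 38, FP 11,
FN 2) give 71.4%/77.6%; the package implements the footnote formulas
exactly and reports unrounded values.

Similarity stratification uses radial (Morgan) fingerprints of radius 2
hashed to 1024 bits — the vendor tool behind the published workflow
documents only "default settings", so radius and width are the common
convention and configurable. Band edges default to
0.10/0.14/0.22/0.29 (left-closed, right-open intervals). Interpretation
notes encode safety-screening practice: positive calls at similarity
≥ 0.22 and negative calls below 0.10 are high-confidence; records with a
positive call below 0.14 or a negative call at ≥ 0.22 are flagged for
in vitro follow-up. The leader clustering used for centroid-based splits is
single-pass and order-dependent by construction (documented; deterministic
for a fixed input order), with a helper that searches the threshold
producing a target cluster count. The random split is unstratified by
default; the centroid split takes the cluster centroids plus a stated
number of extra actives, with both counts left as parameters (published
counts for this design are internally inconsistent by one compound, so the
package does not hard-code them).

## The synthetic test bed

Two tiers:

* **Geometry tier** — site sets with a planted four-site AAAR geometry
  (asymmetric, all intersite distances distinct, 2.7–5.3 Å) under Gaussian
  jitter (default SD 0.3 Å, a typical site-position uncertainty after
  alignment), two random extra sites per active, random rigid motions, and
  decoys that are re-sampled until a brute-force oracle — independent of
  the production matcher — certifies they contain no type-compatible match
  to the planted geometry. Pseudo-atom structures (one 1.7 Å sphere per
  site) let the QSAR and screening stages run without chemistry. Activities
  follow `pIC50 = intercept + bonus·planted + β·occupancy + N(0, σ)` with
  σ = 0.3 (a realistic assay noise on the log scale) and the 5.0 active
  threshold.
* **SMILES tier** — molecules assembled from a fragment grammar of
  xanthine/purine-like cores and small substituents, run through the real
  preparation and perception stack.

For coefficient-recovery tests the generator plants 24 atom slots on a 4 Å
lattice (so slot cube sets are disjoint), activates each independently with
probability 1/2, and gives 8 slots coefficients of magnitude 0.5–1.0 with
random signs — signal strength chosen once to mimic a pIC50 range of about
3–9 over a 0.3 noise floor. The ground-truth coefficient of each cube is
its slot coefficient divided by the slot's cube count, making the activity
exactly occupancy-linear.

What passing tests show: the search recovers a planted common substructure
in feature space and ranks it above all decoy-derived hypotheses; the PLS
recovers planted cube coefficients (sign agreement of the top-10
coefficients) and predicts held-out occupancy-linear activities; all
bookkeeping identities hold; the pipeline is bit-reproducible. What they do
not show: performance on real conformational ensembles with correlated
site noise, activity cliffs, or tautomer/protonation ambiguity — real data
have structure the generator deliberately does not imitate, and published
benchmark numbers tied to proprietary compound sets are not reproducible
from their papers' text.

Problem sizes in the tests and acceptance script (20 + 20 molecules in the
geometry tier, 120/40 for QSAR recovery, about a dozen molecules through
the full chemistry tier) are the package's choice of smallest sizes at
which the statistical claims are stable across seeds.

## Numerical conventions and degenerate inputs

* Kabsch superposition uses SVD with a determinant correction; reflections
  are never returned. Ties in matching resolve to more sites, then lower
  RMSD; hypothesis ordering is by matching actives, then variant code, then
  reference id, so output order is total and reproducible.
* All RNG consumers take explicit seeds; chemistry runs single-threaded.
* Zero-variance responses, factor counts ≥ n, empty libraries, empty
  fingerprint pairs and out-of-range similarities are errors; a molecule
  with zero perceivable sites is an empty site set (it simply cannot
  match), and a pose entirely outside the model grid is an all-zero
  descriptor row with a warning.
* Whether screening requires all hypothesis sites or at least 3 is exposed
  as `minSites` (default 3, matching the convention that sub-threshold
  partial matches still receive predictions).

## Known limitations

* Ionization is rule-based; unusual pKa's and tautomers are out of scope.
* Alignment is rigid per conformer; no flexible refitting onto the
  hypothesis.
* The leader clustering and hypothesis partitioning are deterministic
  simplifications of proprietary tree-partitioning schemes; hypothesis
  *counts* per variant are therefore not comparable to tools using those
  schemes, and no attempt is made to reproduce them.
* Excluded-volume features and more than 7 sites are not supported.
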