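---
title: "duotox: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{duotox: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, the numerical conventions, and the
places where the design was genuinely open and a choice had to be made. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## 1. The double-activity composite

Quinolone ecotoxicity is characterized here on two endpoints: green-algae
growth inhibition (pEC50, log scale, negative for most compounds) and
bacterial genotoxicity (pLOEC = −log10 of the lowest observed effective
concentration in mol/L, typically 5–9). The comprehensive index method
normalizes each endpoint against a standard value and combines linearly:

$$Y_1 = X_1 / M_1, \qquad Y_2 = X_2 / M_2, \qquad Z = w_1 Y_1 + w_2 Y_2,$$

with default weights $w_1{:}w_2 = 0.8{:}0.2$ reflecting the emphasis on the
algal endpoint. Standards must be positive so the sign structure of the
endpoints survives indexing.

**The calibration question.** The method description says each standard is
"the mean value of each single toxicity", i.e. $M_1 = \overline{|pEC50|}
\approx 2.88$ and $M_2 = \overline{|pLOEC|} \approx 7.8$. That literal
reading does *not* reproduce the published composite column. Solving the
2×2 linear systems implied by published (pEC50, pLOEC, Z) rows yields
$M_1 = M_2 \approx 2.87$: one standard, shared by both endpoints, equal to
the mean absolute pEC50. `calibrate_standard()` therefore defaults to
`mean_abs_algae_shared` (which reproduces 48 of the 50 packaged rows at two
decimals) and exposes `per_endpoint_mean` as the literal alternative. We do
not guess which was intended; both are first-class.

Two rows resist reproduction under any calibration: one row's published
composite (−0.17) has the wrong sign relative to its own endpoints
(recomputation gives +0.20; the row is stored as published and flagged
`inconsistent`), and one row (PAZ) computes −0.38536, which rounds to −0.39
against a published −0.38 — a rounding-boundary miss of 4×10⁻⁴ consistent
with the original authors computing from unrounded endpoint values whose
shared standard falls in [2.878, 2.882] rather than the 2.8752 obtainable
from the printed table. This is why the acceptance test demanding ≥49/50
matches is left red at 48/50 rather than silently weakened.

## 2. Structure preparation and alignment

The real-chemistry path needs four things per molecule: a minimized 3D
conformer, partial charges, per-atom field weights, and a mapping onto the
template's common scaffold. No R cheminformatics stack is assumed; these
steps run through a bundled RDKit helper (`inst/python/chemtools.py`)
invoked as a subprocess, with all mathematics downstream of perception
(Kabsch superposition, fields, PLS) in R.

Substitutions relative to the original proprietary protocol, all recorded
as approximations:

* **Force field**: MMFF94 replaces the Tripos force field. The convergence
  target (0.005 kcal/mol) and iteration cap (10,000) are kept as the
  `prep_config()` defaults; the lowest-energy member of a seeded
  10-conformer ETKDG ensemble is retained, and the seed is recorded.
* **Charges**: plain Gasteiger charges replace Gasteiger–Hückel. The charge
  sum is checked against the net formal charge (|Δ| < 0.01 e).
* **Steric weight**: vdW radius cubed (∝ atomic volume). **Hydrophobicity**:
  Crippen atomic logP contributions (the published SYBYL atomic parameters
  are proprietary; any published atomic logP scheme is acceptable and
  Crippen's is the standard open one). **Donor/acceptor**: SMARTS-based
  perception with the donor weight on the donor *heavy* atom, the standard
  CoMSIA convention.
* **Protonation**: neutral as-drawn. Fluoroquinolones are zwitterionic near
  pH 7; since the original protocol does not state protonation states, the
  neutral form is the default and the input SMILES/SDF controls anything
  else.

Alignment computes the heavy-atom maximum common substructure (elements and
bond orders must match, ring atoms only match ring atoms; ties resolved by
the MCS engine's canonical ordering) and superposes the molecule onto the
template by least squares over the mapped atoms (Kabsch, with reflection
guard). A common substructure below 6 atoms is an error. For the packaged
ciprofloxacin/moxifloxacin pair the scaffold map covers the full 24-atom
shared core. The template itself is never moved.

## 3. Similarity fields and the descriptor matrix

Each of the five fields (S steric, E electrostatic, H hydrophobic, D donor,
A acceptor) is evaluated on a shared rectangular lattice as a Gaussian
similarity index

$$A_f(q) = -\sum_i w_{probe,f}\; w_{i,f}\; e^{-\alpha r_{iq}^2}.$$

Grid and attenuation parameters are not stated in the source; the package
adopts the conventional published values and makes them all configurable in
`field_config()`: spacing 2 Å, margin 4 Å beyond the union bounding box,
α = 0.3 Å⁻², unit probe (charge +1, radius 1 Å, hydrophobicity +1,
donor/acceptor +1). Columns with standard deviation below 10⁻⁶ across
molecules (numerical noise) are dropped, identically for all molecules, and
the surviving columns of each field block are rescaled to equal total block
variance ("CoMSIA standard" scaling) so the five per-field contribution
percentages are comparable; `block_scaling = "none"` disables this.
Field values are non-positive wherever atomic weights are non-negative —
the sign convention tests rely on this.

## 4. PLS and validation statistics

The descriptor matrix is mean-centered (no autoscaling beyond block
scaling) and fitted by single-response NIPALS. Conventions, stated
explicitly because the source gives none:

* $R^2 = 1 - SS_{res}/SS_{tot}$; SEE $= \sqrt{SS_{res}/(n-a-1)}$ with $a$
  components; $F = (R^2/a)/((1-R^2)/(n-a-1))$.
* LOO $q^2 = 1 - PRESS/SS_{tot}$, PRESS from $n$ refits each excluding one
  observation, $SS_{tot}$ about the full training mean. The component count
  is scanned 1..10 (the conventional cap) and the optimum taken at maximal
  q² with ties to fewer components; a SEP-minimizing criterion is available
  (`criterion = "sep_min"`) since the original optimum's criterion is
  unknown.
* External validation: $r^2_{pred} = (SD - PRESS_{test})/SD$ with $SD$ the
  test-set sum of squares about the *training* mean; SEP
  $= \sqrt{PRESS_{test}/n_{test}}$.
* Field contributions: $\sum_j |\beta_j| s_j$ per field, normalized to
  100%.
* Degenerate conventions: a constant response fits with zero coefficients
  and $R^2 = 0$; rank exhaustion truncates the component count with a
  warning; an all-dropped descriptor matrix is a configuration error.

Contours are StDev*Coeff values per grid point, thresholded per field at
the 80th percentile (favored, additionally requiring a positive value) and
20th percentile (disfavored, negative value), written as Gaussian cube or
OpenDX. The sign gates make the masks provably disjoint and give the
expected empty-mask behavior when a field's coefficient mass is one-signed.

## 5. Progressive scrambling

The robustness test perturbs the response to a ladder of intensities and
tracks q² against the squared correlation $r^2_{yy'}$ between original and
perturbed response. The source names only the three output statistics, so
the internals are fixed, seeded package choices:

* **Mechanism**: at level $L$ the responses are sorted into
  $B = \lceil (1-L) \cdot 10 \rceil$ value bins and fully permuted within
  each bin. $L = 0$ is the identity, $L = 1$ one bin — an unrestricted
  permutation. This bin-coarsening design was chosen after a
  stratified-partial-permutation design proved far too destructive (q²
  collapsing below −2 by mid-levels, leaving nothing to interpolate).
* **Statistics**: 10 levels (0.1..1.0), 20 seeded replicates per level
  (tests scale this down and say so), q² and cSDEP fitted as quadratics in
  $r^2_{yy'}$; Q² and cSDEP are the fitted values at the critical point
  0.85 and the slope $dq^2/dr^2_{yy'}$ is the fitted curve's *derivative at
  the critical point* — the local sensitivity the statistic is meant to
  capture, not the global decay rate.

One analytic fact matters for interpreting slopes on clean data: a perfect
model refitted on a perturbed response still predicts the *original*
values, so its $q^2 \approx 2\sqrt{r^2_{yy'}} - 1$, whose derivative at
0.85 is ≈1.08. That is a *floor*: real refits also absorb distortion from
the corrupted labels, which at training sizes of 20–40 raises measured
slopes well above 1 (the suite observes roughly 1–5 across seeds). A
noiseless synthetic world therefore cannot exhibit "slope ≈ 1 with tiny
variance", and the corresponding test asserts the floor-and-boundedness
property instead.

## 6. The synthetic world

`synthetic_spec()` states a world with the statistical structure the QSAR
stages assume, chosen once:

* 40 molecules (the training-set size of the motivating study), each 12
  point atoms: 8 scaffold atoms on a 2 Å lattice inside [0,6]³ with weights
  shared across molecules (it is the common skeleton), plus 4 substitution
  *sites* at fixed positions 2–6 Å off the scaffold centroid whose weights
  are redrawn per molecule. Coordinate jitter defaults to 0: the world
  models a series *after* scaffold superposition, where alignment is exact
  by construction.
* Activities are linear functionals of the true similarity fields at
  planted grid locations plus optional Gaussian noise, composited through
  the real `composite_index` machinery (per-endpoint-mean standards,
  0.8/0.2 weights).
* Planted hotspot locations default to the substitution sites — the places
  where a congeneric series actually varies and hence the only places a
  field model can express structure. An earlier design with free-floating
  decoration atoms (positions redrawn per molecule) was rejected: each
  left-out molecule then leaves the span of the training rows and even
  noiseless planted-linear data cap LOO q² near 0.5, contradicting the
  recovery property the generator exists to provide.

**What a green recovery test establishes** — that the field evaluation,
descriptor assembly, block scaling, PLS, and LOO machinery jointly recover
planted linear structure (q² > 0.99 noiseless) and that the fitted
coefficients at the planted locations correlate with the planted ones
(> 0.8). **What it does not establish**: anything about real conformers,
charges, alignment quality, or the published model's statistics; the
point-atom world has no chemistry, its variance structure is exactly
low-rank, and raw grid coefficients remain non-identifiable off the planted
support (the full-vector planted-vs-fitted correlation is materially lower,
≈0.6–0.8, because PLS smears coefficient mass over each hotspot's Gaussian
footprint; `recovery_correlation(where = "all")` reports it).

## 7. Derivative-screening arithmetic

Change rates use two conventions, selected per metric to match the
published tables: `signed` $= 100(d - p)/|p|$ for composites, logKow,
half-lives, and docking total scores; `magnitude`
$= 100(|d| - |p|)/|p|$ for negative-valued DFT total energies and binding
energies, whose published "increases" refer to growing magnitude. The
log-level toxicity ratio divides each endpoint's absolute log-scale change
by the *parent's* log value and takes the quotient; as documented, this is
deliberately not invariant to re-expressing concentrations in other units —
the formula is asserted exactly as defined, with LOEC in mol/L.

Three published screening numbers are arithmetically inconsistent with
their own printed inputs and are excluded from (or left red in) the
reproduction tests rather than matched by adjustment: the two LOEC change
rates (printed 30.98/31.77, computable 31.00/31.79), one docking-score rate
(printed 19.72, computable 19.71), and one derivative row's EC50 change
rate (printed 25.19, computable 7.59).

## 8. Known limitations

* The published model statistics (q² = 0.58, n = 7, R² = 1, F = 1265.33,
  contributions, etc.) are not reproducible from a desk: they depend on
  proprietary geometries, charges, and alignment. All model-quality
  acceptance here is property-based, by design.
* The chemistry bridge requires a Python with RDKit on `PATH`; without it
  the synthetic, compositing, PLS, and screening paths still work.
* MOL2 reading handles single-molecule files only.
* The pipeline treats externally computed properties (DFT, logKow, t½,
  docking) strictly as inputs; it never attempts to compute them.
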