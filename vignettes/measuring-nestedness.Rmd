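---
title: "Measuring nestedness in bipartite networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nestedness in bipartite networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binest)
```

## Scope and data model

`binest` measures the nestedness of *binary bipartite* networks: an
`n × m` biadjacency matrix `B` with `b_ij ∈ {0, 1}`, rows forming one
guild (say plants) and columns the other (say pollinators). Weighted
interactions are binarized at read time (any positive weight becomes a
link); weighted nestedness variants are out of scope. Zero-degree rows
and columns are legal throughout — null-model samples routinely
contain them — and every metric either tolerates them or flags itself
undefined through an explicit condition, never by propagating `NaN`.

Two fill conventions coexist deliberately. The *matrix fill*
`φ = E/(n·m)` enters the temperature and NIR formulas (it is what
makes the NIR identity `R_DDR = φ` come out for nested matrices),
while the *density of links* `φ = E/(n+m)` is the covariate used by
the regression analyses. Both are computed and named distinctly
(`fill_matrix`, `links_per_node`) so neither is silently substituted
for the other.

Eccentricity is `|n − m|/(n + m)`: the printed formula is unsigned,
but the quantity describes the deviation from a square matrix, so a
magnitude is intended and used consistently, in the descriptors and as
a regression covariate. Degree degeneracy `g` counts, per guild, the
nodes whose degree value occurs more than once in that guild, summed
over both guilds and divided by `n + m`; this convention is monotone
in repetition, bounded in [0, 1], and restricted to within-guild
coincidences.

## The packed configuration and the nested reference

All comparison-to-perfect-order indices start from two constructions:

* **Packing** (`pack_network`) orders rows and columns by
  non-increasing degree. Ties are broken deterministically: among
  equal-degree rows, the one whose partners sit further left under the
  current column order comes first, then the original index; columns
  symmetrically; the two sorts alternate until stable (at most 100
  passes). We deliberately use one reproducible deterministic packing
  rather than a stochastic packing search: the discrepancy index is
  known to depend on the packed configuration chosen, and averaging
  over packings is a cost we do not take on.
* **The canonical nested matrix** (`canonical_nested(n, m, E)`) fills
  the `E` cells whose unit-square centres `(x_j, y_i) =
  ((j−0.5)/m, (i−0.5)/n)` have the smallest Manhattan distance
  `x_j + y_i`, ties broken by smaller row then smaller column index.
  The result is perfectly nested (row supports are nested prefixes)
  and already maximally packed. The isocline of perfect nestedness
  (IPN) is defined *discretely* as this matrix's row-wise boundary
  `c_i`: the analytic isocline family cited in the literature is not
  reproduced here, and the discrete construction guarantees
  parameter-free exactness of the identity `T_AP = 0` for a perfectly
  nested matrix of the same fill — the property the temperature's
  designers intended. Published BINMATNEST temperatures will therefore
  not be matched digit-for-digit, by design.

A consequence worth stating: cells tied at the cutoff distance make
`canonical_nested(n, m, E)` and the transpose of
`canonical_nested(m, n, E)` differ within the tie group only.

## Index-specific numerical choices

**Temperature.** Unexpected cells (1s outside the IPN, 0s inside) are
scored `u_ij = (d_ij/D_ij)²`. The geometry convention: `D_ij` is the
length of the 45° diagonal of the unit square through the cell centre,
and `d_ij` the distance along it to the IPN crossing. Because the
discrete IPN is a non-increasing step curve, that crossing is unique
(the signed gap is strictly increasing along the diagonal, with upward
jumps at row boundaries); when the boundary lies beyond the square
edge the crossing clamps to the segment end. `U_max = 0.04145` is the
constant of the original 1993 implementation, adopted because the
BINMATNEST family uses it; it only rescales `T_AP`. On strongly
anti-nested toy matrices `T_AP` can exceed 100 under this geometry, so
the transformed `T = 100 − T_AP` is clamped to [0, 100] while the raw
value is reported unclamped.

**NMD.** `d_rand`, the expected Manhattan sum under uniform placement
of `E` links, is taken analytically: the mean cell distance is exactly
1 (mean `x` and mean `y` are both 1/2), so `d_rand = E`. This removes
Monte-Carlo noise from a normalization constant; a sampling
cross-check against the uniform null is part of the test suite. τ is
clamped to [0, 1] and undefined at `E = n·m`, where the denominator
vanishes.

**NODF.** The Heaviside convention is `θ(0) = 1`: tied degrees
annihilate a pair's contribution, which is exactly what makes NODF
penalize degree repetition. stable-NODF keeps tied pairs, dividing by
the degree of the smaller element. Pairs whose smaller element has
degree 0 contribute 0 in both variants — note that this means a
*sparse* perfectly nested matrix with empty rows scores below 100 even
on stable-NODF, because empty-row pairs still count in `K`.

**Discrepancy.** Computed on the single deterministic packing;
row `i` contributes its 1s outside the `d_i` leftmost packed columns.

**NIR.** The attack tolerance curve records, before each removal, the
fraction of surviving opposite-guild nodes *among those initially
connected*. This normalization is what makes the identity `R_IDR = 1`
exact for any perfectly nested network — with an all-nodes denominator
the identity fails as soon as the nested matrix has empty rows (a
canonical 50×50 matrix at fill 0.2 has 19 of them), and null-model
samples with stray zero-degree nodes would bias the curve downwards.
`R_DDR` then equals the fill of the connected submatrix, so the full
`NIR = 1` identity is exact precisely when the nested matrix has no
disconnected nodes; the package's identity checks use that regime.
Degree ties make the removal order ambiguous, so areas are averaged
over seeded tie permutations (default 100; automatically reduced to 1
when the removed guild has no ties). The area is a left-Riemann sum,
evaluated before each removal.

**Spectral radius.** The largest singular value of `B` (LAPACK, via
`norm(·, "2")`), equal to the spectral radius of the symmetric
two-guild adjacency; invariant under permutations, hence packing-free.
`ρ_norm` divides by the canonical nested reference's radius. The
canonical matrix may in rare cases miss the true maximizer over all
nested matrices with the same `n, m, E` by a sliver; `ρ_norm` is then
reported above 100 unclamped, with a warning.

**Undefined cases.** `E = 0` (temperature, NMD, discrepancy, NIR,
`ρ_norm`), `φ = 1` (NIR) and `E = n·m` (NMD) raise a condition of
class `nest_undefined_error`; `nestedness_report()` converts it into a
flagged row rather than a numeric placeholder.

## The null ensemble

The null model is the bipartite configuration model: the
maximum-entropy ensemble over all `n × m` binary matrices constrained
to reproduce both observed degree sequences *on average*. The
probability of each link takes the closed form
`p_ia = x_i y_a / (1 + x_i y_a)` in the Lagrange multipliers, which
are fixed by maximum likelihood. The solver:

* **clamps structurally forced nodes analytically** — empty nodes get
  `p = 0`, nodes connected to the whole opposite guild get `p = 1` —
  and peels iteratively, since a clamp can force further nodes. A
  consequence: a perfectly nested matrix, whose degree-sequence pair is
  the conjugate-partition extremal case with a unique realization, is
  *fully* clamped and its ensemble is degenerate (every sample equals
  the observation, σ = 0, z flagged undefined). This is correct
  behavior, not a failure mode;
* **solves the remaining system by damped fixed-point iteration on
  degree classes** (nodes with equal residual degree share a
  multiplier). The default tolerance is `1e-8·max(n, m)` on the
  maximum absolute degree residual, with a 5000-iteration cap. The
  log-likelihood is concave in the log-multipliers, so the optimum is
  unique; as a safeguard the solve is nonetheless repeated from 8
  seeded random starts and the runs must agree on expected degrees
  within 10× the tolerance. A full per-node solve (`reduce = FALSE`)
  exists solely to validate the class reduction and is tested against
  it.

Sampling draws each cell independently; sample `k` uses a substream
seed derived deterministically from `(seed, k)`, so any subset of an
ensemble is reproducible regardless of the ensemble size requested.
`ensemble_metrics` defaults to ensembles of 10⁴ samples, the reference
choice; the test suite uses a few hundred samples per ensemble, with
ensemble sizes always recorded alongside the summaries.
z-scores compare on the transformed (0–100) orientation, for which
affine invariance makes the choice immaterial up to sign, except for
the unnormalized spectral radius which is compared raw.

## Statistics

Spearman correlations are tie-corrected (Pearson on average ranks)
with the two-sided t-approximation p-value; an exact permutation
p-value is available for `n ≤ 8`, where full enumeration is instant.
The regressions are ordinary least squares with intercept on size,
density of links and eccentricity — degree degeneracy is deliberately
excluded as a covariate, because its dependence on nestedness is
expected rather than confounding. Significance is flagged at raw
`p < .01` with no multiple-testing correction across the metric ×
descriptor grid, mirroring the reference analysis; users scanning the
grid for discoveries should correct accordingly. The calibration of
the flag (≈1% type-I rate) and its power against a planted
eccentricity dependence are themselves part of the acceptance tests.

## Synthetic fixtures: what they emulate and what they do not

The generators produce (i) canonical nested matrices, (ii) i.i.d.
Bernoulli matrices, and (iii) *noisy nested* matrices: canonical
matrices degraded by relocating randomly chosen links into randomly
chosen empty cells, preserving `n`, `m`, `E` exactly.

Link relocation — rather than degree-preserving checkerboard swaps —
is a considered choice. A perfectly nested matrix contains no 2×2
checkerboard submatrix at all, and its degree sequence admits exactly
one realization; consequently *no* noise process that fixes both
degree sequences can move off the perfectly nested configuration.
Degree-preserving randomization (`checkerboard_swaps`) is provided and
tested for non-extremal matrices, but a nestedness *gradient* must
perturb the degrees, and relocation does so in the gentlest way while
holding size and fill fixed.

The battery (`fixture_battery`) crosses sizes 20–200 nodes, fills
0.05–0.5, eccentricities 0–0.6 and three noise levels (0, 0.2·E and
1·E relocations), 108 networks by default, each with at least 20
nodes, and verifies at generation that no two regression covariates
are perfectly confounded. It emulates the *spread* of descriptor
values in real mutualistic datasets; it does not emulate their joint
distribution (real size–fill anticorrelation is weaker here), nor
phylogenetic, spatial or sampling structure. Passing tests on the
battery therefore validate the machinery and its calibration, not any
ecological claim about real webs.

Problem sizes throughout the suite — networks of 20–60 nodes for
null-model recovery, ensembles of 400–1000 samples, 50 self-consistency
replicates, 500 calibration replicates at 200 observations — were
chosen as the smallest sizes at which the binomial and normal
tolerances of the checks are comfortably discriminating.

## Known limitations

* Temperature values are convention-dependent (cell-diagonal geometry,
  discrete IPN, `U_max`); comparisons with other implementations are
  meaningful only within one convention.
* `ρ_norm` normalizes by the canonical construction, which is not
  proven to maximize the spectral radius for every `(n, m, E)`.
* The discrepancy uses a single packing; its known sensitivity to the
  packed configuration is inherited, documented, and not averaged
  away.
* NIR loses sensitivity as fill grows (the `1 − φ` denominator); it is
  undefined at `φ = 1`.
* The regression model is linear in `s`, `φ`, `ε`; curvature or
  interactions are not modeled.
* The CLI batch mode can process a directory of real matrices (e.g.
  Web-of-Life downloads), but no external dataset is bundled or
  required.
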