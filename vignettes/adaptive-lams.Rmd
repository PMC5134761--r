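---
title: "Adaptive local approximate models of torsional energy surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive local approximate models of torsional energy surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamadapt)
```

## The surrogate model

Crystal structure prediction global searches must evaluate the
intramolecular energy penalty of a candidate conformation millions of
times. Doing that with constrained quantum-chemistry minimizations is
hopeless, so the search instead consults a library of **local
approximate models (LAMs)**. Each LAM is built from one constrained
minimization at a reference conformation $\theta^{\mathrm{ref}}$ of the
flexible torsions: the *dependent* degrees of freedom $\beta$ (bond
lengths, bond angles, stiff torsions) are relaxed at fixed $\theta$,
and the relaxed energy surface
$E_{\min}(\theta) = \min_\beta E(\theta, \beta)$ is expanded to second
order,

$$\Delta E_{\mathrm{intra}}(\theta) \approx E_{\mathrm{ref}}
  + b^\top \Delta\theta
  + \tfrac12\, \Delta\theta^\top A\, \Delta\theta,
  \qquad
  \beta(\theta) \approx \beta_{\mathrm{ref}} + C\, \Delta\theta ,$$

where $\Delta\theta = \theta - \theta^{\mathrm{ref}}$ taken along the
shorter arc for full-circle torsions, and all energies are referenced
to $U_{\mathrm{global}}$, the unconstrained global minimum of the
isolated molecule, so that $\Delta E_{\mathrm{intra}} \ge 0$ there. A
query point is served by the *nearest* LAM in the Euclidean
conformational metric. Because the models are derivatives of the
*relaxed* surface — the dependent coordinates are re-minimized at every
finite-difference stencil point — the relaxation of $\beta$ with
$\theta$ is folded into $b$ and $A$; building them from frozen-$\beta$
Hessians instead would be inconsistent with the linear $\beta(\theta)$
model and is deliberately not offered.

## Adaptive placement

A regular grid of LAMs over the torsional search box needs a number of
models that grows exponentially with the number of flexible torsions.
The adaptive algorithm instead asks, for every unordered pair of
existing models $(A, B)$, whether their predictions disagree where both
are least reliable — around the conformational midpoint $M$ of their
reference points. A new model is built at $M$ exactly when

1. the two predictions at $M$ differ by **strictly more than**
   $\delta_E^{\mathrm{LAM}}$ (default 1 kJ/mol);
2. the **lower** of the two predictions is at most
   $\Delta E^{\mathrm{cutoff}}$ (default 20 kJ/mol) — conformations
   more strained than that cannot matter for packing, a level in line
   with surveyed distortion energies of real polymorphs;
3. no third model is **strictly nearer** to $M$ than $A$ and $B$ are —
   otherwise neither model would ever be asked about $M$.

Pairs whose periodic coordinates are antipodal (shorter-arc difference
of exactly 180°) have no well-defined midpoint; they are skipped rather
than resolved arbitrarily, because any choice changes under coordinate
relabelling, and in practice such pairs are always separated by nearer
models. Midpoints within `eps_dup` (0.5°) of an existing model are
duplicates; on a regular grid two diagonal pairs share a midpoint and
only the first acceptance wins.

Two sweep protocols are provided. `single_pass` visits the pairs of the
initial set once, in lexicographic index order — the cheap mode for
large multi-torsion grids, where additions only join the duplicate
veto. `iterate` repeats full sweeps with all current models, including
fresh ones, until a sweep accepts nothing; the duplicate spacing bounds
the number of models that fit in the compact domain, so termination is
guaranteed. The sweep order is one faithful reading of
"repeat until no more models are found"; the decision log (one row per
pair considered, with the midpoint, discrepancy, lower prediction,
outcome and blocking criterion) makes any alternative order auditable
without changing data structures.

The strictness conventions follow the wording of the criteria: (1) is a
strict inequality, (2) is non-strict, and (3) blocks only on strictly
nearer third models (an exactly equidistant model does not). The
boundary case of (2) is immaterial at the default settings. Criterion
(3) is evaluated first because it is cheap and prunes most pairs;
acceptance requires all three, so the order changes only which blocker
a log row reports.

## The synthetic oracle

At desk scale the constrained quantum-chemistry calculations are
replaced by an analytic potential family (`potential_spec`): Fourier
torsional terms $V(1-\cos(k\theta_i+\phi))$, product couplings
$W\cos(k_i\theta_i+\phi_i)\cos(k_j\theta_j+\phi_j)$, optional bounded
quadratic terms, and dependent coordinates restrained harmonically
about smooth targets $\hat\beta(\theta)$. The harmonic dependent model
is what makes the family a good test-bed: the constrained minimum is
analytic ($\beta^* = \hat\beta(\theta)$, $E_{\min}$ in closed form), so
LAM construction can be checked against exact values, while the
surfaces still have multiple minima, couplings and full periodicity.
What the generator does *not* emulate: real dependent coordinates mix
units (Å, degrees) and can respond non-smoothly near steric clashes;
conformation-dependent electrostatics are absent (LAM payloads carry
such data but never interpret it); and energies here are cheap, so
nothing in the tests probes the cost asymmetries that motivate the
method in production. Passing tests demonstrate the placement logic and
its bookkeeping, not quantum-chemical accuracy.

An external engine can stand in for the synthetic family by honouring
the `constrained_minimize` contract (minimize over $\beta$ at fixed
$\theta$, report the minimum energy, the minimizer and a convergence
record); level-of-theory labels ride along as provenance, never
executed.

Three frozen presets anchor the documentation and tests:

* `quadratic` — $E = \tfrac12\,0.01\,\theta^2$ on $[-90°, 90°]$ with
  $\hat\beta = 0.1\,\theta$. Second-order models are *exact* here, so
  every LAM set reproduces the oracle to round-off and adaptation adds
  nothing; any other behaviour is a bug.
* `double_well_1d` — $20(1-\cos 2\theta) - 10(1-\cos 4\theta)$ on
  $[-90°, 90°]$: wells of equal depth at $\pm 30°$, a 5 kJ/mol barrier
  at 0°, 45 kJ/mol edges. Seeded with models at $-90, -30, +30, +90°$,
  adjacent models disagree by 4.34 kJ/mol at $\pm 60°$ (above the
  1 kJ/mol trigger, and with predicted energies of ~12 kJ/mol, inside
  the 20 kJ/mol relevance window) while the $0°$ midpoint between the
  symmetric well models agrees exactly — so adaptation inserts
  precisely two models. The barrier heights were chosen analytically
  so that the second generation of pairs is stable: the $\pm 45°$
  midpoints disagree by 0.88 kJ/mol (below trigger) and the $\pm 75°$
  midpoints predict ~37 kJ/mol (beyond the relevance cutoff). Note the
  agreement at $0°$ comes from symmetric placement, not accuracy — the
  classic argument for letting users inject symmetry-breaking extra
  points (`cmd_adapt(extra_points = ...)`).
* `coupled_2d` — $250(1-\cos(\theta_1-\theta_2-20°)) +
  8(1-\cos(\theta_1-60°)) + 3\cos(6\theta_1+15°)\cos(6\theta_2+45°)$
  on the torus: a steep wall confines the low-energy region to a
  narrow diagonal band (the two torsions are strongly correlated, so
  the relevant region is nothing like an axis-aligned box), the $k=1$
  term articulates distinct minima along the band, and the $k=6$
  corrugation gives the refinement something real to chase.

## Numerical choices

* Angles are degrees throughout; energies kJ/mol; dependent
  coordinates unitless in the synthetic family (unit bookkeeping for
  real molecules belongs to the adapter).
* Finite differences: central, default step 1.0°; diagonal second
  derivatives from the 3-point stencil, off-diagonals from the 4-point
  cross stencil; $A$ symmetrized afterwards. Halving the step must
  shrink the derivative error about fourfold — tested.
* $U_{\mathrm{global}}$: a capped dense pre-scan (~50,000 points,
  resolution split evenly across dimensions) followed by L-BFGS-B
  polish with analytic gradients from the 20 lowest scan points plus
  seeded random starts. The pre-scan is what makes the search reliable
  on corrugated surfaces, where gradient descent from a coarse start
  stalls in a local wrinkle.
* Reference energies in $(-10^{-6}, 0)$ kJ/mol are clamped to zero
  with a warning (finite-difference noise); anything lower aborts,
  since it means $U_{\mathrm{global}}$ is wrong.
* Nearest-model ties break on the lowest insertion index; grid points
  and pair sweeps are ordered lexicographically — identical inputs give
  bit-identical decision logs.
* Serialized LAM sets write numbers with 17 significant digits, so a
  read/write round trip is bit-exact.
* Two grid conventions coexist deliberately: multi-torsion search
  grids count cell *centres* (a span of 90° at ±15° holds 3 models),
  while one-dimensional illustrations traditionally count *nodes*
  including both endpoints (−90°…+90° at ±15° gives 7). The default is
  `centered`; on periodic dimensions the node endpoint merges with the
  start.

## Measuring the benefit

`scan_error_map()` tabulates LAM-versus-oracle differences on a dense
grid (5° here) and `summarize_error_map()` reduces them. Two averages
are reported. The plain mean over the whole scan shows that refinement
helps globally (on `coupled_2d`: 33.2 → 13.3 kJ/mol going from the 3×3
grid to the adapted set). The mean over the *energetically relevant*
rows (oracle energy ≤ 20 kJ/mol) is the figure of merit for comparing
model counts, because it covers exactly the region the placement
criteria are designed to serve: criterion (2) *forbids* spending models
where the energy is irrelevant, so a refined-everywhere comparison grid
will always look better in regions the algorithm has chosen to ignore,
and a whole-domain average would mostly measure that choice rather than
model quality. On the relevant region the adapted set (46 models,
minimum spacing 13.5°) reaches a mean deviation of 0.56 kJ/mol versus
53.7 for its initial grid and 1.09 for a 12×12 = 144-model centered
grid — better accuracy than a regular grid with more than three times
as many oracle calls.

These numbers are recomputed, not quoted: the test suite and
`scripts/acceptance.R` derive all of them at run time from the shipped
presets (problem sizes: 181-point scans in one dimension, 72×72 = 5184
scans on the torus, 46-model adapted sets, twenty seeded random
surfaces for the decision-log equivalence check — sizes chosen to keep
a full run in minutes on one core).

## Known limitations

* Nearest-model evaluation is piecewise quadratic and therefore
  *discontinuous* across midlines between disagreeing models; the jump
  equals the midpoint discrepancy, which adaptation drives below
  $\delta_E^{\mathrm{LAM}}$ but not to zero. Smoothing across model
  boundaries is explicitly out of scope here.
* The iterate-mode fixed point guarantees pairwise consistency, not
  oracle accuracy: symmetric model placements can agree on a wrong
  value, as the one-torsion example shows at 0°.
* Edge-energy domain expansion probes edges through the centre of the
  other dimensions only; a low-energy corner reached along a diagonal
  can be missed at extreme couplings.
* `expand_domain()` may return spans that the configured grid spacing
  no longer divides; regenerate the grid spacing (or pick the
  increment as a multiple of the cell width) before building.
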