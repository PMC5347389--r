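---
title: "Predicting binary mixture toxicity by triangulation-based interpolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting binary mixture toxicity by triangulation-based interpolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixray)
library(dplyr)
```

## The problem

Risk assessment of chemical mixtures usually leans on two reference models.
Concentration addition (CA) sums toxic units: a mixture applied at
concentration fractions $p_i$ reaches effect $x$ when
$\sum_i c_i / EC_{x,i} = 1$, where $EC_{x,i}$ is the concentration at which
component $i$ alone produces effect $x$. Independent action (IA) multiplies
survival fractions, $E = 1 - \prod_i (1 - E_i)$. Both need assumptions about
the components' modes of action, and CA needs every component to *have* an
effective concentration at the effect level of interest. When a component is
hormetic — stimulatory at low concentration (negative inhibition), toxic at
high concentration, a J-shaped concentration-response curve — no monotone
partner reaches the stimulatory effect levels, and CA has a *predictive
blind zone* there. Interactions (synergism, antagonism) further break both
models, and they are ratio- and time-dependent.

`mixray` implements an assumption-free alternative: treat the measured
toxicity of a binary system as a scattered 2-D field over the concentration
plane $(c_A, c_B)$ and interpolate it. The training set is the standard
fixed-ratio design — the two single compounds plus five EquRay mixture rays,
each tested over a 12-point dilution series, giving 84 vertices per exposure
time. Two interpolants are built per time:

* **LinIP** — the Delaunay triangulation of the vertices; a query is
  answered by the plane $Z = aX + bY + c$ through the three vertices of its
  containing triangle (the coefficients solve the $3 \times 3$ vertex
  system).
* **NeiIP** — Sibson natural-neighbour interpolation on the dual Voronoi
  tessellation; inserting the query $q$ creates a cell $V(q)$ that steals
  area from its neighbours' cells $V_i$, and
  $f(q) = \sum_i W_i\, f(x_i)$ with
  $W_i = \mathrm{Area}[V_i \cap V(q)] / \mathrm{Area}[V(q)]$.

Both reproduce the training vertices exactly, have linear precision, never
overshoot the participating vertex values, and refuse queries outside the
convex hull rather than extrapolate. Because the surface is interpolated
from data, hormetic zones and interacting rays are predicted like any other
region — there are no blind zones inside the hull.

## Concentration-response models

Monotone S-shaped curves use the two-parameter Weibull and Logit forms on
the decadic-log concentration scale (effects in percent throughout):

$$E = 100\,[1 - e^{-e^{\alpha + \beta \lg c}}], \qquad
  E = \frac{100}{1 + e^{-\alpha - \beta \lg c}}.$$

J-shaped (hormetic) curves use a five-parameter double-logistic: a falling
limb scaled by the minimum effect plus a rising limb to 100%,

$$E(c) = \frac{m}{1 + 10^{-\beta_{dn}(\lg c - \lg \varepsilon_1)}}
       + \frac{100 - m}{1 + 10^{-\beta_{up}(\lg c - \lg \varepsilon_2)}}.$$

The user-facing parameters carry fixed semantics: $E_{min}$ is the minimum
(most stimulatory) effect, $\varepsilon_{dn}$ the concentration at
$E_{min}/2$ on the falling limb, $\varepsilon_{up}$ the median effective
concentration (effect 50%), and $\beta_{dn}, \beta_{up}$ the limb shapes.
The three internal constants $(m, \varepsilon_1, \varepsilon_2)$ are solved
numerically (Levenberg–Marquardt on the three defining equations) so that
those semantics hold exactly; property tests verify all of them on random
parameter draws rather than trusting algebra. Two numerical footnotes:
the anchoring requires the limbs to be separable (roughly
$\varepsilon_{up}/\varepsilon_{dn} \gtrsim 10$; otherwise `fivepl_params()`
refuses), and the power-law tails of the double-logistic can carry ripples
below 0.05% effect far outside the observed range — irrelevant at assay
scale, but visible to a fine grid, which is why the unimodality test uses
that tolerance.

```{r fivepl}
p <- fivepl_params(e_min = -20, eps_dn = 1e-5, beta_dn = 1.5,
                   eps_up = 1e-3, beta_up = 2)
effect_fivepl(c(1e-5, 1e-3), p) # E_min/2 at eps_dn, 50 at eps_up
```

`fit_crc()` least-squares fits any of the three families (`minpack.lm`
underneath, with transform-based starting values and multi-start for the
J-shape). `family = "auto"` picks the better monotone family by RMSE and
switches to the J-shape only when the data dip below zero *and* the J-shape
fits better — hormesis is claimed only when stimulation is observed.
`invert_ecx()` returns $EC_x$; for the J-shaped family it uses the rising
branch (above the curve minimum), and any level $x \le 0$ is reported as
undefined (`NA`): that convention is exactly CA's blind zone, and it keeps
$EC_x$ single-valued. `hormesis_characteristics()` extracts the zero effect
point (ZEP), $EC_{min}$ and $E_{min}$ by bracketed root/minimum search.

Observed 95% confidence intervals are replicate-based $t$-intervals per
concentration (the assay's natural uncertainty statement); the fitted-curve
confidence band (delta method) is also available via
`predict(fit, interval = "confidence")` but is not what interaction calls
compare against.

## Reference models and interaction calls

`ca_ecx_ray()` is toxic-unit summation,
$EC_{x,mix} = 1/\sum_i (p_i / EC_{x,i})$, with blind-zone propagation;
`ca_effect_at()` inverts it by bisection on the effect level (tolerance
$10^{-8}$ on the percent scale, bracketed on the range where every
component's $EC_x$ exists). `ia_effect()` multiplies survival fractions and
warns on negative inputs, where IA loses its probabilistic reading.

Interactions are quantified by the effect residual ratio. At effect level
$x$ of a ray, the concentration $c_x$ where the fitted ray curve reaches
$x$ is found; the CA prediction $E_{prd}$ at $c_x$ is compared with the
observed CI there (CI bounds interpolated between tested concentrations on
the $\lg c$ scale). If the prediction falls inside the CI the cell is
additive (rendered "—"); otherwise

$$ERR_x = 100\,\frac{E_{CI} - E_{prd}}{E_{prd}},$$

with $E_{CI}$ the CI limit nearer the prediction (upper under antagonism,
lower under synergism); $ERR_x > 0$ is synergism, $< 0$ antagonism. The
denominator is $E_{prd}$, matching the percent units of the published
grids; dividing by 100 instead is available via `normalize = "hundred"` for
compatibility with the alternative reading of the statistic.

## The EquRay design

`equray_ratios()` anchors the rays on the components' EC50s: ray $k$ of $n$
has toxic-unit proportions $(n{+}1{-}k):k$, so the middle ray of five is
equitoxic and

$$p_A^{(k)} = \frac{(n{+}1{-}k)\,EC_{50,A}}
  {(n{+}1{-}k)\,EC_{50,A} + k\,EC_{50,B}}.$$

Concentration series are geometric (`dilution_series()`, default factor 0.7,
12 levels — the published gradient formula is not reproducible, so the
factor is an explicit knob). Ray stocks default to four times the additive
EC50 proxy $4/(p_A/EC_{50,A} + p_B/EC_{50,B})$ so each series spans the
informative effect range; which exposure time anchors the ratios is
configurable (`anchor_time`, default the last).

## Geometry: the consequential choices

**Coordinate space.** Interpolation runs on $\lg c$ axes by default: a
geometric dilution series is evenly spaced there, so triangles are well
shaped across the four orders of magnitude a series spans. Raw-linear axes
are retained (`coordinate_space = "linear"`) but cluster 11 of 12 points
near the origin. This choice is not derivable from the method definition
itself and changes the triangulation, so it is surfaced in the constructor
and the printed model summary.

**Axis floors.** A single compound has zero partner concentration, which
has no logarithm; zeros map to a floor one geometric step below the lowest
tested concentration on that axis (step estimated from the data's own
spacing, overridable via `axis_floor`). The floor is reported by
`print.mix_interpolator()`.

**Implementation.** The triangulation is Bowyer–Watson incremental
insertion with cached circumcircles; on-circle ties (determinant within
$10^{-12}$ of zero after uniform rescaling) count as "outside", which keeps
the result valid and deterministic for a given input order. Voronoi cells
are built directly as bisector half-plane intersections
(Sutherland–Hodgman clipping of convex polygons), nearest sites first with
a distance-based stopping rule. Unbounded cells are clipped to the data
bounding box expanded by three diagonals; Sibson weights are ratios of
stolen areas, so hull-interior queries are insensitive to that margin (a
doubling-margin test asserts this). Coordinates are uniformly centred and
rescaled before cell construction — a similarity transform, so the
tessellation and all area ratios are unchanged but absolute tolerances
stay meaningful on badly scaled inputs.

**Near the hull.** For a query next to the convex hull the inserted cell is
unbounded in the infinite plane; any implementation must truncate it, and
the weights then depend on the truncation. Consequences: NeiIP's linear
precision is exact in the hull interior but only approximate (sub-percent
on the canonical design) for queries hugging the hull, and the Monte-Carlo
verification of the weights must use the same clipping convention as the
implementation. LinIP is exact everywhere inside the hull. Queries outside
the hull return `NA` with an `outside` flag — never an extrapolation.

## Validation protocols

`lmocv_split()` holds out one third of the mixture points (20 of 60); the
singles always stay in training (64 points). The split is drawn on
(ray, level) identities and shared across exposure times within a repeat,
since the protocol partitions the mixture set once per system.
`lmocv()` repeats this 20 times by default (per-repeat seeds spawned from a
master seed and recorded), rebuilds the per-time models, predicts the
holdouts, and averages the per-repeat metrics. `loocv_by_ray()` leaves out
one complete ray per fold — deterministic, no RNG — testing whether a whole
missing concentration-response curve can be reconstructed from the
neighbouring rays.

Scoring follows the CI-overlap convention: a prediction is correct when it
falls inside the observed 95% CI (closed bounds), and the accuracy rate
(AR) is the percentage of correct predictions. RMSE and $R^2$ are standard.
Held-out points outside the training hull are a deliberate refusal, not an
error: they are counted and reported (`n_outside`) but excluded from the
metric denominators. Metrics are pooled over exposure times within a system
(per-time tables remain available in `per_point`).

## The synthetic generator

Real raw data for this assay are not redistributable, so the package ships
a generator that emulates the *statistical structure* the method assumes:

* singles and five EquRay rays, 12-point geometric series, seven exposure
  times (0.25–12 h), three replicate wells;
* component curves monotone (Weibull/Logit, optionally time-dependent
  EC50s) or hormetic (`component_fivepl()`, with an optional trend that
  deepens $E_{min}$ over exposure time);
* the true mixture surface is the CA solution with a multiplicative
  toxic-unit deviation $\lambda(\text{ray}, x, t)$: $\lambda = 1$ additive,
  $\lambda < 1$ synergistic, $\lambda > 1$ antagonistic — injected on the
  toxic-unit scale so ratio-, level- and time-dependent interaction
  patterns are expressible smoothly;
* replicate noise is Gaussian on the percent-effect scale (default SD 5%,
  a typical mid-range luminescence CV), and observed CIs are the replicate
  $t$-intervals.

What it does **not** emulate: heteroscedastic or concentration-dependent
noise, plate/position effects, solubility ceilings, non-Gaussian outliers,
and mixture-level hormesis beyond what CA over a hormetic single implies.
Green tests therefore certify the machinery under the design's geometry and
honest replicate noise — not robustness to assay artifacts.

```{r generator, eval = FALSE}
sys <- simulate_mixture_system(seed = 101)        # additive, 7 times
glance(lmocv(sys, n_repeats = 20, seed = 202))    # AR ~94% both methods
glance(loocv_by_ray(sys))                         # lower, ~92-94%
```

On that additive system with 5% noise the repeated holdout reaches ARs in
the low-to-mid 90s for both interpolators, and leave-one-ray-out is
consistently a few points lower — reconstructing a whole missing ray is the
harder task. Both patterns are recomputed by `scripts/acceptance.R` and
asserted (at AR ≥ 90% and LOOCV ≤ LMOCV) in the test suite.

## Numerical choices, sizes, limitations

* Bisection/root tolerances: $10^{-8}$ on effect (CA inversion),
  $10^{-12}$ on $\lg c$ (curve inversion); clipping tolerance $10^{-13}$
  on unit-scaled coordinates; barycentric containment slack $10^{-9}$.
* J-shape fitting uses three starting-value heuristics and keeps the best
  least-squares solution; degenerate inputs (constant effects, fewer than
  six distinct concentrations) are refused with typed errors.
* Unit tests run three exposure times and the full suite in well under a
  minute; the acceptance checks use the full seven-time design, 20 holdout
  repeats, and 200 Monte-Carlo weight verifications at $10^5$ samples each
  (about two minutes) — sizes chosen to exercise the canonical protocol
  while staying comfortably interactive.
* The repeated-holdout convergence law ($\mathrm{SE} \propto
  1/\sqrt{\text{repeats}}$) is a property of averaging independent
  repeats; the suite verifies per-repeat independence and determinism
  rather than re-estimating the law at large repeat counts.
* Scope is binary mixtures. The geometry generalises to higher dimensions
  in principle (3-D triangulations for ternary systems), but nothing here
  validates that, and multi-component ray designs are out of scope.
* Interpolation quality degrades where the training hull is thin (e.g. a
  single ray): most queries are then refused as outside, which the
  validation reports make visible.
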