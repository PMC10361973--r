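---
title: "Growth exponents of brain metastases: models, estimators, and the mesoscopic simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth exponents of brain metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmgrowth)
```

## The model

Macroscopic tumor growth is summarized by the Von Bertalanffy law

$$\frac{dV}{dt} = \alpha V^\beta - bV,$$

where $V$ is volume (cm³), $\alpha > 0$ is an energy-intake coefficient, $b$
a maintenance coefficient, and $\beta$ the growth exponent. For growing
lesions essentially all metabolic intake goes into biosynthesis, so this
package fixes $b = 0$ throughout; three measurements per lesion can identify
at most $(V_0, \alpha, \beta)$ anyway. With $b = 0$ the law integrates in
closed form,

$$V(t) = \left[V_0^{1-\beta} + (1-\beta)\,\alpha\,(t - t_0)\right]^{1/(1-\beta)},$$

with the exponential limit $V_0 e^{\alpha (t-t_0)}$ at $\beta = 1$
(a removable singularity; `vb_volume()` switches branches when
$|1-\beta| < 10^{-6}$). For $\beta > 1$ the solution blows up at a finite
$t^* = t_0 + V_0^{1-\beta}/((\beta-1)\alpha)$ and evaluation at or past
$t^*$ is a domain error, not a number.

$\beta$ is a *shape* parameter, not a speed: $\beta = 1$ is exponential
growth, $\beta < 1$ decelerating (sub-exponential) growth, and $\beta > 1$
accelerating, "explosive" growth. The biological reading is evolutionary:
sequential takeover by progressively fitter clones accelerates whole-tumor
growth, so heterogeneous untreated lesions tend to $\beta > 1$, while
treatment strips clonal diversity and pushes recurrent lesions toward
$\beta \approx 2/3$.

## The three estimators

**Three-point solver** (`solve_three_point_beta`). Clinical follow-up gives
three scans $(t_0,V_0), (t_1,V_1), (t_2,V_2)$ with strict growth required
for inclusion. Eliminating $\alpha$ between two evaluations of the closed
form yields one equation in $\beta$ alone:

$$\frac{1 - (V_1/V_0)^{1-\beta}}{1 - (V_2/V_0)^{1-\beta}}
  = \frac{t_1 - t_0}{t_2 - t_0}.$$

The left side is strictly monotone in $\beta$ for any growing record (a
property test checks this on 1000 random records), so the root is unique.
The solver scans $[-5, 10]$ in steps of $0.01$ for a sign change and
bisects to $10^{-8}$. A reference implementation would hand this to a
general root finder; the scan-and-bisect contract is chosen so that the
(never observed) multiple-root case is *reported* (`bm_ambiguous_root`
carries all roots) rather than silently resolved. Powers are evaluated as
`expm1((1-beta)*log(r))` for stability at large volume ratios.

**Multi-point log-linear fit** (`fit_multipoint_beta`). Dense series (mouse
bioluminescence, measurement days 7/14/18/21/25/28) are fitted by
discretizing the law over consecutive pairs and taking logs:

$$\ln\frac{V_i - V_{i-1}}{t_i - t_{i-1}} = \ln\alpha + \beta \ln V_i.$$

The OLS slope is $\beta$. Two filters mirror the animal analysis: points
after day 21 are dropped by default for mouse-group series (late volumes
approach the whole-brain volume, and mechanical constraint biases the slope
down — the package's ceiling test demonstrates exactly this bias), and any
non-positive increment raises an exclusion error rather than a fit, the
analogue of excluding animals with volume decrease.

**Group sweep** (`sweep_group_beta`). The best *common* exponent
$\beta^*$ for a treatment group minimizes the summed relative error

$$E(\beta') = \sum_{\text{lesions}} \min_{V_0', V_1'}
  \left[ \frac{|V_0'-V_0|}{V_0} + \frac{|V_1'-V_1|}{V_1} +
  \frac{|V_2'-V_2|}{V_2} \right],$$

where $V_2'$ follows from $(\beta', V_0', V_1')$ in closed form. Grids
default to the original analysis resolution — 300 exponent values on
$[0,3]$, 500 × 500 volume candidates on $(0,V_1] \times [V_0,V_2]$ — about
75 million candidate evaluations per lesion (~10 s per lesion vectorized;
tests and interactive runs use reduced grids, which the equality-with-brute-
force test shows are exact at any resolution). Ties in the argmin break
toward the smaller exponent, deterministically. Candidate pairs whose
implied power base is non-positive are infeasible and skipped; a lesion with
no feasible candidate at some $\beta'$ contributes an infinite error there.

## Sensitivity analyses

Two robustness procedures probe the three-point computation:

1. `perturbation_screen()` multiplies each volume by an independent factor
   uniform on $[1-\varepsilon, 1+\varepsilon]$ ($\varepsilon = 5\%$ by
   default, 200 replicates) and re-solves. A lesion is *consistent* when the
   mean perturbed exponent is within 0.5 of the unperturbed one. The noise
   is multiplicative because segmentation error scales with lesion size; the
   uniform distribution is the minimal reading of "error smaller or equal to
   ±5%", and the errors are independent per volume (a shared-factor reading
   would cancel in the volume ratios and test nothing). Replicates that
   break monotonicity or lose the root are counted and excluded from the
   mean — near-flat records can fail most replicates, which is itself
   diagnostic and is reported.
2. `curve_family_beta_distribution()` samples random time triplets from
   exponential, cubic, Gompertz and logistic curves. Exponential and cubic
   give point masses at 1 and 2/3 exactly; saturating curves give spreads
   below 1; ±20% noise widens every spread around its clean center. The
   parameterizations ($A e^{-c e^{-dt}}$, $A/(1+m e^{-rt})$, $a(t+s)^3$,
   $V_0 e^{rt}$) and their default windows are package choices: the
   saturating-curve windows cover the rising phase up to ~80–90% of the
   plateau, because deeply saturated triplets have no admissible exponent in
   the default solver bracket (they are recorded as failures, not errors).

## The mesoscopic simulator

`simulate_bm()` grows a virtual metastasis on an $L^3$ voxel lattice
(default $L = 80$, 1 mm voxels, carrying capacity $K = 2\times10^5$ cells
per voxel, 4-hour steps). Agents are *clonal populations per voxel*, not
cells: for each voxel, population and process, the number of successes among
$N$ cells is one binomial draw. Two populations compete; the aggressive one
divides and migrates faster by factors $v_{div}, v_{mig} \ge 1$ (defaults
1.8 and 1.925, i.e. 80% and 92.5% advantages). No mutation or phenotype
switching: composition changes only by differential growth.

The upstream model family defers the exact per-step probability forms to its
original implementation, so this package adopts and documents one reading:

* division: $p = v_{div}\, r_{div}\, \Delta t \,(1 - N_{tot}/K)$ — free-space
  limited;
* death: $p = r_{death}\, \Delta t \,(N_{tot}/K)$ — crowding-driven;
* migration: $p = v_{mig}\, D\, \Delta t / \Delta x^2$, migrants split
  uniformly over the 6 face neighbors.

Rates are per day (0.36, 0.144, 2.88 mm²/day). Probabilities must land in
$[0,1]$ *after* advantage scaling; at the 4-hour default step this caps
usable $v_{mig}$ near 2.08, and violating configurations fail at
construction rather than silently clamping. Boundaries are no-flux:
off-lattice migrants stay put. A migrant whose destination is full returns
to its source, so migration conserves cell number exactly and no voxel ever
exceeds $K$ (both are tested invariants; division successes are likewise
trimmed to the remaining capacity). All updates are computed from the
pre-step state and swapped in synchronously. Volume is
(total cells$/K$) × voxel volume — a voxel at capacity contributes exactly
its physical 1 mm³.

Treatment operators (`apply_treatment`) implement three post-radiosurgery
scenarios: total depletion of either clone, or a *balanced* reduction by
per-voxel binomial thinning to a target survival fraction and aggressive
share. The balanced defaults are a $10^{-4}$ overall survival (multi-log
radiosurgical cell kill) with the aggressive share reset to 10%: by the
time the default 1 cm³ trigger fires the aggressive clone dominates almost
completely, so only a deep kill leaves enough of the other population to
restore a mixed composition — larger survival fractions are rejected as
infeasible, which is the honest answer rather than a silent renormalization.

The growth exponent of a simulated trajectory (`beta_from_trajectory`)
follows the reference protocol: one uniformly random recorded point from
each third of the simulated time span forms a three-point record for the
solver, resampling (up to a budget) if the draw is not strictly growing.
For treated runs the post-treatment segment is used — the regrowth exponent
is the quantity of interest.

### What the simulator does and does not reproduce

With these probability forms, single-population dynamics behave as expected
(mean-field logistic agreement within Monte-Carlo error, decelerating
$\beta < 1$ regrowth after depletion of the dominant clone, capacity and
conservation invariants exact), and the balanced-treatment scenario lands
close to its reference exponent (~1.0). The headline *untreated* scenario,
however, does not reach its reference value of 1.53: with a 10-cell seed,
competition between clones differing by 80% in division rate is decided
within ~2–3 weeks, while the tumor is far below imaging resolution.
Thereafter the tumor is effectively homogeneous and the macroscopic
trajectory shows no succession signature: measured exponents cluster near
1.0. Back-of-envelope, an 8-month takeover at these rates requires the
*expressed* selection coefficient to be ~15× smaller than the bare rate
difference, which no local density-dependence can deliver for a well-mixed
microscopic seed — any free-growth phase completes the takeover first. The
reference implementation's unpublished probability forms (or a spatially
segregated, macroscopic initial state) presumably avoid this regime; lacking
them, the package keeps its documented forms and reports the discrepancy
openly: the corresponding acceptance assertions are left red by design, and
the advantage-sweep maximum is likewise flatter than its reference. The
treatment-scenario orderings that do not depend on a slow takeover are
reproduced.

## The synthetic cohort generator

The clinical dataset behind the reference analysis is not public, so
`generate_cohort()` provides the statistical stand-in that every pipeline
stage is validated against: per lesion it draws $\beta$ (truncated normal;
untreated-like preset centered at 1.5, treated-like at 0.65 — presets, not
reproductions of any table), a log-normal first-scan volume (median
~0.5 cm³), and two log-normal inter-scan gaps with medians 92.5 and 80.4
days (3.04 and 2.64 months, the typical follow-up cadence). The intake
coefficient $\alpha$ is *solved* from a drawn total fold-change
$F = V_2/V_0$ (log-uniform on $[1.5, 20]$) rather than drawn independently;
this guarantees every $\beta > 1$ lesion's scan window sits below its
blow-up time, makes the generated dynamic range interpretable, and leaves
ground truth exact. Volumes then get independent multiplicative uniform
noise (default 5%, the segmentation-error scale) and lesions violating the
strict-growth inclusion rule are redrawn, with the discard count reported.
Ground truth is attached as an attribute and written as a sidecar CSV by the
CLI, because parameter recovery is the acceptance surface standing in for
the non-public cohort.

`generate_mouse_series()` emulates the animal data: fixed measurement days
7–28, exponents centered at 1.44, a 0.4 cm³ ceiling after day 21 standing in
for the whole-brain volume constraint, and an injected late decrease in a
configurable fraction of animals to exercise the exclusion rule. The default
fold-change range (12–30× between days 7 and 21; doubling time roughly 3–4
days) was calibrated once so that the secant discretization bias of the
log-linear estimator stays within the ±0.05 recovery band on noiseless
series — small fold-changes, counterintuitively, bias the slope *up* by
more than large ones.

## Pipeline statistics

`run_cohort_analysis()` estimates one exponent per lesion (first three
strictly increasing scans), optionally filters by the perturbation screen,
and compares groups with a Kruskal–Wallis omnibus. Post-hoc pairwise
comparisons use Dunn's rank test with Holm adjustment — the conventional
follow-up to a significant Kruskal–Wallis when only "adjustment for multiple
comparisons" is specified; both the test and the adjustment are explicit,
deterministic choices. A Kolmogorov–Smirnov normality check is computed and
reported per group but never gates the nonparametric comparison (note the
usual caveat: with estimated mean and SD its p-values are conservative).
Groups with fewer than two usable lesions are dropped from comparisons with
a warning. The type-I error of the whole generate→estimate→test pipeline is
itself under test (rejection rate ≤ 7% at nominal 5% over 200 replications).

## Numerical and design notes

* Time is days and volume cm³ everywhere; no unit arguments.
* Solver bracket $[-5, 10]$ covers every exponent seen in any analysis
  here; canonical-curve triplets from deeply saturated regions can fall
  below it and are recorded as failures.
* `beta_from_trajectory` and all simulation code draw exclusively from R's
  RNG (also inside the C++ stepper), so a single `seed` makes an entire run
  bitwise reproducible.
* The advantage sweep derives per-grid-point seeds from the base seed, so
  the sweep is a pure map: re-running one grid point with its derived seed
  reproduces its entry exactly.
* When the initial aggressive share of a 10-cell seed would round to zero
  cells, the seed is raised to a 1000-cell floor so the share is
  representable (a 10-cell seed cannot express a 1% subclone).
* Acceptance-grade simulation checks run at a reduced 40³ lattice with
  scaled replicate counts; dynamics are bbox-limited, so the reduction
  affects memory and boundary margin, not the physics, while the tumor stays
  inside the domain.

## Known limitations

* The per-step probability forms are one documented reading of an
  unpublished reference; in-silico exponents are therefore matched in
  tolerance where the dynamics allow, and the untreated/sweep-maximum
  discrepancies are reported red rather than recalibrated away.
* The generator emulates marginal distributions and scan cadence, not
  patient-level covariates, radiologic artifacts, or segmentation bias
  structure; a green recovery test establishes estimator correctness, not
  clinical validity.
* No confidence intervals on $\beta$ (none are defined in the reference
  workflow), no $b > 0$ estimation, no image handling.
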