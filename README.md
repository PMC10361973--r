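# bmgrowth

Growth exponents and clonal dynamics of brain metastases.

Brain metastases (BMs) are followed with serial MRI, giving a handful of
volume measurements per lesion. `bmgrowth` asks a simple question of those
sparse series: *what is the shape of the growth curve?* The answer is the
exponent β of the Von Bertalanffy law

    dV/dt = α V^β        (maintenance term b ≈ 0 for growing lesions)

β = 1 is exponential growth; β > 1 is accelerating, "explosive" growth — the
macroscopic signature of ongoing clonal succession in a heterogeneous tumor;
β < 1 is decelerating growth, typical of recurrent lesions whose clonal
diversity was depleted by treatment. β is a shape, not a speed: two lesions
with the same β can grow at very different rates.

The package is aimed at mathematical-oncology and quantitative-imaging
groups who want to (a) estimate β from clinical three-scan or dense animal
series, (b) check how robust those estimates are to segmentation error, and
(c) explore the evolutionary mechanism in silico with a stochastic
voxel-lattice simulator of two competing clonal populations.

## What it provides

| Piece | Functions |
|---|---|
| Closed-form growth laws | `vb_params`, `vb_volume`, `canonical_curve` |
| β estimators | `solve_three_point_beta` (implicit 3-point equation), `fit_multipoint_beta` (log-linear fit for dense series), `sweep_group_beta` (best common β\* per treatment group) |
| Sensitivity analyses | `perturbation_screen` (±5% volume errors × 200), `curve_family_beta_distribution` (random triplets on canonical curves) |
| Mesoscopic simulator | `simulate_bm`, `apply_treatment`, `beta_from_trajectory`, `advantage_sweep` |
| Synthetic data | `generate_cohort`, `generate_mouse_series` (ground truth attached) |
| Pipeline & stats | `read_cohort_csv`, `run_cohort_analysis` (Kruskal–Wallis + Dunn/Holm), `bm_cli` |

The clinical dataset behind the reference analysis is not public; the
synthetic-cohort generator reproduces its statistical structure (per-group β
distributions, ~3-month scan intervals, ≤5% multiplicative volume noise) so
that every stage is validated by parameter recovery. Ground truth always
travels with the generated data.

## Worked example

```r
library(bmgrowth)

# synthetic cohort: 20 untreated-like lesions (beta ~ 1.5) vs 20 post-RT
# lesions (beta ~ 0.65), 5% volume noise, three scans each
coh <- generate_cohort(list(cohort_group_spec("untreated", 20),
                            treated_group_spec("RT", 20)),
                       noise_level = 0.05, seed = 7)
res <- run_cohort_analysis(cohort_table_from_series(coh),
                           sweep = TRUE, n_beta = 61, n_v0 = 150, n_v1 = 150)
res$group_summary
#>       group  n    q1 median   q3
#> 1        RT 20 0.395  0.584 0.77
#> 2 untreated 20 1.423  1.548 1.76
res$kruskal$p.value
#> 6.3e-08
sapply(res$sweeps, `[[`, "beta_star")
#> untreated 1.550, RT 0.750
```

The untreated group's median recovered exponent (1.55) and group-sweep
exponent (1.55) sit near the generating value 1.5; the treated group is
clearly sub-exponential; the omnibus test separates the groups decisively.

A single lesion, and its robustness to segmentation error:

```r
rec <- three_point_record(c(0, 92, 174), c(0.49, 1.31, 4.82))
solve_three_point_beta(rec)$beta
#> 1.350
perturbation_screen(rec, seed = 1)$passed   # |mean perturbed - 1.350| < 0.5
#> TRUE
```

In-silico growth of a heterogeneous virtual BM (10% aggressive clone with
80%/92.5% division/migration advantages, 80³ lattice — takes ~15 s):

```r
traj <- simulate_bm(sim_config(initial_aggressive_fraction = 0.1, seed = 42))
beta_from_trajectory(traj)$beta
```

## Command line

```sh
Rscript inst/cli/bmgrowth synth --out cohort.csv --n 30 --seed 1
Rscript inst/cli/bmgrowth estimate --input cohort.csv --outdir results --no-sweep
Rscript inst/cli/bmgrowth sweep --input cohort.csv --outdir results --n-beta 61 --n-vol 150
Rscript inst/cli/bmgrowth simulate --out traj.csv --treatment balanced --seed 1
```

Every run writes a `run.log` with its seed and configuration.

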