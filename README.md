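# sasconsensus

Tools for building a **consensus small-angle scattering profile** from
independently measured SAXS/SANS curves of one biomolecule, and for the
standard analyses used to vet and characterise the result.

## The problem

When the same protein is measured on many instruments — different
synchrotron beamlines, lab sources, neutron instruments, SEC or batch mode —
the buffer-subtracted 1-D profiles *I(q)* vs *q* differ by an arbitrary
multiplicative scale, by small additive background offsets left over from
solvent subtraction, by their q-grids and error levels, and occasionally by
gross outlier points or low-q contamination (aggregate, interparticle
interference). Combining them into one optimal curve requires putting all
datasets on a common footing and filtering what should not be averaged.

`sasconsensus` implements this combination: all profiles are re-gridded onto
a common q-scale, then per-dataset scale factors *a_j* and offsets *b_j* are
determined by Levenberg–Marquardt minimisation of the sum of all pairwise
error-weighted discrepancies

```
f = sum_{j<k} sum_i [ (a_j I_j(q_i) + b_j) - (a_k I_k(q_i) + b_k) ]^2
              / ( a_j^2 s_j^2(q_i) + a_k^2 s_k^2(q_i) )
```

with the gauge fixed by a reference dataset (a = 1, b = 0). Two optional
filters remove data that should not enter the average: a **modified Z-score
outlier filter** (Z = 0.6745 |x − MED| / MAD > 2, re-identified and refit
until the removal set is stable) and a **high-error filter** that keeps, at
each grid point, the ascending-error prefix minimising the propagated error
of the plain average. The consensus intensity is the unweighted mean of the
included scaled values; its error is `sqrt(sum a_j^2 s_j^2)/M`.

Around the combiner the package provides the standard SAS toolbox used to
vet the inputs and characterise the result:

- `auto_guinier()` / `guinier_fit()` — Guinier analysis (R_g, I(0)) with
  self-consistent window selection (q_max·R_g ≤ 1.3);
- `pr_transform()`, `refine_dmax()`, `background_check()` — regularised
  indirect Fourier transform P(r), integer-Å maximum-dimension refinement by
  the horizontal-tangent criterion, and the P(0)-release solvent-subtraction
  check;
- `porod_volume()`, `kratky_dimensionless()` — Porod invariant/volume
  (V_P = 2π² I(0)/Q) and the dimensionless Kratky transform
  (qR_g)² I(q)/I(0), which peaks near (1.73, 1.1) for compact globular
  particles;
- `scale_overlap()`, `merge_profiles()`, `merge_scan()` — splicing low-q
  (SEC / dilute) with high-q (concentrated batch) data, with an iterative
  q_min scan that detects low-q contamination from the concentrated data;
- `chi2_compare()`, `cormap_test()`, `compare_profiles()` — reduced χ² on
  pooled errors and the correlation-map test (exact fair-coin longest-run
  law, Bonferroni-adjustable);
- `sphere_profile()`, `ellipsoid_profile()`, `simulate_instrument()`,
  `contaminate()`, `simulate_campaign()` — a synthetic multi-instrument
  campaign generator with recorded ground truth, so every algorithm is
  testable without downloads.

A thin command-line wrapper is installed as `exec/sastool`
(subcommands `combine`, `guinier`, `pr`, `metrics`, `merge`, `compare`,
`simulate`), all dispatching to the exported `sas_cli()`.

## Worked example

```r
library(sasconsensus)

# a simulated 8-instrument campaign on a 20 A sphere (Rg ~ 15.5 A)
camp <- simulate_campaign(campaign_config(), master_seed = 7)
cons <- sas_combine(camp$profiles, qgrid(c(0, 0.5, 0.005)),
                    filter = "both", reference = 1)
print(cons)
#> Consensus of 8 datasets on 99 grid points (filter: both)
#>   scale/offset fit: f = 1298.77, 18 outer iteration(s)
#>   excluded points: 87 outlier, 329 high-error

g <- auto_guinier(cons$consensus)
print(g)
#> Guinier fit: Rg = 15.654 +/- 0.034 A, I(0) = 4.867 +/- 0.0043
#>   window: points 1..14 (q = 0.0075..0.0725), n = 14
#>   qmin*Rg = 0.117, qmax*Rg = 1.135, Pearson r = -0.99958
```

The recovered scales match the planted truth (median relative error of
`coef(cons)[, "a"]` is 0.099% in this campaign), the consensus Guinier R_g
of 15.65 ± 0.03 A sits about 1% above the sphere value sqrt(3/5)·20
= 15.49 A (the usual Guinier-window curvature bias at this data quality),
and the exclusion log records which instrument contributed each removed
point and why.

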