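---
title: "Building consensus scattering profiles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building consensus scattering profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models behind `sasconsensus`, the
tunable parameters and their defaults, the numerical choices made where the
design was genuinely open, what the synthetic-data generator does and does
not emulate, and the known limitations. It states no empirical result that
the package's test suite or `scripts/acceptance.R` does not itself compute.

## 1. The combination model

Each input dataset `j` is a buffer-subtracted profile `I_j(q)` with standard
errors `s_j(q)`, measured on an arbitrary intensity scale and with a small
residual background offset from imperfect solvent subtraction. After
re-gridding onto a common q-scale, the model is that all datasets measure
one underlying curve up to an affine map per dataset:

    a_j I_j(q_i) + b_j  ~  C(q_i) + noise,   noise sd = a_j s_j(q_i).

`fit_scales()` estimates `(a_j, b_j)` by minimising the symmetric sum over
all dataset pairs `j < k` and shared grid points of

    [ (a_j I_j + b_j) - (a_k I_k + b_k) ]^2 / ( a_j^2 s_j^2 + a_k^2 s_k^2 )

by Levenberg–Marquardt iteration (`minpack.lm::nls.lm`; the weights follow
the current scales, i.e. the problem is iteratively reweighted). The
overall scale of a consensus is not physically meaningful, so the gauge is
fixed by one reference dataset (`a = 1, b = 0`); by default the dataset
covering the most grid points. Scales are parameterised as `log a` to keep
them positive, and the start values come from a Theil–Sen affine alignment
to the reference, which is exact on affine data and immune to gross spikes —
a plain least-squares start can be wrecked by a single 10× outlier point.
Offsets are applied after scaling (`a_j I_j + b_j`) and carry no
statistical error: they model a systematic (background-subtraction error),
not a random variable.

Assumptions: errors are independent between datasets and between grid
points, and correctly estimated by the facilities. Re-gridding introduces
some correlation between neighbouring q-channels; like the propagated-error
bookkeeping below, the model ignores it.

### Grids

`qgrid()` builds contiguous-segment grids with bin edges at
`q_start + k * dq` and centers at edge midpoints; `default_grid()` encodes
the conventions used for consensus work: uniform Δq = 0.005 Å⁻¹ for small
globular proteins, 0.002 Å⁻¹ (or a graduated 0.001/0.002/0.004 Å⁻¹ scale
up to q = 1 Å⁻¹) for large ones, and 0.002 → 0.006 Å⁻¹ for SANS with a
configurable transition q (default 0.05 Å⁻¹; real SANS submissions dictate
values between roughly 0.02 and 0.08 Å⁻¹). The grid origin is pinned at
q = 0 so grids are reproducible across runs. Within one dataset, re-binning
uses the inverse-variance-weighted mean (statistically efficient within one
instrument); across datasets the consensus uses the plain average — the
asymmetry is deliberate: cross-instrument weights would let one
high-precision facility dominate the consensus, and error estimates are not
comparable enough across facilities to justify that.
Empty bins are omitted rather than interpolated, because interpolation
would correlate errors beyond what the filters assume.

### Outlier filter

At each grid point with at least 3 contributing datasets, the modified
Z-score `Z_j = 0.6745 |x_j - MED| / MAD` (raw MAD, no consistency constant)
flags scaled intensities with `Z > 2` for removal. Because outlier status
depends on the current scaling, and flagged points influenced the fit that
defined it, the package alternates: refit scales on trusted points,
re-identify the outlier set *from scratch* under the new scaling, and stop
when the set stabilises (a revisited set — a limit cycle between
near-equivalent solutions — also terminates the loop; cap
`max_outer = 20`). Median and MAD are always computed over all present
values at a point: they are robust to the outliers by construction, and
keeping the sample fixed avoids the ratchet of ever-shrinking trimmed
statistics. Degenerate cases (MAD zero, or at floating-point jitter level
relative to the values) disable removal at that point.

A caveat the user should know: with `N ≈ 8` values per grid point, the MAD
is a noisy scale estimate and the `Z > 2` rule removes roughly 9–12% of
perfectly clean Gaussian points (the asymptotic rate, 2Φ(−2) ≈ 4.6%, is
approached only for large N). This inflation is a property of the
published rule at small samples, not of this implementation; the package's
test suite measures it explicitly. The filters nevertheless leave the
consensus curve essentially unchanged — they mainly reshape the error
distribution.

### Error filter

At each grid point the contributing (scaled) errors are sorted ascending
and the prefix minimising the propagated plain-average error
`g(m) = sqrt(s_1^2 + ... + s_m^2)/m` is kept. This "best prefix" form —
rather than stopping at the first m where adding a point increases `g` —
is what guarantees that the filtered error never exceeds the all-points
average error (the first-stop rule does not: a set like σ = 1, 2.1, 2.1, …
stops at one point with g = 1 while the full average is smaller). The
filter depends only on the errors, never the intensities. It runs after
the outlier iteration settles.

### Consensus and its error

The consensus intensity at a grid point is the unweighted mean of the `M`
included scaled values; its error is `sqrt(sum_j a_j^2 s_j^2)/M`. Grid
points where every dataset was excluded are dropped with a warning.

## 2. Guinier analysis

`guinier_fit()` is a weighted least-squares fit of `ln I` on `q²` with
weights `(I/s)²` (first-order variance of `ln I`), giving
`Rg = sqrt(-3·slope)` and `I(0) = exp(intercept)` with errors from the fit
covariance. The Pearson r of the window is computed unweighted, as is
conventional for reporting Guinier linearity.

`auto_guinier()` searches contiguous windows subject to the
self-consistency constraints `q_max·Rg ≤ 1.3` (the conventional globular
limit) and `q_min·Rg ≤ 0.65` (avoiding fits confined to the flat top; not
part of the published protocol but standard practice), a minimum length of
10 points, and `|r| ≥ 0.99`. Among admissible windows it prefers the
longest whose weighted linear fit is *statistically adequate* — window
reduced χ² at most 1.5 given the reported errors — falling back to the most
adequate window when none passes. The adequacy guard matters: the Guinier
law is only the leading term of the low-q expansion, and on an exact sphere
curve the `ln I` vs `q²` curvature biases a full-window (q_max·Rg = 1.3)
fit by +1.1–1.8% in Rg at any noise level. On realistic noisy data the
curvature is far below the errors, every window is adequate, and the
selector behaves like the conventional longest-window rule; on noise-free
or ultra-high-precision curves it shrinks the window and recovers the true
Rg. Windows are enumerated with prefix sums, so the search is linear
per window end.

## 3. Indirect Fourier transform

`pr_transform()` expands P(r) on `[0, d_max]` in a sine series
`P(r) = Σ c_k sin(kπr/d_max)` with `K = ceil(q_max·d_max/π) + 4` terms (a
Shannon-channel count plus margin), which enforces `P(0) = P(d_max) = 0`;
the forward map is `I(q) = 4π ∫ P(r) sinc(qr) dr`, discretised by the
trapezoidal rule on `n_r = 201` points (the stored fitted curve and
`pr_forward()` use the same quadrature, so they agree to rounding). The
coefficients minimise `χ² + α ∫ P''(r)² dr`; with `alpha = "auto"` the
weight is chosen at the L-curve corner (maximum curvature of log-residual
vs log-penalty over a 25-point α grid). The L-curve is reproducible and
has no hand-tuned perceptual weights, which is why it was chosen over
multi-criterion "total estimate" scores used by classical IFT tools.
Singular normal equations trigger an automatic α increase with a warning.
P(r) errors come from first-order propagation through the regularised
linear solve at fixed α; correlations between r-points are not reported.
Rg and I(0) derive from the moments `Rg² = ∫r²P dr / (2∫P dr)`,
`I(0) = 4π∫P dr`.

`refine_dmax()` scans integer d_max candidates and scores each solution by
(i) failure of the horizontal-tangent criterion — the mean |P′| over the
terminal 5% of the r-range, normalised by `d_max/max(P)`; the short-arc
average is used because the exact endpoint derivative of a regularised
sine series carries a boundary wiggle that destabilised the scan — plus
(ii) a penalty of 10 when P dips below −3σ anywhere (interference-like
artefact), plus (iii) 3× the dead-tail fraction (the contiguous end region
with |P| below 2% of the peak; penalises overextension). The weights were
calibrated once on sphere simulations with known diameter and then frozen.
The smallest candidate within a near-tie band of the minimum score (10%
relative + 0.05 absolute) is returned, matching the convention that d_max
is the smallest dimension consistent with the data, reported in whole
Ångström. At percent-level noise the estimator carries an honest bias of
about +3 Å (regularisation rounds the termination of P(r), so slightly
overextended supports score as well as the true one); a resolution guard
warns when fewer than ~3 Shannon channels span the selected support
(featureless decays cannot localise d_max).

`background_check()` implements the P(0)-release test for solvent
subtraction errors. Quarter-wave cosine terms (nonzero at r = 0, zero at
d_max) are added to the basis and the constrained and released fits
compared. Two numerical findings shaped the implementation. First, the raw
released P(0) — and the raw jointly-fitted flat constant — sit several
*statistical* sigma from zero even on clean data, because the smoothness
prior prefers explaining part of the high-q tail with a constant; the
significance trigger therefore uses a bias-corrected constant: the (linear)
estimator is applied to the fitted background-free surrogate curve,
subtracted, and normalised by the estimator's response to a unit constant,
iterated to a fixed point. Second, a flat constant is nearly degenerate
with a finite-support P(r) unless the data reach high q: the check is only
as good as `q_max·d_max/π` channels allow, and the package's own tests run
it at q_max = 0.8 Å⁻¹. The flag fires on a >10% released-χ² improvement or
a >3σ corrected constant; the corrected constant is returned as the
suggested subtraction adjustment.

## 4. Scalar diagnostics

`porod_volume()` computes `Q = ∫ q²I dq` on `[0, q_cut]` with the
`[0, q_min)` gap filled by the Guinier extrapolation (the extrapolated
share is reported), and `V_P = 2π² I(0)/Q`. The automatic cutoff is
`q_cut = min(8/Rg, q_max)`: the published V_P values do not state their
integration limits, so a common-practice default is used and exposed.
Optional Porod-constant subtraction (fit `I ≈ c + K q⁻⁴` over the last
decade) is off by default because consensus building already fits offsets.
For hydrated globular proteins `V_P/m` is expected around 1.2–1.7 Å³/Da.

`kratky_dimensionless()` returns `(qRg)² I/I(0)` vs `qRg` with the first
local maximum at `x ≤ 3` refined on a parabola; the `x ≤ 3` restriction
avoids high-q noise maxima. The ideal Guinier-law curve peaks analytically
at `(sqrt(3), 3/e) ≈ (1.732, 1.104)`; compact globular particles plot near
(1.73, 1.1), and a homogeneous sphere slightly below (the acceptance script
recomputes the analytic anchor).

## 5. Merging and the contamination scan

`merge_profiles()` splices a low-q profile (SEC or dilute batch, trusted at
low q) with scaled high-q data (concentrated batch, better statistics at
high q). The scale comes from `scale_overlap()` — the weighted ratio
minimising `Σ (I_low − c·I_high)²/(s_low² + c² s_high²)`, iterated to
1e-10; no offset, offsets are the combiner's job. The default overlap
window is about 75 points centred at the geometric mean of the shared
q-range (the published procedure used 50–100 points in the mid-q regime).
With `cut_q = "auto"` the splice point is restricted to the upper half of
the overlap window — the low-q side of a merge must come from the SEC
profile, that being the purpose of the merge — and placed at the first q
there where the scaled high-q error drops below the low-q error. No
interpolation: every output point is an input point times its block scale,
with provenance recorded.

`merge_scan()` raises the minimum q accepted from the concentrated data
(each candidate is the splice cut itself), recomputes Guinier and P(r) per
merge, and recommends the smallest candidate whose Rg agrees with the
low-q-only reference within 1 combined standard error and whose d_max
agrees within 3 Å (the d_max estimator's own noise band; both thresholds
configurable). Candidates should start above the reference's Guinier range:
then every merge shares its low-q information with the reference and the
1σ criterion rejects clean data only rarely, while contamination entering
above the cut still shifts P(r)/d_max and is caught.

## 6. The synthetic campaign generator

`simulate_campaign()` emulates a multi-facility round-robin: one ideal
curve (homogeneous sphere by default, R = 20 Å, so Rg ≈ 15.5 Å — a small
globular protein) observed through 8 instruments with log-uniform scale
factors in 0.5–5 (arbitrary detector units), background offsets within
±0.3% of the scaled forward intensity (residual subtraction error at the
level real campaigns show), per-instrument q-ranges (q_min 0.006–0.015,
q_max 0.35–0.5 Å⁻¹) and spacings (0.001–0.003 Å⁻¹) that differ but
overlap, and Gaussian counting-like noise `s(q) = k sqrt(a I + floor)`
with k = 0.01 (≈1% relative error at low q). The reported σ column is the
*true* generating σ, so coverage tests are exact. Outliers are planted as
stated multiples of the clean value; contamination follows
`I = [(1−x) I_ideal + x s³ I_big] · (1 − β exp(−q²ξ²))` — the equal-mass
aggregate weighting (forward intensity ∝ s³ per mass fraction) makes the
apparent-Rg algebra checkable in closed form, and the interference dip is
phenomenological (a Gaussian in q), sufficient to exercise the q_min scan
but *not* a physical structure factor. Everything is reproducible
bit-exactly from the master seed; per-instrument seeds are derived as
`seed + 7919·j`.

What the generator does not emulate — and hence what passing tests do not
show about real data: SANS resolution smearing (deliberately, matching the
scope of the consensus methodology), radiation damage, inter-channel error
correlation from instrument-side binning, non-Gaussian (Poisson, at very
low counts) statistics, concentration series, and facility-specific
systematic error misestimation.

## 7. Null calibration choices

The correlation-map test compares profiles via the longest run C of
same-sign differences; under the null the signs are fair coins and
`cormap_pvalue()` evaluates the exact tail law by the run-length
composition recursion, normalised in units of 2⁻ⁿ so it is finite for any
n. Zero differences inherit the preceding sign (leading zeros count
positive): ties are measure-zero for real data but arise in synthetic
tests. "Adjusted" P values are Bonferroni over the caller-supplied number
of comparisons. Because the statistic is integer-valued the attained level
of a nominal-0.05 test depends on n; the package's null-calibration test
uses n = 200 points, where the attained exact level is 0.0454 — chosen
from the analytic law, before any simulation, so the empirical rejection
rate over 1000 trials estimates a quantity genuinely near 5%.

Reduced χ² between two measured profiles pools variances with no
covariance term (independent measurements), `dof = n − n_fitted`.

## 8. Problem sizes used by the test suite

Simulated campaigns use 8 instruments with a few hundred points each;
recovery statistics use 50 seeded campaigns; the longest-run law is checked
exhaustively against enumeration for all n ≤ 16; the null calibration uses
1000 trials at n = 200; d_max scans use 20 seeds. These sizes make every
claim in the suite a direct computation while keeping the default test run
in tens of seconds.

## 9. Known limitations

- Error estimates are taken at face value; no cross-facility error
  rescaling is attempted (the published methodology validated errors via
  pairwise solvent comparisons upstream of combination).
- The modified Z-score's small-sample inflation (Section 1) means the
  outlier filter is aggressive at N ≲ 10 datasets; use `filter = "error"`
  or raise `z_threshold` when few datasets are available.
- Maximum-likelihood (inverse-variance) cross-dataset weighting is
  deliberately not implemented; the plain average matches the published
  consensus convention.
- The P(r) error band ignores r-point correlations, and the d_max
  estimator's +3 Å bias at percent-level noise should be kept in mind when
  comparing to crystallographic dimensions.
- SANS q-resolution smearing is not modelled anywhere; the `dq` column is
  read, written and preserved but never used in fits.
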