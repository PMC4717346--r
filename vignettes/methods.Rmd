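---
title: "Models and methods in urbanfelid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in urbanfelid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanfelid)
```

# The analysis problem

Camera traps record time-stamped photographs of species at fixed sites.
Two inferential targets drive this package: whether a dominant carnivore
(species A) alters where and how often a subordinate carnivore (species
B) uses the landscape, and whether the two species partition the 24-h
day. Both must be estimated through an imperfect observation process —
a species can use a site without being photographed — which is why the
package is built around occupancy models with explicit detection
probabilities rather than raw count comparisons.

# From photographs to detection histories

Raw photographs overcount behaviour: an animal lingering at a camera
fires many frames. The independence rule collapses them: within a site
and species, a photograph starts a new *event* only if more than 60
minutes (`window_minutes`, configurable) have passed since the most
recent **retained** event, or it shows a different marked individual.
Two choices here were genuinely open:

* *Reference point.* Independence is assessed against the last retained
  event, not the last raw photograph. Chaining on raw photographs would
  let a burst of sub-hour frames suppress detections indefinitely;
  anchoring on retained events bounds the suppression at one window and
  makes the filter idempotent (filtering twice changes nothing, which
  the test suite checks).
* *Boundary.* Exactly 60 minutes apart is *not* independent: the rule
  is read strictly as "more than".

Daily occasions run noon-to-noon (`day_boundary = "12:00"`), so the
crepuscular and nocturnal activity of both felids falls within a single
occasion rather than being split at midnight. Occasion `d` covers
`[day_d 12:00, day_{d+1} 12:00)`; one occasion per calendar day of the
configured survey window. The number of occasions is always derived
from the configured window — it is not hard-coded. (In the motivating
study's first survey, the published window spans 115 calendar days
while the published occasion count is 113; whether deployment was
staggered or days were trimmed is not recoverable, so the window is a
user decision and the package simply counts the days it is given.)

Effort for a daily occasion is 1 if the camera was active during any
part of the noon-to-noon interval, else 0; pooled effort is the sum of
daily efforts (operating days). Cells without effort are *missing*, not
zero, and contribute no factor to any likelihood. Pooling length `L`
collapses blocks of `L` days by max-with-data; trailing remainder days
are dropped (113 daily occasions at `L = 22` give 5 pooled occasions
with 3 days dropped), which is the documented default rather than
truncating or extending the final occasion.

Timestamps are treated as naive local clock time throughout; there is
no time-zone or solar-time conversion.

# Covariates

**Human development (HD).** Each human structure contributes a
truncated Gaussian kernel centred on its location: influence is 1 at
the structure, decays with `sigma = radius / 3`, and is exactly zero
beyond the radius. Site values sum over structures. The original GIS
workflow's absolute density normalization is not recoverable, so only
relative values are meaningful; HD always enters models standardized,
which makes the unknown scale constant irrelevant. Both the kernel
family and the sigma rule are arguments. The spatial scale (radius, in
metres) is chosen by fitting one univariate detection model per
candidate radius and taking the AICc minimum (`select_scale()`), with
exact ties broken toward the smallest radius and flagged.

**Lag indicators (P1–P4).** `Pk[i, t] = 1` if the dominant species was
detected at site `i` on any of days `t - k + 1, ..., t`: the window is
the detection day plus `k - 1` *following* days (forward in time),
windows from multiple detections union, and windows truncate at the
survey end. `P1` is the dominant species' daily history itself. The
matrices nest (`P1 <= P2 <= P3 <= P4`), which is a tested invariant.
Same-day ordering is ignored — the occasion is the atomic unit, so a
dominant and subordinate detection in the same occasion both count for
that occasion.

**Standardization.** Continuous site covariates (HD, PumaCount) are
z-scored with the *population* standard deviation (the z-scores of
{1, 2, 3} are ±1.2247); binary columns are untouched; the transform is
stored so logit-scale coefficients can be mapped back. Because the
original analysis software's internal scaling is unknown, raw
coefficient magnitudes are not comparable across implementations; signs
and relative magnitudes are.

# Single-species occupancy

The single-season likelihood for site `i` over occasions `t`:

$$L_i = \psi_i \prod_t p_{it}^{y_{it}} (1-p_{it})^{1-y_{it}} + (1-\psi_i)\, I(\text{no detection at } i),$$

with logit links on both parameters (the standard choice for this model
family; the source analysis does not state its link). Occupancy is
intercept-only in the motivating design; detection mixes site
covariates, occasion covariates and product interactions (`G*P3` is the
elementwise product of the 0/1 columns).

Fitting is BFGS from five starts (one at zero, four jittered with sd
0.5 from a private RNG stream, so results do not depend on the caller's
RNG state), relative tolerance 1e-10, standard errors from the inverse
observed information (numerically differenced Hessian). Convergence
requires the optimizer's own flag plus a positive-definite Hessian; a
boundary flag is raised when the occupancy estimate exceeds 0.99
(saturated data), where the information matrix is unreliable. With
complete avoidance in the data the lag coefficient separates
(detection probability exactly 0 inside windows); the logit-scale
estimate then runs to a large negative value with a huge SE. This is
expected, matches the behaviour reported for the field data, and is why
the package's recovery checks use likelihood-ratio tests and
coefficient signs rather than Wald intervals.

Detection-probability predictions use the delta method on the logit
scale and back-transform, keeping intervals inside (0, 1).

# Conditional two-species occupancy

The joint model sums four latent states with conditional occupancy
probabilities (`psiA`, `psiBA`, `psiBa`) and a detection kernel in
which, when both species are present, B's detection is `rBA` on
occasions where A was detected and `rBa` otherwise — occasion-level
conditioning, the standard reading of "given pumas are detected".
Constraint sets (`psiBA = psiBa`; `pB = rBA = rBa`; `rBA = rBa` with
`pB` free; all free; optionally `pA = rA`) map deterministically to the
free-parameter list: `K` is one parameter per occupancy group plus, for
each detection group, one intercept and one slope per covariate, slopes
shared within an equality group and separate across groups.

Two structural facts anchor the implementation and are tested by
enumeration: the site likelihood sums to one over all `2^(2T)` joint
histories, and with everything shared (`psiBA = psiBa`, `pA = rA`,
`pB = rBA = rBa`) the joint likelihood factors *exactly* into the
product of the two single-species likelihoods, so the fitted `-2 log L`
equals the sum of the marginal fits to optimizer precision.

Conditional-detection models (`pB` free) lose identifiability when the
dominant species' occupancy estimate reaches 1: no sites remain that A
"does not occupy", so `pB` carries no information. The fit records a
degenerate-dominant flag (threshold 0.99, configurable, or a singular
information matrix), and flagged conditional models are excluded from
ranking with an audit trail — mirroring how such non-convergent models
were handled in the motivating analysis.

# Model selection

`AICc = -2\log L + 2K + 2K(K+1)/(n - K - 1)`, falling back to plain AIC
with a warning when `n <= K + 1`. The effective sample size `n`
defaults to the number of sites (40 in the motivating design) —
standard occupancy practice; the source does not state its choice — and
is an argument everywhere. Akaike weights are
`exp(-Delta_i/2) / sum_j exp(-Delta_j/2)`; ties are broken by smaller
`K`, then label order, and flagged.

Two quirks of the published comparison tables are documented rather
than matched. First, the broad-scale table for the more rural study
area prints weights (0.45, 0.27, ...) that disagree with weights
recomputed from its own printed Delta column (~0.41, 0.25, ...) and sum
to more than 1; the other three tables reproduce to printed rounding,
so recomputed weights are treated as authoritative. Second, one printed
`K` (12, for a conditional-occupancy model with grid on all detection
parameters and `rBA = rBa`) is one larger than the counting rule that
reproduces every other row; the package's counter follows the rule.
Relatedly, the published "log(L)" column equals `AICc - 2K` exactly,
which is an AIC-style back-calculation rather than a small-sample
log-likelihood; the package reports `-2 log L`, AIC and AICc explicitly
instead of reproducing that column.

# Circadian activity overlap

Activity times map to radians as `2*pi * seconds-since-midnight /
86400`. The density estimate is a von Mises kernel average with
concentration from the plug-in rule
`kappa* = (3 n kappa^2 I_2(2 kappa) / (4 sqrt(pi) I_1(kappa)^2))^(2/5)`
at the sample's ML concentration, divided by an adjustment constant.
The ML concentration uses Fisher's closed-form piecewise approximation
to the solution of `A(kappa) = Rbar` — its error (~1%) is far below
bootstrap noise and avoids a root-finder in the bootstrap's hot path.

The overlap coefficient `Delta = ∫ min(f, g)` has two estimators: the
grid-based form (512-point grid, adjustment 0.8) and the point-based
form (density ratios at the pooled sample points, adjustment 1), with
the conventional automatic switch at a smaller-sample size of 75. The
motivating study's per-comparison sample sizes straddled that
threshold and its choice per comparison is not recoverable, so the
variant is an explicit argument with `"auto"` as default.

Confidence intervals use a smoothed bootstrap — resample a data point,
add von Mises kernel noise — with the percentile interval shifted by
the bootstrap bias (`basic0` style) and clipped to [0, 1]. 10,000
replicates match field practice; the package's own validation uses
1,000, which is ample for 95% intervals.

`interval_overlap_metrics()` compares two interval estimates by the
width of their intersection divided by the mean interval width, and by
the mean half-width (margin of error) — exactly twice the former.
These two definitions jointly reproduce both published comparison pairs
(16%/32% and 97%/complete), which is how they were validated.

# What the synthetic generator does and does not emulate

`sim_config()` defaults encode the motivating design: two grids
(urbanized, wildland) of 20 sites on 2 × 2 km cells, a 92-day
October–December survey, latent occupancy psiA = 0.6,
psiBA = psiBa = 0.9, and daily detection intercepts (dominant 0.04;
subordinate 0.15 urbanized / 0.12 wildland) chosen so survey-length
statistics land in the observed ranges — naive occupancy near the
published values and 0–8 dominant events per site. The avoidance
mechanism multiplies B's daily detection probability by `s` for `l`
days starting at each A detection, wildland only, with `s = 0`,
`l = 3` as the focal scenario: suppression acts on detection
(frequency of use), not on latent occupancy, matching the behavioural
interpretation of detection in this model family. Activity times are
bimodal von Mises mixtures (subordinate peaks 06:00/20:00; dominant
evening/nocturnal 21:00/02:00); photo bursts add sub-hour frames with
probability 0.25 to exercise the independence filter; structures
follow a homogeneous Poisson process with intensity 3/km² (urbanized)
vs 0.05/km² (wildland).

Not emulated: animal movement and home ranges (timestamps are
independent across days), abundance-driven detection heterogeneity,
spatial autocorrelation between sites, seasonal trends in activity, and
camera failures (deployments default to full effort; the effort
machinery is exercised through explicit deployment tables instead).
Passing tests therefore demonstrate that the estimators recover the
generative structure they assume — not that real surveys satisfy those
assumptions.

# Validation scale and numerical choices

The test suite enumerates likelihood normalization for histories up to
T = 3 (1,000 random parameter draws), checks the exact factorization
identity to 1e-6 on fitted values, and runs survey-scale recovery: 30
replicates of 40 sites × 92 days per condition, detecting the lag
effect by a 2-df likelihood-ratio test. Power under `s = 0, l = 3` is
required to exceed 0.5 (it is near 1 in practice) and the false-positive
rate under `s = 1` must be statistically consistent with the nominal 5%
(one-sided 99% binomial bound). Overlap estimation is validated against
numerical integration of the true von Mises densities (error ≤ 0.05 at
n = 1000) and by CI coverage over 200 simulated pairs at n = 75 and
1,000 bootstrap replicates, required to be statistically consistent
with ≥ 90%. These problem sizes are the package's chosen validation
scale; all are arguments and scale up directly.

Numerical details worth knowing: likelihood products are computed in
log space with probabilities floored at 1e-300 before the final log;
the von Mises normalizer uses exponentially scaled Bessel functions so
large concentrations do not overflow; optimizer starts and bootstrap
draws run in private RNG streams so seeded results are reproducible
without touching the caller's RNG; and `Inf` is a valid AICc sample
size (recovering plain AIC).

# Limitations

Single-season models only — no dynamic occupancy, no Bayesian fitting,
no spatial autocorrelation corrections, and no species-interaction
factor reparameterization of the co-occurrence model. The kernel
density for development assumes projected planar coordinates in metres.
Published headline parameter estimates that depend on the unavailable
raw field data (e.g. the occupancy point estimates) are out of reach by
construction; what the package reproduces is everything derivable from
printed inputs, plus the statistical behaviour of the estimators under
the generative model the field design implies.
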