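---
title: "Methods: step selection and the energetic cost of transport in stepcot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step selection and the energetic cost of transport in stepcot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package estimates

`stepcot` implements a two-part analysis of terrestrial dispersal tracks:

1. **Habitat selection** by step-selection analysis (SSA): each observed
   5-minute movement step is matched with 20 alternative steps the animal
   could have taken, and a conditional logistic regression on the matched
   sets estimates, per habitat feature and movement stage, the relative
   selection strength (RSS) — the relative probability of choosing a
   location with that feature over the reference, given equal
   availability.
2. **Energetic efficiency** as the cost of transport (CoT, J kg⁻¹ m⁻¹):
   1 Hz tracks are cut into 50 m net displacements; each second inside a
   displacement is costed with a speed- and incline-dependent oxygen
   consumption model; the summed energy divided by the realised
   displacement distance is the CoT, compared across habitats per stage
   with linear models.

Because desk-scale work cannot use the original multi-month GPS dataset,
the package ships a first-class synthetic generator whose landscapes and
walkers have *known* (planted) selection coefficients, movement kernels
and habitat-dependent speeds. Every downstream stage is tested against
those planted truths.

# The movement and selection model

## Five-minute steps

A track is divided into consecutive 5-min windows anchored at its first
fix. Steps with net displacement below 10 m are dropped, so the model
reflects *where* the animal moved rather than the timing of inactivity.
A retained step has a turning angle only if its immediate predecessor
window was also retained; a dropped window breaks the angle chain, and
such steps contribute strata whose alternatives use length-only sampling
with uniform direction. Dropping sub-threshold windows does not shift
the window grid (the grid stays anchored to the first fix); this
resolves an ambiguity in how "the next time point" starts a new step and
is recorded in the step table's metadata.

## Movement kernels and alternative steps

Per individual and movement stage (resident, local transience, active
dispersal), step lengths get a gamma MLE and turning angles a von Mises
MLE (mean direction estimated by default; a `fix_mu` switch constrains
it to zero, the other common convention). Keys with fewer than 30 steps
fall back to stage-pooled fits and are flagged. Each observed step then
receives `m = 20` alternatives drawn from its kernel; endpoints falling
off the raster are resampled up to 100 times, after which the stratum
keeps fewer controls (logged). Resampling preserves the kernel's
interior shape without inventing an edge-truncation model.

## Conditional logistic regression

The estimator maximises the stratified conditional likelihood

$$\prod_{\text{strata}} \frac{e^{\beta^\top x_{\text{case}}}}
{\sum_j e^{\beta^\top x_j}}$$

by Newton–Raphson with analytic gradient and Hessian: start at
$\beta = 0$, step-halving line search (the log likelihood is concave, so
ascent is guaranteed), convergence when the maximal score component
falls below 1e-8 or the log-likelihood change below 1e-10, at most 50
iterations. Covariance is the inverse observed information; Wald z, p
and 95% intervals follow. Perfect separation is detected as a
coefficient exceeding 15 in absolute value and reported as a divergent
fit rather than silently returned. Covariates constant within every
stratum cancel from the likelihood; `fit_clr` refuses them as rank
deficient, while the pipeline-level wrapper drops them (and aliased
columns) with a message, because at desk scale some covariate-stage
combinations are genuinely inestimable.

Three design variants mirror the standard modelling choices: nested
within-stage coefficients (selection vs. 0 per stage), resident-referenced
interactions (difference from residents), and a two-level
transient/resident variant. Stage main effects are absorbed by the strata
and therefore omitted. Terrain ruggedness enters z-scored over the
endpoints used in the analysis; binaries enter as 0/1; cover enters as
dummies against the scrub reference. After an initial fit, steps in
habitats unused by the reference animals (black cotton, bare soil) can be
removed post hoc: strata whose *case* sits in a dropped class are removed
whole (a case cannot be compared without itself — the one coherent
reading of "remove all steps"), alternatives in dropped classes are
removed from surviving strata, and strata left with fewer than two steps
are discarded. All counts are logged.

# The energetics model

Oxygen consumption (ml O₂ kg⁻¹ min⁻¹) while moving is linear in speed
with incline-specific constants: 24.0·v + 27.2 on level terrain,
30.7·v + 27.6 at 10% incline, 47.7·v + 21.3 at 20% incline; stationary
birds consume a flat 19.1. Energies convert at 20.1 J ml⁻¹ O₂. The
experienced slope is `θ' = atan(tan θ · cos Δψ)` where Δψ is the angle
between the *upslope* aspect and the movement bearing — the package
stores aspect as the upslope direction precisely so that Δψ = 0 means
climbing and downhill grades come out negative. Percent grade
(100·tan θ') is binned: below 5% (including all downhill) level, 5–15%
the 10% incline, 15–25% the 20% incline. Grades of 25% or more would
round to an incline with no measured relationship and raise an error;
the synthetic DEM is calibrated so they cannot occur.

Two numerical caveats are worth knowing. First, the measured 10% and 20%
lines cross at v = 6.3/17 ≈ 0.37 m/s (the 20% line has the *lower*
intercept), so energy is monotone in incline class only above that
speed; the package reproduces the published constants rather than
"fixing" them. Second, for constant-speed level movement CoT(v) =
((24v + 27.2)/60 · 20.1)/v, strictly decreasing in v — faster movement
is cheaper per metre, which is the premise the whole analysis rests on;
the pipeline reproduces this closed form to 1e-9 on constructed tracks.

## Movement states

Whether a second is costed as moving or stationary comes from a 4-state
hidden Markov model on 10 s step lengths (gamma emissions) and turning
angles (von Mises), fitted by EM with scaled forward–backward recursions.
Five seeded random starts with randomised quantile anchors are
pre-iterated ten EM steps and the best continued to convergence — the
random anchors matter, because they let the starts explore different
allocations of states to the length distribution (one slow + three fast
vs. two + two). States are relabelled ascending by mean step length with
ties broken by decoded occupancy (so a fully stationary track decodes to
state 1, not an arbitrary duplicate); states 2–4 count as moving. Each
second inherits its 10 s window's Viterbi state. On tracks longer than
20 000 windows, parameters are estimated on the leading contiguous block
of that size and decoding uses everything, keeping EM cost bounded. The
pipeline fits one HMM per individual.

## Displacements and CoT models

Net displacements close at the first 1 Hz fix at least 50 m from the
segment start; the realised distance (slightly above 50 m due to
discrete sampling) is the CoT denominator. Displacements never span gaps
in 1 Hz coverage, and unclosed tails are discarded. A displacement is
labelled `road` when both endpoints sit on road cells (roads override
the cover they cross), otherwise with the shared endpoint cover, and is
excluded when the endpoints disagree. Per stage, `CoT ~ habitat` is fit
by ordinary least squares with roads as the reference level, plus all
pairwise Wald contrasts. OLS was chosen over a mixed model as the
default because the per-stage question is a fixed contrast of habitat
means; with few synthetic individuals a random intercept is barely
identified (the source material itself is ambiguous between the two).

# The synthetic world

The generator emulates a semi-arid savannah: five cover classes from a
thresholded smoothed Gaussian field (scrub dominant, a coherent
black-cotton block, glades and bare-soil patches), straight unpaved-road
transects 15 m to either side of a centre line, a river with a 15 m
water buffer inside a 30 m riverine strip, and a smooth DEM (default
8 km × 8 km at 10 m, relief 60 m over ~900 m correlation length,
keeping maximal grades under 25%). Roads occupy well under 3% of cells
at the default config — rare linear features, as in the study system the
package emulates.

Walkers take 5-min steps: candidate endpoints (50 per decision) are
drawn from the stage's gamma/von Mises kernel and one is chosen with
probability ∝ exp(βᵀx) — the standard SSA-consistent mechanism, so the
conditional logistic regression is estimating exactly the planted β.
Defaults plant the qualitative pattern of interest: active dispersers
select roads strongly (+1.5) and glades moderately; residents avoid
roads (−0.5); everyone mildly avoids riverine strips and rugged terrain.
Magnitudes are larger than a field study would report because desk-scale
strata counts (~10⁴, not ~6×10⁴) need detectable effects; tests assert
signs and orderings, not the inflated magnitudes.

Three further mechanisms make the world behave like its real
counterpart, and each is a documented choice:

* **Day-goal drift** (active days only): candidate weights gain
  `exp(0.8·cos(bearing − goal))` toward a random central goal point.
  Without it, boundary reflection turns large daily paths into small net
  displacements and no day would classify as active dispersal. Resident
  and local days instead get an afternoon roost-return attraction.
* **Habitat-speed step scaling**: the step-length kernel is scaled by
  `speed(habitat at start)/0.45`; road steps are about twice scrub
  steps. Because the scaling is stratum-constant it cannot bias the
  selection estimates, but it is what makes per-second road movement
  genuinely faster.
* **Habitat-neutral resting**: each step is walked in the first
  `1 − U(0.1, 0.4)` share of its 5 minutes (lateral wiggle per habitat:
  1 m on roads, 8 m in scrub) and the bird then stands at the endpoint.
  Drawing the resting fraction independently of habitat is essential:
  if fast habitats simply finished the same step earlier and rested
  longer, the extra stationary seconds would cancel the speed advantage
  and the road/scrub CoT contrast would invert, which is exactly what an
  earlier design of this generator did.
* **Road persistence**: the turning-angle concentration is multiplied by
  6 when a step starts on a road, making road movement straighter and
  letting multi-step road-following bouts emerge (without which
  road-labelled 50 m displacements are vanishingly rare).

What a green end-to-end test establishes is therefore directional and
structural: planted signs and orderings are recovered, filters count
correctly, the CoT closed form holds. It does not establish the
magnitudes a real dataset would give, GPS measurement error (not
simulated), canopy-driven fix loss, or behaviour at habitat boundaries
finer than the 10 m grid.

# Numerical and degenerate-input policy

* Half-open raster cells `[x0, x1) × [y0, y1)`, row 1 north; point
  lookup by floor division. No interpolation anywhere.
* Walkers reflect at the landscape boundary (absorbing edges would bias
  selection estimates near borders).
* Days missing a first/last fix within 30 min of the tag duty cycle are
  excluded from classification; the settlement rule uses a 200 m roost
  radius over 14 days (the radius is a package choice — some tolerance
  is needed to make "same roosting site" operational).
* Stationary 10 s windows produce zero step lengths; they are floored at
  0.05 m to stay inside gamma support, and an EM state collapsing onto
  that constant is represented by a sharply peaked gamma rather than a
  failed fit.
* The total daily path length used in the straightness index sums over
  all available fixes of the day (mixed resolutions included); this is
  one of two defensible readings and is flagged in the output metadata.

# Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_step` | 10 | m | drops stationary 5-min windows |
| `m` | 20 | steps | alternatives per stratum |
| `d_hard`, `d_soft`, `s_min` | 1500, 1200, 0.3 | m, m, – | active-day rules |
| `settle_window`, `settle_radius` | 14, 200 | d, m | settlement rule |
| `disp_radius` | 50 | m | net-displacement closure |
| `hi_res_hours` | 4.5 | h | tag battery limit for 1 Hz bouts |
| grade bins | 5, 15 (cap 25) | % | measured incline classes |
| `n_candidates` | 50 | – | generator candidate pool |

# Known limitations

No GPS error model; no continuous-time SSA or movement-kernel
covariates in the linear predictor (habitat covariates only, as in the
analysis this mirrors); no substrate-dependent energetic terms and no
downhill-savings model; no reprojection (all layers share one grid); no
robust/clustered standard errors by default (individuals are pooled in
one conditional model; a flag exists for per-individual cluster-robust
SEs in the CoT models only).
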