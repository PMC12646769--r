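# stepcot

Step-selection analysis and cost-of-transport energetics for terrestrial
dispersal tracks.

## The problem

Dispersing terrestrial animals must cover distances far beyond their
daily norm, and field evidence shows they do it partly by *choosing
where to walk*: open, linear features such as unpaved roads permit
faster, straighter — and therefore energetically cheaper — movement.
Testing that idea from GPS tracking data takes two coupled analyses:

1. **Habitat selection** via step-selection analysis (SSA). Each
   observed 5-minute step is matched with 20 alternative steps drawn
   from the animal's own movement kernel (gamma step lengths, von Mises
   turning angles), and a conditional (fixed-effects) logistic
   regression on the matched case–control strata estimates the relative
   selection strength
   `RSS = exp(β̂)` per habitat feature and movement stage
   (resident / local transience / active dispersal). The estimator
   maximises the stratified conditional likelihood
   `∏ exp(β'x_case) / Σ_j exp(β'x_j)` by Newton–Raphson, with Wald
   inference from the inverse observed information.
2. **Energetic efficiency** as the cost of transport
   (CoT, J kg⁻¹ m⁻¹). 1 Hz tracks are cut into 50 m net displacements;
   each second is costed from speed `v` and experienced incline using a
   walking-bird respirometry model (`VO₂ = 24.0v + 27.2` on the level,
   `30.7v + 27.6` at 10% grade, `47.7v + 21.3` at 20%, stationary rate
   19.1 ml O₂ kg⁻¹ min⁻¹, 20.1 J ml⁻¹ O₂), with moving/stationary
   seconds decided by a 4-state hidden Markov model on 10 s steps and
   the experienced slope `θ′ = atan(tan θ · cos Δψ)` from a DEM. Summed
   energy over realised distance gives the CoT, compared across
   habitats per stage by linear models with roads as the reference.

Everything runs end-to-end on a built-in synthetic generator
(landscapes, DEMs, dual-rate GPS walkers with *planted* selection
coefficients), so the whole pipeline is testable without any field
data. See `vignettes/stepcot-methods.Rmd` for the model details and the
generator's assumptions.

## Who it is for

Movement ecologists who want a transparent, dependency-light R
implementation of the SSA + locomotion-energetics workflow, and method
developers who need a ground-truthed sandbox where the true selection
coefficients are known.

## Worked example

```r
library(stepcot)

L <- generate_landscape(landscape_config(n_cells = 400, seed = 1))
round(L$road_fraction, 4)
#> [1] 0.0604

w  <- walker_config()   # planted betas: active road +1.5, resident road -0.5
tr <- simulate_track(L, w,
        c("resident", "active_dispersal", "local_transience",
          "active_dispersal"), individual = "disp01", seed = 42)
d  <- emit_dual_rate(tr, hi_res_hours_per_day = 4.5)

ds <- day_summaries(d, resident = FALSE)
ds$classification
#> [1] NA  "active_dispersal"  "local"  "active_dispersal"
```

Day 1 has no previous roost, so it cannot be classified; the two
large-displacement days (roost-to-roost D = 2138 m and 4995 m) classify
as active dispersal, the D = 180 m day as local prospecting — the
planted schedule, recovered from the track alone.

```r
st <- discretize_5min(d)            # 5-min steps, 10 m filter
c(attr(st, "n_windows"), attr(st, "n_retained"))
#> [1] 624 573

fit_step_distributions(st)[, c("stage", "shape", "scale", "kappa")]
#>              stage shape scale kappa
#> 1 active_dispersal  1.92  45.4  2.12
#> 2 local_transience  1.91  45.4  0.45
#> 3         resident  1.79  35.3  0.41
```

The fitted movement kernels separate the stages: active-dispersal days
have longer steps and much more directional persistence (kappa 2.1 vs
0.4).

The full pipeline (7 birds, 12 days, 8 km landscape; ~2–3 min):

```r
res <- run_pipeline(pipeline_config(seed = 1))
rs <- res$fits$within_stage$rss
rs[grep("road", rs$term), c("term", "estimate", "p")]
#>                     term   estimate            p
#>            road:resident -0.5023980 1.710811e-02
#>    road:local_transience -0.0951805 6.194705e-01
#>    road:active_dispersal  0.8954778 1.589548e-11
```

Actively dispersing birds select roads (RSS = exp(0.895) ≈ 2.4) while
residents avoid them — the planted pattern, estimated through day
classification, kernel fitting, alternative-step generation and the
conditional-logistic engine. And the energetics side:

```r
res$cot$active_dispersal$coefs[1:2, c("term", "estimate", "p")]
#>           term  estimate            p
#>    (Intercept) 32.309918 7.221879e-10
#>   habitatscrub 13.613943 1.272576e-02
```

During active dispersal the CoT on roads is ~32 J kg⁻¹ m⁻¹ and moving
through scrub costs ~14 J kg⁻¹ m⁻¹ *more* per metre — the road
advantage the habitat-speed mechanism plants, recovered at the end of
the displacement/HMM/incline/energy chain.

## Command line

```sh
inst/exec/stepcot simulate  --config cfg.json --seed 1 --out-dir out/
inst/exec/stepcot run-all   --config cfg.json --seed 1 --out-dir out/
inst/exec/stepcot ssa-fit   --strata out/strata.csv --variant within_stage
inst/exec/stepcot energetics --tracks out/tracks.csv --landscape out/landscape
inst/exec/stepcot report    --manifest out/manifest.json
```

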