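# coneSpec

Stochastic simulation of thyroid-hormone-gated cone photoreceptor
specification in human retinal organoids.

## The problem

Developing retinas generate their photoreceptor subtypes in a fixed temporal
order — S (blue) cones before L/M (red/green) cones — and do so reproducibly
despite large organoid-to-organoid variation in starting progenitor numbers.
The timing signal is thyroid hormone (T3): retinal progenitor cells (RPCs)
express DIO3, the T3-degrading deiodinase, so T3 stays low while progenitors
are abundant and rises as they differentiate away. The shrinking progenitor
pool is the clock ("hourglass" feedback). `coneSpec` is for modelers and
quantitative biologists who want to simulate this feedback, compare it
against a probabilistic cell-intrinsic alternative, and reproduce the
DIO3-mutant and exogenous-T3 perturbations in silico.

## The model

Seven cell classes (RPC; immature and mature S and L/M cones; S/L/M
coexpressing cones; lumped non-cone fates) and seven stochastic events:

    RPC --f(T3)--> immature S        f(T3) = λ_S T3 / (K_S + T3)
    RPC --g(T3)--> immature L/M      g(T3) = λ_L T3 / (K_L + T3),  K_S < K_L
    RPC --λ_N----> non-cone
    immature S  --μ_S--> mature S          immature S  --g(T3)--> coexpressing
    immature L/M --μ_L--> mature L/M       immature L/M --f(T3)--> coexpressing

coupled to one deterministic concentration:

    dT3/dt = σ_basal + σ_exo·[t ≥ t_exo] − δ_eff · R(t) · T3,
    δ_eff = δ · mutant_degradation_fraction

with `R(t)` the RPC count (plus immature cones in the DIO3-persistence
variant). Cell-fate events are sampled with the Gillespie algorithm inside
0.1-day operator-splitting steps; T3 is integrated with substepped RK4.
Because both specification gates are activating with `K_S < K_L`, rising T3
opens the S gate first (subtype ordering), and because the gates open at a
characteristic pool size rather than a characteristic time, the final cone
count is buffered against noise in the initial pool — the property the
noise-filtering experiments quantify against a constant-rate cell-intrinsic
comparator calibrated to identical mean outputs.

The DIO3-mutant preset scales T3 degradation to 6% of wild type, the value
implied by the measured deiodination activities (wild type 16.8, mutant 1.0
pmol/h/mg protein: a ~94% reduction; `deiodinationCalibration(16.8, 1.0)`).

## Worked example

```r
library(coneSpec)

tr <- simulateOrganoid(ConeModelParams(), initial_rpc = 10000, seed = 42)
tr
#> Trajectory: custom, 189 snapshots, t in [0, 187.8] d (complete)
#>   initial RPC 10000, seed 42, step 0.1 d
#>   final counts:
#>          RPC   IMMATURE_S  IMMATURE_LM     MATURE_S    MATURE_LM COEXPRESSING
#>            0            0            0          625          560           43
#>      NONCONE
#>         8772
#>   final T3: 89.95
```

Every cell reached a terminal fate by day ~188: 625 mature S cones, 560
mature L/M cones, 43 coexpressing cones, the rest non-cone. S cones cross a
500-cell threshold on day 50, L/M cones only on day 72 (the S-before-L/M
ordering), and the wild-type L/M:S ratio is 0.90 with 3.5% of cones
coexpressing:

```r
timeToThreshold(tr, "MATURE_S", 500)   # 50
timeToThreshold(tr, "MATURE_LM", 500)  # 72
lmToSRatio(tr)                         # 0.896
coexpressionFraction(tr)               # 0.035
```

The DIO3-mutant condition (6% residual degradation) is dramatically
accelerated and L/M-shifted — thresholds at days 16 and 14, ratio 1.35,
coexpression 6.8%:

```r
mut <- runCondition("MUT", seed = 42)
timeToThreshold(mut, "MATURE_S", 500)  # 16
lmToSRatio(mut)                        # 1.353
```

Feedback filters initial-pool noise: with organoids seeded from
Normal(10^4, 2000), the coefficient of variation of the final photoreceptor
count is roughly halved relative to the mean-matched intrinsic model:

```r
nf <- noiseFilterExperiment(ConeModelParams(), n_reps = 200, seed = 2)
summaryStats(nf$signaling)$cv   # 0.107
summaryStats(nf$intrinsic)$cv   # 0.200
```

`conditionPanel()` produces the four-condition comparison (WT, MUT, WT+T3,
MUT+T3), `parameterSweep()` the log-uniform 100-fold robustness sweep, and
`synthesizeDensityTimecourse()` synthetic opsin-density tables with
organoid-level noise. A command-line front end with the same functionality
ships in `inst/scripts/conesim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","conesim.R",package="coneSpec"))')" \
    simulate --out out/ --seed 1 --set mutant_degradation_fraction=0.06
```

See `vignettes/cone-specification-model.Rmd` for the model assumptions,
parameter calibration and numerical choices.

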