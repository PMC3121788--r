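# nhoskit

Quantifying the stability of the nuclear higher-order structure (NHOS) —
the genome-wide pattern of supercoiled DNA loops anchored to the nuclear
matrix (NM) — from the three classic nucleoid assays: DNA-halo loop-size
measurement, limited DNase I digestion kinetics, and PCR-based positional
mapping of gene sequences relative to the NM. The package is written for
chromatin and nuclear-architecture researchers who analyse nucleoid data
(e.g. from developing or aging post-mitotic tissue) and for anyone who
needs a generative model of NM-anchored loops with known ground truth to
validate such analyses.

## The model

Each DNA loop of length $L$ bp is anchored to the NM at both ends through
MAR (matrix attachment region) footprints of embedded, non-digestible DNA
(~2 % of the total). DNase I cuts fall as a non-homogeneous Poisson process
with per-bp hazard

$$h(u) = k_0 \left(\frac{d(u)}{0.5}\right)^{\alpha}, \qquad d(u) = \min(u, 1-u),$$

zero inside MAR footprints — one monotone accessibility standing in for
steric hindrance by the NM plus the tip-to-base supercoiling gradient. A
fragment remains NM-attached iff it contains an anchor, so the expected
attached fraction of a loop is

$$\frac{1}{L}\int_0^1 \left[e^{-H(0,u)} + e^{-H(u,1)} - e^{-H(0,1)}\right]\,L\,du ,$$

with $H$ the cumulative cut hazard (MAR mass always attached). On top of
this sit: local digestion slopes $S = \Delta\mathrm{pct}/\Delta t$ defining
the topological zones D, P, VC, E (distal → embedded, bound to the 5, 15,
30, 60 min timepoints); innermost-positive-zone calling of PCR patterns
with the published +/±/− replicate semantics; halo-radius → loop-size
conversion $\mathrm{kbp} = 2R/0.34$; pooled Student's t-tests; and the two
competing aging operators — MAR substitution (mode A) versus MAR extension
(mode B) — applied to the simulated ensemble.

## Worked example

```r
library(nhoskit)

# digestion kinetics: local slopes of the 7-day-old neuron course
tc <- read_timecourse(nhos_example("table3_timecourses.tsv"), "P7")
local_slopes(tc)$slope
#> [1] -10.2  -2.5  -0.3  -0.1

# positional mapping: call all 36 (target, age) zone placements
scheme <- zone_scheme(c(5, 15, 30, 60))
scores <- read_score_matrix(nhos_example("table5_scores.tsv"))
calls  <- mapping_table(scores, scheme)
subset(calls, amplicon == "NFM")[, c("age", "zone", "ambiguous")]
#>     age zone ambiguous
#>      P0   VC     FALSE
#>    P540    P      TRUE
#>      P7   VC      TRUE
#>     P80   VC      TRUE

positional_shift(subset(calls, age == "P0"), subset(calls, age == "P540"))$summary
#>      away    toward unchanged
#>         9         0         0

# end-to-end recovery on synthetic ground truth
report <- run_recovery_experiment(default_run_config(seed = 1))
report
#> Zone recovery: 9/9 amplicons correct (accuracy 1.00)
#> ...
#> After B_extension: median rank shift +0 (away 0 / toward 0 / unchanged 9),
#> mean loop-size drift +0.00%, embedded fraction 0.0200 -> 0.2160, loops 1000 -> 1000
```

The slopes are the per-interval digestion rates in percentage points per
minute (fast early loss of distal loop DNA, near-plateau after 30 min);
the NFM calls show a target sitting very close to the NM in newborn
neurons that has moved to the proximal zone by old age, a shift shared by
all nine targets; and the recovery report shows the pipeline re-deriving
every planted zone from simulated replicate PCR data, with the
MAR-extension aging model conserving DNA mass while raising the embedded
fraction from 2 % to 21.6 % exactly as its absorption parameter dictates.

The numbered scripts under `analysis/` run the same stages as a narrative
pipeline (simulate → kinetics → mapping → halo → model discrimination) and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_ensemble.R
Rscript analysis/02_digestion_kinetics.R
# ... through 05_model_discrimination.R
```

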