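# cardioquant

Image-based quantification of larval-zebrafish cardiac function, with
Bliss-Independence drug-synergy analysis and Kaplan–Meier/log-rank
survival comparison.

Cardioprotective drug screens in zebrafish record the beating heart of a
transgenic line with fluorescent cardiomyocytes and read contractile
function off the video: the ventricular chamber is segmented in every
frame, its area is the pixel count, and a rotated minimum-area rectangle
gives the long axis *a* and short axis *b*. With end-diastolic (ED) and
end-systolic (ES) frames identified per cycle,

- FAC = (EDA − ESA)/EDA × 100 % (ventricular fractional area change)
- FS = (EDa − ESa)/EDa × 100 % (fractional shortening)
- Vol = 4π/3 · (a b²) at ED and ES (prolate-spheroid model),
  SV = ED.Vol − ES.Vol, CO = SV × BPM

averaged over at least four consecutive cycles, with BPM counted from the
contractions in the fixed-length video. Downstream, rescue-type endpoints
are normalized to per-animal rescue effects E ∈ [0, 1], combinations are
judged against the Bliss additive threshold E_add = E_A + E_B − E_A·E_B
via the combination index CI = E_add/E_AB (CI < 1 ⇒ synergy) and a
one-sample t-test of the combination group against E_add; survival under
toxin challenge is compared with Kaplan–Meier curves and the log-rank
(Mantel–Cox) test.

Raw videos for such screens are rarely deposited, so the package includes
a synthetic-data module — beating-ellipse videos with PSF blur and
Gaussian/Poisson noise, treatment cohorts with chosen true rescue
effects, interval-recorded exponential survival — whose analytic ground
truth backs every accuracy claim in the test suite.

## Worked example

```r
library(cardioquant)

## a 2 s, 100 fps recording at 120 BPM, true FAC 40%, SNR ~ 5
p <- heartSimParams(noiseGaussianSd = 0.2)
v <- simulateVideo(p, seed = 7)
quantifyVideo(v)
#> CardiacMetrics (axis convention: semi )
#>   FAC 39.76 % | FS 23.33 % | BPM 120.0 | cycles 4
#>   ED.Vol 41861.7 | ES.Vol 18883.1 | SV 22978.7 | CO 2757438.7 /min
```

FAC lands within 0.3 percentage points of the generative truth and the
heart rate is recovered exactly; volumes are in px³ under the semi-axis
convention (supply `pixelSizeUm` for µm³).

```r
## a cohort with true effects E_A = 0.6, E_B = 0.5 and built-in synergy
## (combination effect 12.5% above the Bliss threshold, true CI = 0.889)
sim <- simulateCohort(cohortDesign(), seed = 7)
analyzeSynergy(sim$table)[[1]]
#> SynergyResult [FAC]
#>   E_A 0.615  E_B 0.489  E_AB 0.905  E_add 0.804
#>   CI 0.8875  t 5.367  p 0.0004524  (n_AB = 10)
#>   verdict: synergy

## survival: model hazard ln2/8 per h vs a protected group, 0.5 h grid
sv <- simulateSurvival(survivalSimParams(), seed = 7)
lt <- logrankTest(sv[sv$group == "model", ], sv[sv$group == "treated", ])
#> log-rank chi2 = 5.896, p = 0.0152
```

The estimated CI of 0.8875 recovers the design's true 0.8889, and the
significant positive deviation from the additive threshold yields the
`synergy` verdict.

File-based pipelines (`runSimulate`, `runQuantify`, `runSynergy`,
`runSurvival`) read TIFF stacks / PNG directories and CSV tables, write
JSON/CSV results with a config echo and seed, and are wrapped by a thin
command-line script at `inst/scripts/cardioquant.R` with the subcommands
`simulate`, `quantify`, `synergy`, `survival`.

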