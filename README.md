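# pparClock

Circadian timecourse analysis for hepatic PPARα in factorial
developmental-programming studies: clock-forced kinetic modeling,
Monte Carlo + conjugate-gradient parameter estimation, PRCC global
sensitivity analysis, qPCR/ChIP-qPCR quantification, and 24-h rhythm
statistics — validated closed-loop on synthetic data with known ground
truth.

## Who this is for

Groups analysing cross-sectional circadian expression data from 2 × 2
factorial animal designs (maternal phenotype `lean`/`obese` × post-weaning
diet `control`/`HFD`; six clock hours at 4-h spacing; 3–5 animals per group
per hour) who want to go beyond "the amplitude is blunted" to a mechanistic
attribution: did mRNA *synthesis* fall, or did *degradation* rise?

## The model

Relative PPARα mRNA `X(t)` follows a single kinetic equation forced by the
24-h-periodic BMAL1 drive `B(t)`:

```
dX/dt = v0 + vp * B(t)^n / (Kp^n + B(t)^n) - vd * X/(Kd + X) - deltaP * X
```

Eight parameters: basal synthesis `v0`, maximum clock-driven synthesis `vp`,
activation constant `Kp`, Hill coefficient `n`, saturable degradation `vd`
with Michaelis constant `Kd`, non-specific first-order degradation `deltaP`,
and the 6AM initial condition `x0`. Per experimental group, parameters are
estimated by 10,000 Monte Carlo draws followed by Polak–Ribière
conjugate-gradient refinement against the group-mean curve; global
sensitivity is assessed by Latin-hypercube sampling with partial rank
correlation coefficients (PRCC, N = 1000) read at the light/dark switch
hours (6AM, 6PM). Rhythm statistics follow the field's conventions:
trapezoidal 24-h AUC with delta-method errors, per-timepoint pooled t-tests,
2 × 2 ANOVA with Student–Newman–Keuls letter groupings. ChIP-qPCR
enrichment is quantified as percent of dilution-adjusted input.

## Worked example

Generate a study-shaped dataset whose four groups differ by a stepwise
increase in degradation (`deltaP` 0.15 < 0.20 < 0.25 < 0.35 across
lean-control < lean-HFD < obese-control < obese-HFD) and reduced synthesis
in obese groups, then recover the mechanism from the data alone:

```r
library(pparClock)

forcing <- cosinorForcing()                   # BMAL1 drive, peak 10AM
sim <- synthPparGroups(seed = 11)             # noise CV 5%, n = 4/cell
cfg <- fitConfig(nMonteCarlo = 10000, mode = "periodic", seed = 42)

fit <- fitGroup(sim$experiment, "PPARA", "obese", "HFD", forcing, cfg)
fit
#> FitResult [periodic mode]: rss = 7.58114e-05 over 6 points (seed 42), iteration budget reached
#>       v0       vp       Kp        n       vd       Kd   deltaP       x0
#> 0.031369 0.353670 0.806910 2.453100 0.028254 0.816510 0.365020 0.900620
sim$truth[sim$truth$maternal == "obese" & sim$truth$diet == "HFD",
          c("vp", "deltaP")]
#>     vp deltaP
#> 4 0.42   0.35
```

The fitted `deltaP` (0.365 vs truth 0.35) pins the degradation mechanism
tightly, and across all four groups the fitted `deltaP` reproduces the
generating stepwise order; `vp` (0.354 vs truth 0.42) lands within the
~±25% spread the six-point design allows (see the vignette's
identifiability analysis — the synthesis amplitude trades against the
Hill shape). Sensitivity analysis identifies the three parameters that
control the output at both switch points:

```r
sens <- runSensitivity(fittedParams(fit), forcing,
                       prccConfig(nSamples = 1000, seed = 1,
                                  bounds = pparSensitivityBounds(fittedParams(fit))))
subset(prccTable(sens), parameter %in% c("vp", "Kp", "deltaP") & time_h == 6)
#>   parameter time_h       prcc statistic p_value    n
#> 2        vp      6  0.9408744  87.39019       0 1000
#> 3        Kp      6 -0.9139020 -70.83710       0 1000
#> 7    deltaP      6 -0.9309401 -80.21251       0 1000
```

(|PRCC| > 0.91 with p < 0.001 for `vp`, `Kp`, `deltaP`; the built-in dummy
parameter stays null.) Rhythm summaries mirror the familiar per-gene AUC
table:

```r
te <- synthDataset(cosinorSpec(gene = "CLOCK",
                               groups = cosinorGroups("interaction_obese_hfd")))
aucTable(te, "CLOCK")
#>    gene maternal    diet   auc se_auc  closure p_maternal p_diet p_interaction
#> 1 CLOCK     lean control 36.55 0.7327 periodic     0.3738 0.4515        0.9613
#> 2 CLOCK     lean     HFD 37.04 0.8595 periodic     0.3738 0.4515        0.9613
#> 3 CLOCK    obese control 35.90 0.6046 periodic     0.3738 0.4515        0.9613
#> 4 CLOCK    obese     HFD 36.46 0.5413 periodic     0.3738 0.4515        0.9613
```

(An amplitude-only deficit leaves the 24-h AUC unchanged — the cosine
integrates out — while the peak-hour factorial ANOVA detects the
interaction; both behaviours are asserted in the test suite.)

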