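# movesync

Spectral and hierarchical-Bayesian analysis of daily animal displacement
series, for movement ecologists working with radiotelemetry panels: several
individuals relocated once a day over the same contiguous window. The
package answers two questions about such data:

1. **At what time scale is movement synchronous across individuals?**
   Synchronous displacement points to shared external drivers (weather,
   season, prey pulses); its absence points to individual-level drivers.
2. **How strongly is each individual's movement autocorrelated?** Expressed
   as the *colour* of 1/f noise: red (positively autocorrelated) to white to
   blue.

## Models

Daily displacements D<sub>t,n</sub> (individual *n*, day *t*) are first
power-transformed, X = D^c, with *c* chosen to minimise
Σ<sub>n</sub> |Skewness(D<sub>·,n</sub><sup>c</sup>)|. Each series is then
Fourier-decomposed; for an even record of length *L* this leaves
*l* = *L*/2 − 1 frequencies *f* = 1..*l* (cycles per record; time scale
*L*/*f* days) with phases θ<sub>f,n</sub> and periodogram ordinates
ψ<sub>f,n</sub>.

**Synchrony.** Phases at frequency *f* ≤ φ follow a wrapped Cauchy
distribution with common mean μ<sub>f</sub> and concentration
ρ<sub>f</sub> ∈ [0, 1) (ρ = 0: uniform circle, no synchrony); phases above
the cutoff φ are uniform. The ρ<sub>f</sub> borrow strength through a beta
distribution parameterised by mode *M* and shape ν = α + β, with hyperpriors
*M* ~ Uniform(0,1) and ν ~ Gamma solved so that 95% of its density lies in
(5, 200). The cutoff is selected by scanning φ = 0..*l* and minimising
DIC = 2p<sub>D</sub> + D(ξ̄); a runner-up more than 3 DIC units behind marks
a well-supported cutoff.

**Colour.** Under the Whittle approximation, ψ<sub>f,n</sub> ~
Exp(mean Y<sub>f,n</sub>) with Y<sub>f,n</sub> = a<sub>n</sub>
f<sup>−γ<sub>n</sub></sup>. Individual colours pool through
γ<sub>n</sub> ~ Normal(γ̄, σ<sub>γ</sub>) and scales through
log a<sub>n</sub> ~ Normal(ā<sub>log</sub>, σ<sub>a log</sub>), with a
Normal(0, 4) hyperprior on γ̄, a scaled-inverse-χ² prior on σ²<sub>γ</sub>
solved from mode 0.0625 and 95th percentile 1, and flat hyperpriors on the
scale level. Model adequacy is checked by posterior-predictive periodogram
bands and by residuals Z = ψ/Y tested for autocorrelation (lags 1, 5, 10)
and exponentiality over posterior realizations.

## Worked example

Simulate the stated world (6 individuals, 64 days, synchrony at the three
lowest frequencies with ρ = 0.9, population colour γ̄ = 0.75), then run the
pipeline:

```r
library(movesync)
cfg <- synthetic_config(N = 6, L = 64, phi = 3, rho = 0.9, gamma_bar = 0.75,
                        sigma_gamma = 0.25, c = 0.17, seed = 7)
sim <- simulate_panel(cfg, back_transform = TRUE)
tp  <- power_transform(sim$D)       # skewness-minimising exponent
dec <- spectral_decompose(tp)       # phases + periodogram
scan_cutoff(dec, chains = 2, iters = 4000, seed = 11)
```

```
DIC scan over synchrony cutoffs phi = 0..31
Selected cutoff: phi = 3  (time scale 21 days and above, L/phi = 64/3)
Runner-up Delta_DIC = 5.79 (exceeds the support threshold of 3)
Best cutoffs:
 phi    DIC Delta_DIC
   3 657.80      0.00
   4 663.59      5.79
   2 667.23      9.43
```

The scan recovers the true cutoff φ = 3: synchrony is supported at time
scales of 64/3 ≈ 21 days and longer, not below. The colour fit:

```r
fit_colour(dec, chains = 2, iters = 4000, seed = 12)
```

```
Hierarchical 1/f-noise colour fit: N = 6 individuals, m = 31 frequencies
Posterior mean [95% CI] of noise colour:
  gamma[ind1]  1.11 [0.69, 1.55]
  gamma[ind2]  0.45 [0.11, 0.80]
  ...
  gamma_bar    0.52 [0.15, 0.92]
```

All individual colours are positive (red noise: a long move today makes a
long move tomorrow likely) and the population interval covers the generating
γ̄ = 0.75. `residual_diagnostics(fit)` reports, per individual, the
fraction of posterior realizations in which the standardised residuals
Z = ψ/Y fail the lag-1/5/10 autocorrelation tests or the exponentiality
test, with a >50%-of-realizations significance rule.

`run_report()` chains all stages (optionally with a 3 × 3 prior-sensitivity
grid) and writes JSON/CSV output that is byte-reproducible from the seed.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch against the installed package:
it simulates the stated-world panel, back-transforms it to distances,
re-estimates the transform exponent, runs the DIC cutoff scan, the
hierarchical colour fit and the residual diagnostics, prints the recovered
quantities next to their generating values, and writes the acceptance JSON
to `--out`.
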