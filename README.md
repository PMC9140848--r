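# phitau

Integrated information across timescales in continuous neural dynamics.

## What this package is for

Integrated information theory (IIT 3.0) proposes a state-dependent
measure Φ of how irreducible a system's cause–effect structure is, and
posits that Φ be evaluated at the spatiotemporal grain where it is
maximal — for conscious systems, a *macro* timescale rather than the
recording's sampling resolution. Testing that prediction on real
signals (e.g. multichannel local field potentials recorded during
wakefulness and anaesthesia) requires a chain of steps that this
package provides end to end, for researchers working on neural
complexity measures:

1. **Generative models with a known timescale** (`ar_model()`,
   `simulate()`): two- and three-channel autoregressive systems with
   threshold-gated (nonlinear) cross-coupling at lag 10, optionally with
   probabilistically jittered lags 9/10/11 (non-Markovian). If the
   pipeline works, Φ must peak at τ = 10.
2. **Timescale-indexed state coding** (`binarize_median()`,
   `tpm_skipping()`, `tpm_downsampling()`): channels are binarised at
   their median; transition probability matrices are built either from
   transitions τ samples apart (*skipping*: τ as a delay) or after
   averaging bins of τ samples, pooled over all τ starting offsets
   (*downsampling*: τ as the temporal extent of a state).
3. **Exact IIT 3.0 Φ for 2–3 binary nodes** (`system_phi()`,
   `phi_states()`, `mechanism_concept()`, `emd_hamming()`): cause/effect
   repertoires, minimum-information partitions, concepts, and the
   minimum over unidirectional cuts of the extended earth mover's
   distance between constellations — all earth mover's distances solved
   exactly (Rcpp core).
4. **Peak detection** (`tau_sweep()`, `delta_log_phi()`,
   `fit_phi_peak()`): sweep Φ over an exponential τ grid, contrast
   conditions as Δlog(Φ) = log Φ_wake − log Φ_anaesthesia, and test for
   an intermediate-timescale peak by comparing quadratic vs linear
   mixed-effects models in x = log₂(τ) (random intercepts for subject
   and subject:pair, ML fit, χ²(1) likelihood-ratio test). A fitted
   quadratic β₀ + β₁x + β₂x² peaks at 2^(−β₁/2β₂), a local maximum when
   β₂ < 0.

`run_pipeline()` executes the whole chain from a declarative (YAML)
configuration and writes CSV/JSON artifacts with config hash and seed.

## Worked example

```r
library(phitau)
model <- ar_model_nonlinear(n_timepoints = 20000, n_runs = 10)
model
#> Threshold-gated AR model (2 channels, recurrence form)
#>   self coefficients: -0.1, -0.1
#>   cross coefficients: 0.9 (gate: source > 0.9)
#>   lag: 10 (fixed)
#>   noise variance: 0.5; 20000 timepoints x 10 runs

runs <- simulate(model, seed = 1)
sweep <- tau_sweep(runs, method = "skipping")
sweep
#> Timescale sweep: 220 records (skipping method), tau in [1, 512]
#>   10 run(s) x 1 channel set(s) x 22 timescale(s); condition: model
#>   run-mean Phi peaks at tau = 10

cur <- phi_curve(sweep)
cur[cur$tau %in% c(5, 8, 10, 13, 20, 360), ]
#>    tau         mean           sd  n
#> 5    5 5.814088e-05 4.405104e-05 10
#> 7    8 7.685176e-05 9.766668e-05 10
#> 8   10 1.272230e-01 6.082963e-03 10
#> 9   13 5.364868e-05 4.074042e-05 10
#> 11  20 2.378726e-02 1.039469e-03 10
#> 21 360 7.192050e-05 4.277670e-05 10
```

Φ is ~10⁻⁴–10⁻⁵ at off-target timescales but 0.127 at τ = 10: the sweep
recovers the generating delay, with secondary structure at its
harmonics (e.g. τ = 20). The same recovery holds for the downsampling
method, for the non-Markovian models, and for the three-channel system
under partial observation (see the vignette and tests).

For condition contrasts, the turning point of a fitted quadratic in
log₂(τ) locates the peak; with coefficients β₁ = 4.441 × 10⁻²,
β₂ = −9.18 × 10⁻³ on a log₂(ms) axis:

```r
tp <- turning_point(4.441e-2, -9.18e-3)
sprintf("turning point: %.2f ms, local max: %s", tp$tau, tp$is_local_max)
#> [1] "turning point: 5.35 ms, local max: TRUE"
```

## Documentation

The methods vignette (`vignettes/phi-timescales.Rmd`) describes the
generative models and their assumptions, both TPM constructions and
their transition accounting, the Φ algorithm with all numerical
conventions (state indexing, tie-breaks, maximum-entropy imputation),
the mixed-model peak test, and known limitations.
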