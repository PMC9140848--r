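---
title: "Finding the timescale at which integrated information peaks"
author: "phitau"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding the timescale at which integrated information peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phitau)
```

## The scientific question

Integrated information theory (IIT 3.0) quantifies, for a system in a
given state, how much its cause–effect structure is irreducible to that
of its parts: the system-level measure $\Phi$. The theory holds that
$\Phi$ should be evaluated at the spatiotemporal grain at which it is
maximal, and predicts that for systems supporting experience this grain
is a *macro* timescale — coarser than the sampling resolution of the
recording, finer than seconds. `phitau` implements the full computational
chain needed to test that prediction on continuous multichannel signals:
generative models with a known interaction timescale, timescale-indexed
state coding, an exact $\Phi$ engine for two- and three-node binary
systems, and the statistics that decide whether a $\Phi$-versus-timescale
curve has an intermediate peak.

## Generative models with a known timescale

`ar_model()` describes a family of threshold-gated autoregressive
systems. Channels are continuous voltages; each channel self-inhibits
(coefficient $a = c = -0.1$) and excites the others (coefficient 0.9 for
two channels, 0.4 for the fully connected three-channel system), but the
cross-coupling is *gated*: a source contributes only while its voltage
exceeds a threshold (0.9), a simple stand-in for reliable communication
through bursting. Innovations are i.i.d. Gaussian with mean 0 and
variance 0.5. Two generative forms are provided:

* **Fixed lag (recurrence form).** Every influence arrives exactly $l =
  10$ samples later: $X(t) = aX(t-l) + b\,\mathbf{1}[Y(t-l) >
  \theta]\,Y(t-l) + \varepsilon_X(t)$, and symmetrically for $Y$. The
  first $l$ samples are pure noise draws. We apply this initialisation
  uniformly (the accumulation form below forces it), which removes any
  burn-in ambiguity; no burn-in is discarded by default and `burn_in`
  is configurable.
* **Jittered lag (accumulation form).** Every timepoint starts as its
  noise draw; then, processing source times in increasing order, each
  connection adds its contribution at $t + l$ with $l$ drawn
  independently per connection and timepoint from $\{9, 10, 11\}$ with
  probabilities $\{0.25, 0.5, 0.25\}$. The system is then non-Markovian
  — no single fixed-lag state determines the next state — but its
  elements still interact at roughly 10 samples. The gate is tested
  against the *fully accumulated* source value: because all lags are
  $\ge 9$, processing source times in order makes every value final
  before it is read, which is the only self-consistent reading of the
  update rule.

Design notes: the gate tests the realised (noisy) voltage, as the model
equations are written; a guard aborts with a diagnostic if any voltage
exceeds $10^6$ (the stated regimes are stable, so this only catches
misconfiguration); runs are bit-identical given a seed.

These simulations emulate what matters for the method — continuous,
noisy, multichannel signals with two experimental conditions and a
ground-truth interaction delay. They deliberately do not emulate other
features of real extracellular recordings (nonstationarity, $1/f$
spectra, volume conduction, cross-subject variability), so passing the
recovery tests shows the pipeline finds a known timescale in continuous
data, not that any particular neural dataset has one.

## Characterising timescale: skipping and downsampling

States are defined by `binarize_median()`: a channel is "on" when its
voltage strictly exceeds that channel's median within the run (ties,
which have measure zero for continuous data, go to "off"; a constant
channel binarises to all-off with a warning). Medians are always
computed per run — and, for the downsampling method, per offset — never
pooled.

Two ways of indexing a transition probability matrix (TPM) by a
timescale $\tau$:

* **Skipping** (`tpm_skipping()`): tally transitions between the state
  at $t$ and the node states at $t + \tau$, leaving samples untouched;
  all $n - \tau$ source times are used. This characterises $\tau$ as a
  *delay*.
* **Downsampling** (`tpm_downsampling()`): average voltages in
  consecutive bins of $\tau$ samples, binarise the coarse series
  against its own medians, and tally transitions between consecutive
  coarse steps. Coarse-graining alone would leave only $\sim n/\tau$
  samples, so the estimate is repeated at every starting offset
  $0, \dots, \tau - 1$ (trailing partial bins dropped; an offset with
  fewer than two complete bins contributes nothing) and the tallies are
  pooled into one TPM. Each offset $o$ contributes
  $\lfloor (n-o)/\tau \rfloor - 1$ transitions, so the pooled total lies
  in $[n - 2\tau,\, n - \tau]$, comparable to the skipping method; we
  keep this exact per-offset bookkeeping rather than any single closed
  form, since it is what the pooling construction actually yields. This
  characterises $\tau$ as the *temporal extent of a state*.

TPM rows for states never observed as a transition source are filled at
maximum entropy (0.5 per node) and flagged; downstream results carry the
imputed-row fraction so the user can judge estimate quality at large
$\tau$. The state index is little-endian throughout (channel 1 is the
least significant bit), matching the convention of the field's standard
IIT software, and `sbn_to_sbs()` expands the state-by-node TPM to
state-by-state form under conditional independence of channels given the
current state.

## The integrated-information engine

`system_phi()` implements IIT 3.0 for binary systems of two or three
nodes (the C++ core keeps a full sweep fast). For a mechanism $M$ in its
current state over a purview $P$:

* the **effect repertoire** is the distribution over $P$'s next states
  given $M$'s state, with non-mechanism nodes marginalised uniformly —
  a product over purview nodes;
* the **cause repertoire** is the Bayesian posterior over $P$'s previous
  states given $M$'s state (uniform prior), assembled by the standard
  virtual-element factorisation: each mechanism node's constraint is
  computed independently, multiplied, and renormalised. A conditioning
  event of probability zero (possible under deterministic empirical
  TPMs) yields a uniform repertoire plus a warning.

A mechanism's irreducibility $\varphi$ in one direction is the minimum
over bipartitions of (mechanism, purview) of the earth mover's distance
(EMD) between the whole repertoire and the product of the part
repertoires, maximised over purviews; a concept's $\varphi$ is the
minimum of its cause and effect values. The EMD uses Hamming ground
distance between purview states and is solved exactly by a
successive-shortest-path transportation solver; for effect repertoires
(products) the EMD reduces analytically to the L1 distance between node
marginals, which the engine exploits and the test suite verifies against
the explicit linear program. System-level $\Phi$ is the minimum over
unidirectional cuts $A \to B$ (connections from $A$ into $B$ noised to
maximum entropy; $2^n - 2$ distinct ordered cuts) of the extended EMD
between the intact and cut constellations: concept $\varphi$ is the
transported mass, ground distances are cause-plus-effect repertoire EMDs
over the full state space, and surplus mass pays its distance to the
unconstrained null concept. Mechanism-level MIP search minimises
unnormalised $\varphi$ — with exact EMD on these small state spaces a
search normalisation would only reorder tied partitions, and the
reported $\varphi$ is unnormalised in any case.

Numerical conventions, fixed package-wide: distribution comparisons at
$10^{-12}$; $\varphi \le 10^{-10}$ counts as zero; searches keep the
first optimum in a fixed enumeration order (subsets by size, then by
ascending node index), so results are bit-reproducible. One consequence
is worth stating plainly: when two purviews tie *exactly* in $\varphi$ —
which happens structurally, for instance when an effect MIP's minimum
isolates a node shared by both purviews — the stored repertoire, and
through it $\Phi$, can depend on node labelling. Any deterministic
tie-break has this property; away from such degenerate ties $\Phi$ is
invariant under relabelling, and the test suite checks both the
invariance and the constellation's equivariance.

Two further choices: background conditions are never fixed — TPMs built
from a channel subset marginalise the remaining channels implicitly,
which is the only option for real recordings and is applied consistently
to the simulations; and `phi_states()` aggregates per-state $\Phi$ by
the empirical frequency of the *source* state at $t$ (the per-state map
is always retained, so any other aggregation can be recomputed).

## The timescale sweep and peak detection

`tau_sweep()` evaluates $\Phi$ on the default grid
$\{1, 2, 3, 4, 5, 6, 8, 10, 13, 16, 20, 25, 32, 40, 50, 64, 90, 128,
180, 256, 360, 512\}$ — approximately exponential, deliberately
including non-powers of two such as 10 and 360 so generating delays of
that kind sit on the grid; it is fully configurable. $\Phi$ is
log-transformed for analysis (it is positively skewed); a record with
$\Phi = 0$ keeps a missing log with a reason, never $-\infty$, and such
records are dropped listwise from fits. `delta_log_phi()` forms the
wake-minus-anaesthesia contrast of log $\Phi$ — the log of the
$\Phi$ ratio — which cancels trends common to both conditions, such as
the systematic drift of empirical TPM estimates with the number of
available transitions.

`fit_phi_peak()` regresses the response on $x = \log_2 \tau$ with linear
and quadratic fixed effects and random intercepts for subject and
subject:pair, fitted by maximum likelihood (the two models differ in
fixed effects, so ML rather than REML is required for the
likelihood-ratio test, which is $\chi^2_1$ here). The fitted quadratic
$\beta_0 + \beta_1 x + \beta_2 x^2$ has its turning point at
$2^{-\beta_1 / 2\beta_2}$; the fit reports a peak at an intermediate
timescale when $\beta_2 < 0$ (local maximum) and the turning point falls
strictly inside the observed $\tau$ range. Records are fitted at the
record level (runs and pairs are not pre-averaged; the random effects
absorb the grouping). Singular random-effect fits drop the
variance-zero term and flag the simplification; a single-group design
falls back to a fixed-effects fit, also flagged.

Two sweep-level generators with known ground truth validate this stage
independently of the $\Phi$ engine: `simulate_parabola_data()` (records
exactly from the fitted model class, for coefficient-recovery checks)
and `simulate_bump_sweep()` (two conditions sharing a trend and group
structure, the wake-like one carrying a concave-quadratic multiplicative
$\Phi$ bump centred at a chosen $\tau^\*$ — planted inside the model
class so the true turning point is $\tau^\*$; sizes default to 13
subjects and 5 pairs, a realistic recording-study shape).

## Problem sizes and runtime

The study conditions are 10 runs of 20,000 timepoints per generative
model, swept over the full default grid with both methods; the package's
test suite and the acceptance script run exactly that (two-node $\Phi$
evaluates in well under a millisecond per TPM; a full three-node sweep
takes a few minutes). Unit tests use shorter series where the property
under test does not depend on scale.

## Known limitations

* Systems of at most three binary nodes; no search over subsets for a
  complex (no exclusion-postulate search), no spatial coarse-graining
  or black-boxing, and no continuous-state $\Phi$ — signals are always
  binarised first.
* TPMs are observational (estimated from state transitions), not
  perturbational; at large $\tau$ with short recordings they rely
  increasingly on maximum-entropy imputation, which is reported but not
  corrected for.
* The $\Phi$ engine assumes conditional independence of channels given
  the current state (a state-by-state TPM input is marginalised to
  state-by-node form under that assumption).
* At exact core-purview ties, $\Phi$ depends on the fixed tie-break
  order (see above).

## A compact end-to-end example

```{r example, eval = FALSE}
model <- ar_model_nonlinear(n_timepoints = 20000, n_runs = 10)
runs <- simulate(model, seed = 1)
sweep <- tau_sweep(runs, method = "skipping")
phi_curve(sweep)        # run-mean Phi per timescale
peak_tau(sweep)         # 10: the generating delay
fit <- fit_phi_peak(sweep, response = "log_phi", subject = "run")
fit                     # quadratic LRT and turning point
```
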