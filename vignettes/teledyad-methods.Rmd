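---
title: "Methods: directed interaction analysis for animal dyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed interaction analysis for animal dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teledyad)
```

This vignette documents the statistical model behind the package, the
estimators and their conventions, the surrogate-based inference, the design
of the synthetic ground-truth generator, and the known limitations. It is a
methods document: the numbers it quotes are either analytic or produced by
the code shown.

## 1. Data model

The unit of data is a planar **trajectory**: strictly increasing timestamps
`t` and positions `(x, y)` sampled at a nominal frame rate (30 Hz by
default), belonging to one subject of a dyad labeled by `size_class`
(`"small"` / `"large"`) and an experimental `condition`. Missing positions
(tracking dropouts) are legal; `fill_gaps()` linearly interpolates gaps up
to `max_gap` seconds (0.5 by default) and splits the trajectory into
independent *segments* at longer gaps. All downstream statistics pool
evidence across segments but never differentiate, correlate, or count
transitions across a segment boundary.

## 2. Kinematics

Speed is the forward-difference step length per unit time; heading is the
`atan2` of the displacement; turn rate is the wrapped heading increment per
unit time. Turn rate is **unsigned** by default — "turning is tightening or
relaxing" is then well defined regardless of turn direction — with
`signed_turn = TRUE` available. Speed and turn rate are smoothed with a
centered moving average (`smooth_window`, default 0.1 s = 3 samples at
30 Hz) before the linear and angular accelerations are taken as centered
finite differences (one-sided at segment ends). Smoothing suppresses
frame-to-frame tracking jitter that would otherwise dominate the sign of the
accelerations; 0.1 s is well below any behavioral time scale of interest.
All four series are truncated to a common time base so that the joint
symbolization below is phase-aligned.

## 3. Joint symbolization

Each sample is encoded as one of four symbols from the sign pair of the
linear and angular accelerations:

| symbol | code | meaning |
|---|---|---|
| `--` | 1 | decelerating, turn relaxing |
| `-+` | 2 | decelerating, turn tightening |
| `+-` | 3 | accelerating, turn relaxing |
| `++` | 4 | accelerating, turn tightening |

Exact zeros (plateaus) carry no trend of their own. The default `"carry"`
tie rule continues the preceding sign within the segment (initializing at
`-`), which keeps the encoding deterministic; `"random"` draws the sign from
a seeded generator that does not perturb the caller's RNG state. Plateaus
are measure-zero for continuous kinematics, so the choice is immaterial for
real data and matters only for pathological inputs.

## 4. Symbolic transfer entropy

For source $X$ and destination $Y$ with symbol histories of length $k$,

$$\mathrm{TE}_{X \to Y} = \sum p\!\left(y_{t+1}, y_t^{(k)}, x_t^{(k)}\right)
\log \frac{p\!\left(y_{t+1} \mid y_t^{(k)}, x_t^{(k)}\right)}
          {p\!\left(y_{t+1} \mid y_t^{(k)}\right)},$$

estimated by the plug-in (maximum-likelihood) histogram estimator with the
convention $0 \log 0 = 0$. Defaults: $k = 1$ and base-2 logarithms (bits).
With a 4-letter alphabet and $k = 1$ the joint histogram has $4^3 = 64$
cells, which a 10-minute session at 30 Hz (~18,000 transitions) samples
densely; larger $k$ is exposed but grows the state space by $16\times$ per
step. **No bias correction is applied** — the plug-in estimator is biased
upward at finite samples, but all inference is against surrogates that share
the same sample size, alphabet and autocorrelation structure, hence the same
bias, so the bias cancels where it matters.

The **net transfer entropy** of a dyad is
$\mathrm{TE}_{\text{small} \to \text{large}} -
 \mathrm{TE}_{\text{large} \to \text{small}}$;
its sign identifies the dominant direction of influence (positive = the
small subject leads).

The estimator is validated two ways. First, against an independent
brute-force implementation of the probability sum (test suite, machine
precision). Second, against an analytic oracle: a coupled chain in which $X$
is i.i.d. uniform on 4 symbols and $Y_{t+1} = X_t$ with probability $c$,
else uniform. There

$$\mathrm{TE}_{X \to Y} = \log 4 + a \log a + 3 b \log b, \qquad
a = c + \tfrac{1-c}{4},\; b = \tfrac{1-c}{4},$$

which spans 0 bits ($c=0$) to 2 bits ($c=1$):

```{r chain}
ch <- simulate_coupled_chain(0.8, n = 50000, seed = 1)
c(estimate = transfer_entropy(ch$x, ch$y)$te, exact = coupled_chain_te(0.8))
```

## 5. Surrogate tests

Significance is assessed by a non-parametric permutation test. The default
surrogate **circularly rotates** one series of each pair by a random offset
drawn uniformly from $[0.1 n,\ 0.9 n]$ frames: this preserves that series'
marginal distribution and autocorrelation exactly (up to one splice point)
while destroying any temporal relation to its partner. It is the most
conservative of the implemented nulls; within-series shuffling (destroys
autocorrelation too) and cross-pair swapping (re-pairs series across dyads)
are alternatives.

The test statistic is the **across-pair average** (e.g. the 12-dyad mean
TE), and every surrogate replicate re-averages a full set of per-pair
surrogates, so the null distribution is that of the averaged statistic. The
p-value uses the add-one estimator
$p = (1 + \#\{\text{surrogate} \ge \text{observed}\}) / (1 + n)$
for one-tailed (upper) tests, with $|\cdot|$ exceedances for two-tailed
tests of statistics whose null is centered at zero (net TE, signed lags).
Add-one p-values can never be exactly zero and are exact under
exchangeability. Reported bands are order statistics of the surrogate
sample: the 95% quantile (one-tailed) or the 2.5%/97.5% pair (two-tailed).
The production default is 20,000 surrogate replicates; examples and tests
use fewer.

Directional conventions: the two TE directions are tested one-tailed
(upper), net TE and lags two-tailed, and the maximum cross-correlation
one-tailed (upper).

## 6. Leader–follower cross-correlation

For two aligned series (speed or turn rate of the small and large subject),
the Pearson correlation is computed at every integer-frame lag in
$[-L, +L]$, re-normalized on the overlapping support at each lag (no zero
padding; missing frames dropped pairwise). The result is the maximum
correlation and its signed lag; **positive lag = the small subject leads**.
Ties break toward the smallest $|$lag$|$, then the negative lag, for
determinism.

The default search bound for leader–follower inference is `max_lag = 0.2 s`,
bracketing startle-response latencies of small fish (tens of milliseconds to
~0.15 s). The width of the search window is not innocuous: under decoupled
surrogates, the arg-max lag of two smooth speed series over a window
narrower than their autocorrelation time clusters at the window boundary
($\pm L$), so the per-pair null lag has standard deviation close to $L$
itself and the across-pair mean lag has a two-tailed critical value of
roughly $0.5\,L$ for 12 pairs. A true lag $\tau$ is therefore only
detectable by this test when $L \lesssim 2\tau$ — a genuine power limitation
of the arg-max-lag statistic documented in §9. The trajectory-similarity
index (next section) keeps its own, wider search bound of 1 s, where the
lag is reported, not tested.

## 7. Trajectory similarity of fish and replica

A session is tiled with non-overlapping 20-s windows. In each window the X
and Y coordinate series of fish and replica are cross-correlated over lags
up to 1 s; the per-lag channel correlations are combined with `min` by
default (both coordinates must match; `mean` is available), and the window's
similarity is the maximum of the combined profile, with its lag. A window
is **successful** when similarity ≥ 0.95 and $|$lag$| \le 0.2$ s. Windows
with replica coverage below 50% are not scored; the session-level
`coverage_fraction` is the fraction of frames with valid replica tracking.
The contract is sharp by construction: a pure transport delay of 0.15 s
succeeds in every window, 0.30 s in none.

## 8. The synthetic generator

Ground truth comes from a coupled-swimmer model (`dyad_sim_config()`,
`simulate_dyad()`). The **leader** swims autonomously: a mean-reverting
(Ornstein–Uhlenbeck) speed process (mean 8 cm/s, reversion 2 /s, noise
6 cm/s per √s, floored at 5% of the mean) and an autocorrelated heading
(noise 2 rad/√s) with a soft wall-avoidance torque inside a margin of 12% of
the 45 × 45 cm arena. The **follower** keeps an internal autonomous state of
the same kind and blends in the leader's *lagged* state with coupling
strength $c \in [0,1]$ at lag $\tau$:

* speed: $s_F(t) = (1-c)\, s_{\text{own}}(t) + c\, s_L(t - \tau)$,
* heading: angular blend with weight $c$ toward the leader's lagged heading,
* plus a distance-saturating attraction toward the leader whose gain is
  multiplied by $c$.

This design puts the coupling in exactly the channels the analysis reads:
the speed cross-correlation peak sits at $\tau$ by construction, symbol
series inherit directed dependence, and $c = 0$ yields two *statistically
independent* swimmers — required for calibrating type-I error. Defaults
($c = 0.6$, $\tau = 0.1$ s, 600 s at 30 Hz, leader = small) emulate a
10-minute session with the small fish dominating. All randomness is drawn
up front from a single seed, so sessions are bit-reproducible.

The **relay channel** (`teleport_channel()`) maps a fish trajectory to a
replica trajectory: transport delay (with optional per-frame jitter),
additive positional noise clamped to the arena, and a fraction of dropped
frames — the degradations of a real-time teleporting rig. A **study**
(`simulate_study()`) assembles per-pair sessions in three conditions:
`control` (direct dyad), `match` (same coupling routed through the channel,
so the effective lag is $\tau$ + channel delay, with replica trajectories
attached for similarity scoring) and `mismatch` (coupling abolished,
$c = 0$).

Scope: the generator is a statistical test harness, not a behavioral model.
It reproduces the *inferential structure* of a dyadic experiment (directed
coupling at a lag, asymmetry of information flow, channel degradations), not
zebrafish ethograms; burst-and-coast locomotion, wall-following bouts and
body-size-dependent kinematics are deliberately out of scope.

## 9. Limitations

* **Plug-in bias.** Absolute TE values are biased upward at finite $n$;
  only surrogate-referenced comparisons are meaningful. Reverse-direction
  TE from a follower to its leader is genuinely positive here (the follower
  carries the leader's past), so "dominance" must be read from the *net* TE
  and its test, not from a single direction.
* **Arg-max-lag power.** As derived in §6, the two-tailed surrogate test of
  the mean cross-correlation lag has a critical value of about half the
  search bound; with the default $L = 0.2$ s this equals the generator's
  default $\tau = 0.1$ s, so that test sits at its own detection boundary
  and is conservative. The maximum-correlation test and the net-TE test,
  which do not rank lags, carry the inferential weight.
* **Unsigned turn rate.** The default discards turn direction; signed
  analyses need `signed_turn = TRUE` and a symmetric reinterpretation of the
  symbol alphabet.
* **Generic proximity metrics.** `alignment_vs_distance()` implements
  standard polarization-versus-distance binning; outputs are flagged
  `definition = "generic"` because shoaling/schooling definitions vary
  across studies.
* **Even-spacing assumption.** Cross-correlation lags are integer frame
  shifts; strongly irregular sampling should be resampled first.

## 10. Reproducibility

Every stochastic function takes a seed; studies derive per-session seeds
from one master seed; permutation tests record seed, method, tail and the
full surrogate sample. `scripts/acceptance.R --seed <int> --out <path>`
recomputes the package's headline verification quantities (oracle accuracy,
type-I calibration, recovery and specificity rates, similarity contract)
from scratch and writes them as a flat JSON record.
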