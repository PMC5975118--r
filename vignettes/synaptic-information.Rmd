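---
title: "Short-term plasticity and information transmission at a depressing GABAergic synapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-term plasticity and information transmission at a depressing GABAergic synapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdsynapse)
```

## The model

`fdsynapse` studies information processing at the synapse between a
parvalbumin-positive (PV) basket cell and a CA1 pyramidal cell, a connection
whose inhibitory currents depress under repetitive stimulation and whose
depression is relieved by the cholinergic agonist muscarine. The core is a
discrete facilitation–depression (FD) map in three variables, driven by the
inter-spike intervals (ISIs) of the presynaptic train: a dimensionless
presynaptic calcium concentration $C$, a release probability $P$, and the
fraction $R$ of release sites ready to release. Given an ISI $T$ (ms):

$$C_{n+1} = C_n e^{-T/\tau_{ca}} + \Delta, \qquad
  P_{n+1} = P_{max}\frac{C_{n+1}^4}{C_{n+1}^4 + K^4},$$
$$R_{n+1} = 1 - \bigl(1 - (1-P_n)R_n\bigr)
  \Bigl(\frac{C_n e^{-T/\tau_{ca}} + K_r}{K_r + C_n}\Bigr)^{\Delta k}
  e^{-k_{min} T},$$

with the normalized postsynaptic response (peak IPSC up to a constant)
$Pr_n = P_n R_n$. Calcium decays between spikes and jumps by $\Delta$ at each
spike; release probability follows calcium through a coefficient-4 Hill
function (synaptotagmin-1 cooperativity); pool recovery accelerates with
calcium through a coefficient-1 Hill function from $k_{min}$ to $k_{max}$.
After release the ready pool is depleted to $(1-P_n)R_n$, which seeds the
recovery ODE whose exact between-spike solution is the $R$ update — no
numerical ODE integration is involved.

The fitted constants (`fd_params("control")`) are $K = 0.2$,
$k_{min} = 0.0017$/ms, $k_{max} = 0.0517$/ms, $K_r = 0.1$,
$\tau_{ca} = 1.5$ ms, $P_{max} = 0.85$, $\Delta = 1$ (calcium is rescaled by
the control influx). Muscarine acts presynaptically: the fitted condition is
$P_{max} = 0.27$, $\Delta = 0.17$. Internally all times are ms and rates
1/ms; the user-facing rate unit is Hz ($\lambda\,[1/\mathrm{ms}] = f/1000$).

### The exponent of the recovery factor

As printed, the calcium-ratio factor in the $R$ update is raised to
$\Delta k$, a quantity carrying units of 1/ms (numerically $0.05$). The
exact solution of the recovery ODE gives the dimensionless exponent
$\Delta k\,\tau_{ca}$ instead. We reproduce the printed map by default and
expose the dimensionally consistent variant as `exponent = "ode"` in
`advance_state()`, `simulate_fd_train()` and `fd_fixed_point()`. The
difference matters in one place: with the printed exponent the factor
$\bigl(K_r/(K_r+C)\bigr)^{\Delta k} \approx 0.887$ survives even as
$\tau_{ca} \to 0$, which is equivalent to shortening every recovery interval
by about 70 ms and shifts the whole stationary law of $R$. The closed-form
large-interval fixed point

$$\bar R(T) = \frac{1 - e^{-k_{min}T}}{1 - (1-P_{max})e^{-k_{min}T}}$$

and the stochastic fixed-point densities built on it correspond to the
`"ode"` variant, so every comparison against those laws runs the map with
`exponent = "ode"`; all frequency sweeps use the printed map.

### The two muscarine parameterizations

The fitted muscarine condition ($P_{max}=0.27$, $\Delta=0.17$) is the preset
`fd_params("muscarine")`. However, the reference results for the muscarine
frequency sweeps are internally consistent only with the calcium dynamics
left at the control normalization: with $\Delta = 0.17$ and $K = 0.2$ the
release Hill function saturates at
$P_{max}\cdot 0.17^4/(0.17^4 + 0.2^4) \approx 0.34\,P_{max} \approx 0.09$,
so the stationary response at very low rates cannot approach $P_{max}$ —
yet the reference low-rate muscarine distribution peaks near $P_{max}$,
its mean falls from about $0.3$ to about $0.1$ across 0.1–100 Hz, and
the closed-form stochastic fixed-point density for muscarine is supported on
$[0, P_{max}]$ with mass near $P_{max}$ at low rates. All of these are
reproduced by the *release-only* variant
`fd_params("muscarine", delta = 1)` (reduce $P_{max}$, share the calcium
dynamics), and none by the fitted $\Delta = 0.17$ (which gives a low-rate
mean of $\approx 0.09$, a drop of $\approx 0.05$, and a high-frequency
entropy maximum near 160 Hz instead of ~390 Hz). The package therefore keeps
both: the preset carries the fitted values, and every reference-comparison
sweep in `analysis/`, the acceptance script and the end-to-end tests uses
the release-only variant, stated explicitly at each call site.

## Synthetic stimulation protocol

All data are synthetic. `poisson_isis(rate_hz, n, seed)` draws i.i.d.
exponential ISIs (a homogeneous Poisson train); `fixed_isis()` provides
constant-period trains for fixed-frequency checks. The stationary protocol
used throughout is $2^{14}$ ISIs per frequency after discarding a 100-spike
transient from the initial state $(C, P, R) = (0, 0, 1)$ — baseline calcium
and a full pool. The transient length is a package choice (the collapse to
the attracting fixed point takes on the order of ten map steps, so 100
spikes is conservative); sweeps derive one sub-seed per frequency from the
experiment seed, making every sweep reproducible element-wise regardless of
grid composition.

What the generator deliberately does not emulate: real PV-cell trains are
not Poisson (bursting, theta phase locking), there is no axonal or release
latency jitter, and the quantal model below ignores receptor desensitization
and postsynaptic conductance dynamics. Passing tests therefore validate the
map-plus-estimator machinery under the stated stochastic drive, not the
biology of in-vivo trains.

## Stationary laws

Two closed-form results are implemented and checked against simulation.

**Calcium.** Sampled at spike times, the calcium recurrence with i.i.d.
random influx $\Delta_n$ has a tractable stationary law. With
$\Delta_n \sim \mathrm{Exp}(\text{mean } 1)$ it is exactly
$\mathrm{Gamma}(\lambda\tau_{ca}+1,\,1)$: the decayed shot-noise sum
contributes $\mathrm{Gamma}(\lambda\tau_{ca}, 1)$ and the final influx an
independent $\mathrm{Exp}(1)$. The mean is $\lambda\tau_{ca}+1$ and the
coefficient of variation $1/\sqrt{\lambda\tau_{ca}+1}$. Note the law is
*not* exact for the deterministic map's fixed influx (then $C \ge \Delta$
and the support is wrong); `simulate_calcium()` defaults to exponential
influx and exposes `influx = "fixed"` for the contrast.

**Response.** When $\tau_{ca}$ is much smaller than the ISIs, calcium and
release probability relax within each interval and the response is
approximately the fixed point for the preceding ISI,
$Pr \approx P_{max}\bar R(T)$. Pushing $T \sim \mathrm{Exp}(\lambda)$
through $\bar R$ gives the density of $X = \bar R$,

$$f(x \mid \lambda, a, k_{min}) = \frac{\lambda(1-a)}{k_{min}}
  (1-x)^{-(1-\lambda/k_{min})}(1-ax)^{-(1+\lambda/k_{min})},
  \qquad a = 1 - P_{max},$$

with mean
$E(X) = (1-a)\lambda\bigl(\tfrac{1}{\lambda(1-a)} -
{}_2F_1(1, \tfrac{k_{min}+\lambda}{k_{min}}; 2+\tfrac{\lambda}{k_{min}}; a)
/(k_{min}+\lambda)\bigr)$, and $Y = P_{max}X$ (the *stochastic fixed point*
of the response) has the scaled density on $[0, P_{max}]$. Because $\bar R$
is monotone, the CDF and quantile function are available in closed form;
QQ comparisons use exact quantiles, not numeric inversion. The
hypergeometric function is evaluated by its power series (the arguments here
have $|z| = 1 - P_{max} \le 0.73$, far inside the unit disc; tolerance
$10^{-12}$), and the densities are computed in log space because the factor
$(1-x)^{\lambda/k_{min}-1}$ under/overflows near $x = 1$ for extreme rate
ratios.

The approximation has a known failure mode that no parameter choice
removes: after a single short ISI the simulated pool falls only to
$(1-P)R \approx 0.13$, whereas $\bar R(T) \to 0$ as $T \to 0$, so the law
overfills the lower tail. QQ plots of simulated responses against the law
are straight (Pearson $r^2 \approx 0.999$ for mean ISIs of 50–2000 ms at
$\tau_{ca} = 0.01$ ms) but bend at the bottom (identity-line $R^2 \approx
0.98$), and agreement degrades for mean ISIs below ~10 ms. The tests assert
exactly that.

## The stochastic response model

The deterministic $Pr$ fixes only the mean pathway; information
transmission needs response variability. Following the Katz quantal
picture, $K \sim B(N, Pr)$ vesicles are released from $N$ independent sites,
and each contributes a quantal amplitude drawn from a normal law with mean
$\mu$ and s.d. $\sigma$, two-sided truncated to $(0, 2\mu)$; the response is
$S = 0$ on failure and the sum of the $K$ quantal draws otherwise. Defaults:
$\mu = 0.5$, $\sigma = 0.1$ (fitted), and $N = 10$ — the number of release
sites is not constrained by the map fit, so it is an explicit model choice,
recorded in every result table; absolute MI values scale with it, which is
why between-condition comparisons are made at matched $N$ and
peak-to-baseline MI ratios are treated as qualitative. Truncated normals are
sampled by inverse CDF (exact, no rejection); summation of $K$ truncated
draws is the generative default, with the untruncated
$N(K\mu, \sqrt{K}\sigma)$ shortcut available as `method = "normal"`.
Failures ($S = 0$) are part of the response law — the atom at zero carries
the failure probability $(1-Pr)^N$ — and are included in the response
histograms by default.

## Information measures

Histogram estimators work in bits. The response–ISI mutual information
$I(S;T) = H(S) + H(T) - H(S,T)$ uses Freedman–Diaconis binning
($nbins = \mathrm{range}/(2\,\mathrm{Iqr}\,n^{-1/3})$, rounded up;
square-root fallback with a warning when the interquartile range is zero)
independently on each axis. Entropy sweeps of the $Pr$ distribution instead
use a fixed partition — 100 equal bins on $[0,1]$ — held constant across
frequencies and conditions, because entropies on data-adaptive partitions
are not comparable across conditions. The bin count is a package choice;
the location of the *low*-frequency entropy maximum is insensitive to it
(any fixed equal-width partition is maximized where the distribution is
flattest), which pins that maximum near 1.9–2 Hz where the control
distribution is flat; no fixed equal-width partition can move it to higher
rates where the distribution is already skewed. Sum-history MI uses
$t_k = \sum_{i=1}^k T_i$ (the $k$ ISIs preceding each response) and the
symmetric three-entropy form of $I(S;t_k)$.

The $n$-tuple history measure $I(\langle T_1..T_n\rangle; Pr)$ cannot use
histograms (curse of dimensionality); it uses k-nearest-neighbor
estimators: the Kozachenko–Leonenko entropy
$\hat H = \psi(N) - \psi(k) + \log c_d + \frac{d}{N}\sum_i \log\epsilon(i)$
and the KSG (variant 1) mutual information
$\hat I = \psi(k) + \psi(N) - \langle\psi(n_x{+}1) + \psi(n_y{+}1)\rangle$,
max-norm metric, default $k = 4$, in nats with explicit conversion to bits.
Neighbor search is exact brute force in compiled code with early-exit
distance evaluation — at $N = 2^{14}$, $d \le 7$ this is faster in practice
than tree structures. Two numerical choices matter. Duplicate points make
$\log \epsilon$ diverge; ties are broken by optional uniform jitter of
half-width $10^{-10}$ (on by default in the history pipeline, off in the
bare estimators, which instead raise an error). And in the history
pipeline every coordinate is standardized before the search: the estimator
is scale-invariant only asymptotically, and with raw coordinates the ISI
axes (hundreds of ms) dominate the max-norm so completely that the response
coordinate is starved of resolution and the estimate collapses. The
deterministic $Pr$ (not the noisy $S$) is the response coordinate in tuple
mode, which isolates the history dependence of the map itself.

Estimator calibration is part of the test suite: KSG on bivariate Gaussians
($\rho \in \{0.3, 0.6, 0.9\}$, $N = 10^4$, $k \in \{3,4,6\}$) within 0.02
nats of $-\tfrac12\ln(1-\rho^2)$; KL entropy of $U[0,1]$ within 0.02 nats of
0; histogram MI exactly equal to an enumeration oracle on explicit 4×4
joint tables.

## Locating entropy maxima

The entropy-rate curve is estimated pointwise with Monte-Carlo noise of a
few hundredths of a bit, and its high-frequency maximum is a broad
asymmetric bump, so the grid argmax alone is unstable. `locate_entropy_maxima()`
smooths with a centered running mean, finds interior local maxima of the
smoothed curve, and refines each by a least-squares parabola over a window
of raw points around it (fit in $\log_{10} f$ on logarithmic grids). On the
5 Hz-step high grid we use a ±25 Hz smoothing window and a ±75 Hz fitting
window; across seeds this places the control maximum within a few Hz of
265 and the muscarine maximum near 340. A wider fitting window drags the
vertex down the bump's long left shoulder — a bias of the symmetric
parabola, not a feature of the curve.

## Problem sizes and reproducibility

The canonical protocol ($2^{14}$ samples per frequency) is used for every
headline number. The sweeps behind the acceptance script cover a 60-point
logarithmic grid on 0.1–20 Hz and a 5 Hz-step linear grid on 50–1000 Hz;
the tuple-history analyses go to depth 6 at $2^{14}$ samples. Unit tests
run reduced problem sizes ($2^{10}$–$2^{12}$) where only correctness, not a
headline quantity, is at stake. Every stochastic routine takes an explicit
seed, restores the caller's RNG state, and derives per-frequency sub-streams
so that results are bit-reproducible given (configuration, seed).

## Known limitations

* The map is parameterized for one synapse type in one preparation;
  facilitation-dominant regimes are outside the shipped presets.
* The stochastic fixed-point law is an approximation with an inaccurate
  lower tail (see above); no closed form exists for the stationary law of
  $Pr$ under the full map.
* Histogram MI carries positive finite-sample bias, so MI values at high
  rates flatten above zero rather than decaying to it; between-condition
  *differences* at matched protocol are the meaningful quantity.
* Absolute MI levels depend on the unconstrained $N$ (release sites);
  only their structure across frequency, depth and condition is
  interpretable.
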