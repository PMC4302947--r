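---
title: "Event-driven simulation of spike-based BCPNN synapses"
author: "bcpnnsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven simulation of spike-based BCPNN synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcpnnsim)
```

## The model

A spike-based BCPNN (Bayesian Confidence Propagation Neural Network)
synapse estimates, online, the probabilities that its presynaptic unit is
active, that its postsynaptic unit is active, and that both are active
together. It does so with a cascade of three linear low-pass filters per
site. Spikes first enter the fast **Z traces** (time constants
$\tau_{zi}, \tau_{zj}$, 5–100 ms, the synaptic-receptor scale): a spike
adds $+1$ to its Z trace, which otherwise decays exponentially. The Z
traces feed the **E (eligibility) traces** with $\tau_e$ (20–1000 ms),
where a separate trace $E_{ij}$ filters the *product* $Z_i Z_j$ and hence
tracks coincident activity. The E traces feed the slow **P traces** with
$\tau_p$ (seconds and beyond); the P traces are the probability estimates.
A global learning-rate parameter $\kappa \ge 0$ scales the speed of the P
stage: while $\kappa$ is constant and positive the P dynamics are a
first-order filter with effective time constant $\tau_p^* = \tau_p /
\kappa$, and $\kappa = 0$ freezes learning entirely.

From the P traces the synapse computes its two outputs,

$$\beta_j = \ln(P_j + \epsilon), \qquad
  w_{ij} = \ln\frac{P_{ij} + \epsilon^2}{(P_i + \epsilon)(P_j + \epsilon)},$$

the log prior of the postsynaptic unit and the log odds of co-activation.
$\epsilon$ is the assumed minimum activity; it keeps both logarithms
finite for silent units. These are the standard readouts of the
spike-based rule; both are hooks that can be replaced. With the default
initial state ($Z = E = 0$, $P_i = P_j = \epsilon$,
$P_{ij} = \epsilon^2$) the weight starts at $\ln\tfrac12$ and the bias at
$\ln 2\epsilon$.

## Three engines, one trajectory

`run_synapse()` drives a synapse over a pair of spike trains with one of
three engines that share a sampling contract (all traces plus $w$ and
$\beta$ recorded at every spike time, after that spike's update):

* **euler** — explicit fixed-step Euler on the cascade, the conventional
  clock-driven reference. All right-hand sides use start-of-step values
  and the spike increment lands within its step after the decay; this
  keeps the scheme first-order consistent, and its error at spike times
  scales linearly with `dt` (verified by a dyadic step sweep in the test
  suite).
* **analytical1** — exact event-driven updates of the canonical eight
  traces. Between spikes each cascade has a closed-form solution (a sum of
  the three exponentials of its stage time constants); states are advanced
  only when a pre- or postsynaptic spike arrives.
* **analytical2** — exact event-driven updates of a transformed state.
  Because the system is linear, the trajectory can be carried by purely
  exponential state variables $Z^*, E^*, P^*$ (one per time constant and
  site): between spikes every variable just multiplies by
  $e^{-\Delta t/\tau}$, and at a spike the presynaptic triple gets $+1$
  while the synaptic pair gets $+Z$ of the opposite side. The canonical
  traces are recovered as fixed linear combinations
  ($P_i = \lambda_{zi} Z^*_i + \lambda_{ei} E^*_i + \lambda_{pi} P^*_i$,
  and analogues), which costs a few extra operations only when a readout
  is actually needed. This roughly halves the arithmetic per update
  (`count_ops()` measures the exact tally by running the kernels under a
  counting backend).

The closed forms require the three time constants of each cascade to be
pairwise distinct ($\tau_{zi}$ may equal $\tau_{zj}$); equal values raise
a "degenerate time constants" error rather than silently switching to a
different solution family. Coincident pre- and postsynaptic spikes are
evaluated consecutively, presynaptic first — the synaptic increment then
is $S_i Z_j^- + S_j Z_i^+$, algebraically identical to the symmetric form
$S_i Z_j^- + S_j Z_i^- + S_i S_j$.

A changed $\kappa$ changes $\tau_p^*$ and therefore all derived
coefficients; engines handle it by synchronising the state to the change
time, recomputing coefficients, and (for analytical2) converting through
the canonical representation. $\kappa = 0$ cannot be represented in the
exponential state (its $\lambda$ coefficients vanish), so the event-driven
simulation of a frozen synapse runs in canonical form with the P traces
held constant; the outputs are identical.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `tau_zi`, `tau_zj` | pre-/postsynaptic Z time constants | ms | 10, 15 |
| `tau_e` | eligibility time constant | ms | 20 |
| `tau_p` | probability time constant | ms | 1000 |
| `kappa` | learning rate (scales the P stage) | – | 1 |
| `eps` | minimum activity, log regulariser | – | 0.001 |
| `dt` | simulation grid step | ms | 1 |

The defaults are the benchmark set used throughout the package and the
test suite. Spike times are restricted to multiples of `dt`; internally
spikes are integer step indices, so no floating-point time error can
accumulate over long runs (file I/O converts to milliseconds).

## Look-up tables

On the integer grid every decay factor is $e^{-N\,dt/\tau}$ for an
integer gap $N$, so the engines can serve decay factors from four
pre-computed tables (one per engine time constant), falling back to the
identical expression for gaps beyond the table length $L$. The tables are
exact caches, not approximations: a LUT-backed run is bit-identical to a
plain run, which the suite asserts. The default $L = 3000$ at 1 ms covers
gaps up to 3 s, i.e. about $1 - e^{-3} \approx 95\%$ of the inter-spike
intervals of a 1 Hz Poisson input (`lut_coverage()`); the best $L$ is
hardware- and workload-dependent and is left as a configuration knob.
Interpolated tables for off-grid times and split integer/fraction
exponentials are documented alternatives, not implemented.

## Fixed-point storage emulation

For memory-constrained implementations the package emulates storing the
analytical2 state variables in a `Qi.f` fixed-point format: arithmetic
runs in double precision, but every value written back to a state
variable is rounded to `f` fractional bits and saturated to the format
range. Rounding is to nearest with ties to even — symmetric, so the
quantisation acts like an additive noise source of amplitude $2^{-f}$;
whether a hardware target would saturate or wrap on overflow is not
prescribed anywhere, and saturation was chosen as the safe behaviour.
Derived coefficients are held at 32 fractional bits. Reconstructed
probabilities are clamped at zero before the logarithm: with coarse
storage the linear combination can land a rounding step below zero.

Integer bits are sized analytically: a trace driven at a sustained
maximum rate $r_{max}$ equilibrates at
$S / (1 - e^{-1/(r_{max}\tau)})$, which approaches $r_{max}\,\tau\,S$
for $r_{max}\tau \gg 1$ (`value_range_bound()`). For the slowest default
trace ($\tau_p^* = 1$ s) and a 1 ms refractory ceiling the bound is
$\approx 1000$, i.e. 10 integer bits suffice
(`integer_bits_required()`).

In the accuracy benchmark the NMAE of the stored variables and of
$\beta_j$ scales cleanly as $2^{-f}$. The weight inherits that scaling
only once the noise is small compared to $P_{ij}$: the log-odds readout
amplifies coarse-resolution noise nonlinearly when $P_{ij} + \epsilon^2$
is tiny, so the suite fits the $w$ slope in the asymptotic bit range.

## The accuracy benchmark

`accuracy_benchmark()` follows a fixed protocol: pre/post Poisson trains
of 1 Hz sharing a fraction $c$ of spike times ($c = 0 \ldots 1$ in steps
of 0.1, ten stimulus seeds each, 1000 s per run, shared postsynaptic
spikes jittered by a 5 ms Gaussian to avoid a systematic zero lag). Each
stimulus is simulated with the exact canonical event-driven solution in
double precision (the reference) and with the approximate engine under
test; absolute errors of $P_i$, $P_j$, $P_{ij}$, $w$, $\beta$ are sampled
at every spike time (after that spike's update — the convention applied
consistently to reference and approximation) and pooled over all 110
runs. The normalized mean absolute error divides the pooled mean absolute
error by the pooled reference range, using the pooled (not per-run) range
so that variables of different scales are comparable.
`equal_error_bits()` reuses one stimulus set to find the smallest
fractional-bit count whose NMAE matches or beats a given Euler step size
for both $w$ and $\beta$.

The generator approximates a Poisson process by at most one spike per
grid step (probability `rate*dt`), consistent with the grid-restricted
simulation; jittered shared spikes falling outside the run are dropped
and collisions on a step are merged. What the synthetic stimuli do *not*
emulate: non-stationary rates, refractoriness, bursting, and
network-generated correlations beyond the single shared-spike mechanism —
so passing benchmarks bound numerical error, they do not validate the
rule against biological data.

## The reduced hypercolumn

`hcu_run()` embeds the synapse array in the reduced cortical module: `M`
minicolumn units (MCUs, default 100) receive input from `n_inputs`
(default 10\,000) units through plastic BCPNN synapses. Each MCU is a
leaky integrator (membrane time constant $\tau_m \approx 10$ ms) of its
bias, its exponentially decaying synaptic current (incremented by
$w_{ij}$ at each presynaptic spike), and an external input. Activations
are a probabilistic soft winner-take-all: $o_j = e^{\gamma_m m_j}$,
normalised by the sum whenever the sum exceeds one (then
$\sum_j o_j = 1$, so on average at most one MCU is active), and the
firing rate is $o_j \, r_{max,HCU}$ (default 100 Hz). Spikes are drawn
per step with probability $\min(r\,dt, 1)$ — the linear form of the
rate-to-probability transform, appropriate for $r\,dt \ll 1$ (the
alternative $1 - e^{-r\,dt}$ differs only at second order). The units and
scaling of $\gamma_m$ and the external input are free configuration
parameters. The bias is refreshed every step (it enters every MCU's
support), while the synapse array is updated only at spike events; the
weight applied at spike delivery is the value after that spike's
plasticity update (the alternative order is a documented configuration
point, not a different model). Storing the array's synaptic traces and
weights plus the marginal traces in single precision exceeds 12 MB at
full scale (`memory_footprint()`), which is what motivates both the
event-driven update and the fixed-point storage.

`runtime_benchmark()` reports wall-clock time per simulated second and
the structural update counts for a rate sweep with pre-generated,
clamped input and output trains. Wall-clock numbers are
hardware-dependent and informational only; the asserted quantities are
the counts — event-driven updates equal spikes times the touched array
dimension, clock-driven updates equal steps times the array size.

## Numerical and design choices

* **Unit spike increments.** A spike adds exactly $+1$ to its Z trace
  (and the sampled $Z$ of the opposite side to the synaptic pair); the
  cascade is interpreted as decay plus unit jumps, not as a Dirac input
  scaled by $1/\tau$.
* **Initial conditions.** $Z = E = 0$, $P_i = P_j = \epsilon$,
  $P_{ij} = \epsilon^2$ by default, fully configurable. This makes the
  initial outputs finite and reproduces the observed minima of the
  benchmark statistics.
* **Final state semantics.** `run_synapse()` reports the final state
  decayed to the end of the run, not at the last event, so engines and
  array simulations are comparable at a common time.
* **Operation counting.** One convention throughout: every binary
  addition/subtraction and multiplication/division on state math counts;
  each distinct decay factor costs one division and one EXP per task;
  per-parameter constants are precomputed (the compound margin
  coefficient $a_i b_i$ included, while the synaptic product
  $a_{ij} b_{ij}$ is formed inline in the kernel); elapsed-step products
  and control flow are bookkeeping. The counts are measured by running
  the kernels under the counting backend, never transcribed.
* **Tolerances.** Engine-equivalence assertions use $10^{-9}$ relative at
  spike times; transform round trips $10^{-9}$; dense-Euler oracle
  comparisons $10^{-4}$ (first-order scheme at $10^{-3}$ ms steps).
* **Problem sizes in the suite.** The module tests use scaled stimuli
  (up to a few hundred seconds, arrays up to $50 \times 8$); the
  acceptance suite runs the full 110-run protocol at 1000 s on the 1 ms
  grid and a 100 s variant on the 0.1 ms grid, sizes chosen so the whole
  suite completes in minutes on one core.

## Known limitations

* Equal time constants within a cascade have no closed form here; they
  are rejected, not approximated.
* Only piecewise-constant $\kappa$; no continuous $\kappa(t)$.
* Single hypercolumn; multi-module networks, spike routing and
  distribution across processes are out of scope.
* Off-grid (continuous-time) spike times are not supported; stimuli
  generated at finer resolution are regridded.
* Probabilistic fractional bits and log-domain storage of the traces are
  documented future work, not implemented.
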