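---
title: "Network bursts from adaptive oscillatory neurons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network bursts from adaptive oscillatory neurons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netburst)
```

## The phenomenon and the model

Dissociated cortical and hippocampal cultures, and several brain circuits,
spontaneously settle into *network bursting*: long quiescent stretches
punctuated by brief population-wide volleys in which most neurons fire a
handful of tightly packed spikes.  `netburst` models this regime with the
adaptive exponential integrate-and-fire (aEIF) neuron, which couples the
membrane potential $V$ to a slow adaptation current $w$:

$$\dot V = -(V - E_L) + e^{V} - w + I_e + I_s(t), \qquad
  \tau_w \dot w = a\,(V - E_L) - w,$$

with the reset rule $V \to V_r$, $w \to w + b$ whenever $V$ exceeds the
cutoff $V_{peak}$.  All quantities are dimensionless: potentials are
measured in units of the spike slope factor $\Delta_T$ relative to the
threshold $V_{th}$ (so the threshold sits at 0), currents in units of
$g_L \Delta_T$, and time in membrane time constants $\tau_m = C_m/g_L$.
`to_dimensionless()` performs this change of variables from physiological
units and keeps the scales attached so every output can be reported in
mV/ms/pA again.

Two ingredients produce collective bursts without any inhibition or
synaptic plasticity:

* **intrinsic oscillation** — the drive $I_e$ exceeds the rheobase
  $(1+a)(\ln(1+a) - 1 - E_L)$, so the rest state has vanished and each
  neuron would spike periodically on its own;
* **spike-driven adaptation** — each spike increments $w$ by $b$, and $w$
  relaxes slowly ($\tau_w \gg 1$), so repeated firing self-limits.

Neurons are coupled by alpha-shaped post-synaptic currents
$s I_0\, t\, e^{-t/\tau_s}$ delivered one transmission delay $d$ after each
presynaptic spike; one PSC transfers the charge $Q_s = s I_0 \tau_s^2$.
Networks are random digraphs in which each node draws its in-degree (fixed
at $k$, or normal with mean $\bar k$ and spread $\sigma_k$) and picks that
many distinct presynaptic partners uniformly.

## The equivalent autapse neuron

In a *synchronized* fixed in-degree network every neuron receives, after
each volley, exactly $k$ simultaneous PSCs — so the whole network is
dynamically identical to one neuron with a self-loop of strength $k s$
(`simulate_equivalent_neuron()`).  The package treats this reduction both as
a theorem about the simulator (the test suite asserts spike-for-spike
equality with the full network) and as the basis of the analytic model.

A burst cycle reads off the $(V, w)$ phase plane.  The V-nullcline
$w_{NV}(V) = -(V - E_L) + e^V + I_e + I_s$ has a single minimum
$w_{min} = 1 + E_L + I_e + I_s$ at $V = 0$; its right branch
$$V_{NV}(w) = u - W_{-1}(-e^{u}), \qquad u = E_L + I_e + I_s - w,$$
(with $W_{-1}$ the lower Lambert branch) acts as an effective spike
threshold.  A burst *starts* when the decaying $w$ passes under the
nullcline minimum, and *terminates* at the critical value $w^*$ at which
the delivered volley can no longer lift the trajectory over $V_{NV}(w)$.
Because $\tau_w$ is large, $w$ is treated as frozen within one interspike
interval (the quasi-static approximation), and since each burst spike adds
$b$, the spikes per burst, peak adaptation, in-burst interval chain, burst
duration and interburst interval all follow from $w^*$
(`predict_bursts()`):

* $n_s = \lceil (w^* - w_{min})/b \rceil$;
* $w_{max} = w_{min} + n_s b$ for fixed in-degree networks (discrete
  ladder), $w_{max} = w^*$ with heterogeneity (smooth population average);
* $T_B = \sum_{j=1}^{n_s-1} t_s(w_{min} + j b)$ with $t_s$ the
  quasi-static interspike interval;
* $T_{down}$, the fast hyperpolarization after the last spike, integrated
  numerically from $(V_r, w_{max})$ to the potential minimum;
* $T_R = \frac{\tau_w}{1+a}\,
  \ln\frac{w^{(2)} - a I_e/(1+a)}{w_{min} - a I_e/(1+a)}$, the slow
  recovery along the quasi-equilibrium;
* $IBI = T_{down} + T_R + 1$, the final $1$ being the first-spike
  initiation time (one membrane time constant).

### The three coupling idealizations

The time course of $I_s$ during a burst is idealized in three ways,
bracketing real networks:

* **Dirac** (`solve_w_star_dirac()`): each volley is an instantaneous kick
  $V \to V + \bar k Q_s$ arriving $d$ after the previous spike.  With the
  membrane linearized during the decay segment, the termination condition
  "post-kick potential = threshold branch" becomes the closed
  self-consistent relation
  $$w^* = E_L + I_e - V_r - e^{d}\left[W_{-1}(-e^{E_L+I_e-w^*})
    + \bar k Q_s\right],$$
  solved by Brent bracketing to a residual below $10^{-10}$.  This is the
  synchronized fixed in-degree limit.
* **Continuous** (`solve_w_star_continuous()`): in a strongly heterogeneous
  network the volley structure washes out; the burst is modelled as a
  constant current $I_s^{(c)}$ whose charge matches the spiking picture,
  $I_s^{(c)} T_B = n_s \bar k Q_s$.  Together with the shifted-nullcline
  condition $w^* = 1 + E_L + I_e + I_s^{(c)}$ and the termination relation
  $w^* = w_{min} + b[\bar t_s - d] + \bar k Q_s$ this forms a small
  fixed-point system, iterated with damping 0.5.  The three relations are
  mutually consistent only if the burst duration inside the solver is
  *defined* by the charge-matching relation ($T_B = n_s \bar k Q_s /
  I_s^{(c)}$, $\bar t_s = T_B/(n_s-1)$); that is how the solver closes the
  system, and both residuals vanish at the returned solution.  Near a
  spike-count boundary the discrete system can have no fixed point (the
  damped iteration enters a period-2 cycle); this is reported as an
  iteration failure rather than silently averaged.
* **Alpha** (`solve_w_star_alpha()`): the full kernel moves the nullcline
  during the burst, so no closed form exists; the equivalent autapse is
  integrated from burst onset $(V = 0, w = w_{min})$ and termination is
  detected when an interspike interval exceeds ten times its predecessor.
  The alpha solution lies between the two closed-form limits and converges
  to the Dirac one as $\tau_s \to 0$ at fixed charge.

The quasi-static interspike interval is computed as
$t_s(w) = d + \int_{V_0}^{V_{peak}} dV / (e^V - V + E_L + I_e + I_s - w)$,
the exact frozen-$w$ passage time from the post-delivery potential to the
cutoff.  A purely linearized crossing-time formula cannot reproduce the two
properties the interval demonstrably has — monotone growth with $w$ and
divergence as the start point approaches the nullcline (the stretching of
late burst slices) — because the linearized flow moves *away* from the
spiking branch; the frozen-$w$ quadrature has both and matches the
event-driven oracle interval by interval.

## Reference parameters ("Set 1")

The packaged reference set (`set1_parameters()`,
`inst/extdata/params_set1.yaml`) is a **synthetic stand-in** assembled from
typical cortical-culture aEIF values, not a transcription of any published
table:

| quantity | physical | dimensionless | rationale |
|---|---|---|---|
| $C_m$, $g_L$ | 200 pF, 10 nS | $\tau_m = 20$ ms | common cortical values |
| $E_L$, $V_{th}$, $\Delta_T$ | −70, −50, 2 mV | $E_L = -10$ | standard aEIF |
| $V_r$ | −58 mV | −4 | fast AHP; below threshold (single-spike cells) |
| $V_{peak}$ | −40 mV | 5 | cutoff $V_{th} + 5\Delta_T$ |
| $\tau_w$ | 1.2 s | 60 | slow-AHP-like; deep quasi-static regime |
| $a$, $b$ | 2 nS, 70 pA | 0.2, 3.5 | spike-driven adaptation dominant |
| $I_e$ | 240 pA | 12 | just above the rheobase (11.02): oscillatory |
| $\tau_s$, $d$ | 1 ms, 3 ms | 0.05, 0.15 | fast excitatory kinetics |
| $s$ | 856 | $\bar k Q_s = 10.7$ at $\bar k = 100$ | see below |

The coupling strength is the one genuinely free constant.  It was fixed
once, using the package's own alpha-model solver, to the midpoint of the
coupling window in which a 100-in-degree network produces six spikes per
burst — the regime the reference set is meant to represent.  The delay was
set to 3 ms so that the burst's final (longest) interspike interval stays
below the burst-detection bound $3d$.  At these values the network bursts
with $n_s = 6$, $T_B \approx 28$ ms and $IBI \approx 3.3$ s.

## Simulation engine

The simulator is a vectorized fixed-step integrator: a Heun (explicit
second-order) update for $(V, w)$ with the exponential clamped at
$V_{peak}$, an auxiliary linear system for the alpha PSCs advanced with
*exact* exponential propagators (so synaptic charge is conserved to
round-off regardless of `dt`), and a ring buffer of length $d/\mathrm{dt}$
for delayed delivery.  Spikes are detected at step boundaries (no
interpolation); a neuron above the cutoff at a step start is reset before
integrating.  The delay must be an integer multiple of `dt`.

Initial conditions emulate an asynchronous culture: $w \sim
\mathcal N(2.5, 0.5)$ dimensionless (50 ± 10 pA at the reference scales)
and $V$ uniform on $[V_r, 0]$.  The synchronization transient is not part
of the modelled attractor; analyses discard the first few bursts (default
3).  With the reference synapse ($\tau_s = 0.05$), production runs use
`dt = 0.0025` (0.05 ms): halving it changes burst-level statistics by less
than 1%, which the test suite asserts.  The generic default `dt = 0.01`
suits slower synapses.

## Burst detection

Pooled spike times are split at gaps exceeding $\min(N t_\nu/2,\ 3d)$,
where $t_\nu = T/N_s$ is the inverse population rate, and groups engaging
fewer than 20% of the neurons are discarded.  The rate scale is the mean
*single-neuron* interspike interval $N t_\nu$: the pooled scale itself is
smaller than the gap between consecutive burst slices in any synchronized
population (a thousand coincident spikes make $t_\nu$ tiny), and a
threshold below the slice spacing would shred every burst into its
slices — no per-burst spike count could then exceed one.  For a
single-neuron raster the two scales coincide.  In practice $3d$ is the
binding bound for bursting rasters.

## Parameter-space exploration

`explore()` samples physiological parameter sets uniformly (defaults:
$C_m \in [100, 300]$ pF, $g_L \in [5, 15]$ nS, $E_L \in [-75, -60]$ mV,
$\Delta_T \in [1, 3]$ mV, $V_{th} \in [-55, -45]$ mV,
$V_r \in [-68, -48]$ mV, $\tau_w \in [0.3, 2]$ s, $a \in [0, 4]$ nS,
$b \in [10, 120]$ pA, $I_e \in [100, 500]$ pA — plausible cortical spans,
fully user-configurable), converts each to dimensionless form, predicts its
burst structure with a fully vectorized batch solver, and applies five
biological validity filters: spiking regime, coherent model solution,
post-burst potential above −120 mV, peak adaptation below 1000 pA, and
reset below threshold.  About half of the default draws survive.  Burst
properties are then standardized and Pearson-correlated with the
parameters.

Two design choices here were genuinely open:

* **Model variant.**  The batch predictor uses the *continuous* threshold,
  in which the spike increment $b$ enters $w^*$ directly through the mean
  interspike term — this is the structure that makes spike-driven
  adaptation's imprint on the interburst interval visible.  The Dirac
  threshold contains no $b$ at all, and with it the ranking of the (small)
  $a$- and $b$-correlations with the IBI is essentially a coin flip.  The
  peak adaptation feeding the recovery time uses the discrete ladder form
  $w_{min} + n_s b$, the canonical fixed-ensemble reading.
* **Throughput.**  The whole chain (threshold bisection/fixed point,
  interspike quadratures, vectorized RK4 descent) is array-valued; tens of
  thousands of parameter sets per second on one core make million-set
  ensembles a matter of minutes.

## Numerical choices and edge cases

* Lambert $W_{-1}$ is evaluated in log space (fixed point plus Newton
  polishing, series at the branch point); the variant taking the exponent
  directly avoids underflow of $e^{u}$ when the adaptation is far above
  the nullcline minimum.  It is cross-checked against an independent
  implementation in the tests.
* Root brackets for $w^*$ are widened geometrically at most five times
  before a no-bursting-solution error; the degenerate tangency (adaptation
  exactly at the nullcline minimum) counts as "no crossing".
* An overshooting kick ($V_0 \ge V_{peak}$) fires immediately: the
  interspike interval is then exactly $d$, which pins the early slices of
  strongly coupled bursts.
* The recovery-start adaptation $w^{(2)}$ defaults to $w_{max}$ (the
  hyperpolarization overshoot is brief on the $\tau_w$ scale) and can be
  overridden.
* The hyperpolarization descent is integrated with classical RK4 rather
  than a closed form: the closed-form constants would require the
  quasi-equilibrium entry point, which the integration determines anyway,
  and the same code yields the minimum potential needed by the validity
  filter.

## What the synthetic conditions do and do not show

The generators emulate the idealized study system: homogeneous aEIF
populations, identical synapses, no spatial structure, no inhibition, no
short-term plasticity, noise only in the initial conditions and the graph
draw.  Passing tests therefore demonstrate internal consistency of the
simulator and the analytic model, and reproduction of the qualitative
phenomenology (synchronized bursting, heterogeneity thinning bursts,
ordering of the three coupling idealizations) — they do not certify
quantitative agreement with any particular biological culture.

Validation is two-tier, and the tier matters:

* the **Dirac solver vs. event-driven oracle** comparison (2%) is a tight
  algebra check run where the quasi-static derivation is actually valid:
  reference sets are drawn with $\tau_w \ge 200\,\tau_m$ and excluded when
  the adaptation shifts the derivation neglects — the interspike drift and
  the fold-passage undershoot at onset, both estimated analytically from
  the prediction itself — approach either the spike-count boundary or 1%
  of the observable.  Near such boundaries the discrete spike count is
  ill-conditioned (the peak adaptation jumps by $b$ under infinitesimal
  perturbations) and *no* numerical oracle can agree to 2%;
* the **alpha model vs. full network simulation** comparison (15%) covers
  the realistic regime ($\tau_w = 60\,\tau_m$), where those neglected
  terms are part of the discrepancy.

Problem sizes used by the packaged checks: networks of 1000 neurons
(50–500 for the equivalence, bracketing and alpha-comparison runs),
simulation spans of 4–7 burst cycles, twenty random reference sets for the
oracle comparison, and $2\times 10^4$ sampled parameter sets (over $10^4$
accepted) for the correlation structure.

## Known limitations

* A single adaptation timescale: fast, medium and slow after-
  hyperpolarization map onto $V_r$, $b$ and $\tau_w$, but cannot act
  simultaneously with distinct kinetics.
* The model describes the fully synchronized attractor; the gradual
  transition from asynchronous firing to bursting is outside its scope,
  and very strong coupling (one PSC driving several spikes) is excluded as
  biologically irrelevant.
* Heterogeneity effects are bracketed, not resolved: simulated Gaussian
  networks fall between the Dirac and continuous predictions, but the
  continuous limit bounds how far heterogeneity can thin bursts — at the
  reference coupling the spikes-per-burst count saturates near two-thirds
  of the homogeneous value (about 4 at $\sigma_k = 20$), even as
  $\sigma_k$ grows.
* Exact event-driven network simulation is used only as a single-neuron
  oracle; the network integrator is fixed-step with grid-quantized spike
  times.
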