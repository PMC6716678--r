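---
title: "Learning to synchronize: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning to synchronize: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncrl)
library(dplyr)
```

## The problem

Sequentially trained neural networks overwrite old associations when they
learn new ones — the stability–plasticity dilemma. `syncrl` simulates a
hierarchical architecture that addresses it by *gating through oscillatory
synchrony*: a classic task-learning network (Rescorla–Wagner or
backpropagation) is divided into task modules whose communication with the
input (and output) layer is modulated by gamma-band phase oscillations.
A reinforcement-learning controller decides *which* module to synchronize
with the task at hand; modules that are actively desynchronized are, in
effect, disconnected — their activations stay near zero, and because
synaptic change requires presynaptic-postsynaptic co-activation, their
weights are protected.

## The model

### Neuronal triplets

Every network node is a triplet: an excitatory/inhibitory phase-code pair
$(E, I)$ and a rate-code neuron $x$. The phase pair follows discrete
updates at $\Delta t = 2$ ms,

$$\Delta E = -C\,I - Damp\cdot J(r > r_{min})\,E + B(t), \qquad
  \Delta I = +C\,E - Damp\cdot J(r > r_{min})\,I,$$

an Euler-discretized harmonic oscillator whose radius
$r = \sqrt{E^2 + I^2}$ is attracted to $r_{min}$ whenever it exceeds it
($J$ is the indicator). Processing-unit nodes oscillate in the gamma band
(40 Hz; $Damp = 0.3$, $r_{min} = 1$); the medial-frontal controller node
(pMFC) oscillates at theta (5 Hz; $Damp = 0.003$, $r_{min} = 0.05$), so its
amplitude decays slowly between control episodes.

The rate neuron is gated by its own excitatory phase:
$x = f(net - bias)\cdot G(E)$ with $G(E) = 1/(1+e^{-5(E - 0.6)})$. Nodes in
the backpropagation network use a logistic $f$ with $bias = 5$; nodes in
the Rescorla–Wagner network are linear with no bias. The gate is open only
near the peak of the excitation cycle, so two nodes communicate efficiently
only when their oscillations are in phase.

### Binding by random bursts

The controller synchronizes and desynchronizes modules with *correlated
noise*. Lateral-frontal (LFC) pointers assign $+1$ to the task-relevant
module (and to the input/output layers) and $-1$ to the others. At each
step the pMFC rate neuron emits a Bernoulli burst with probability
$p = 1/(1+e^{-10(E_{pMFC}-1)})$ — bursts are phase-locked to the top of the
theta cycle and require theta amplitude of order one — and each Processing
node receives $B_i(t) = LFC_i \cdot pMFC(t)\cdot U(t)$ with a *single*
standard-normal draw $U(t)$ shared by all nodes. Same-sign nodes therefore
receive identical kicks and are driven into phase; opposite-sign nodes
receive mirrored kicks and are driven into anti-phase. Once a pair is
exactly anti-phased, shared $\pm$ kicks preserve the anti-phase exactly:
the noise carries no relative component.

The pMFC itself is pumped by the previous trial's negative prediction
error: during the inter-trial interval, Bernoulli kicks of size
$\delta^-_{n-1}$ arrive with a Gaussian-shaped success probability peaking
200 ms after feedback (SD 25 ms, the empirical latency of feedback-related
midfrontal activity). One error therefore pumps theta amplitude sharply
(the window sums to roughly 31 expected kicks on the 2-ms grid), after
which the amplitude decays back toward its floor — theta power and
synchronizing bursts are high exactly while the model is failing.

### The reinforcement-learning unit

A reward-value circuit assigns each module a value $Q_i$; the value of the
pointed module is the reward prediction $V$, compared against the binary
reward to give rectified prediction errors $\delta^+ = \max(R-V,0)$,
$\delta^- = \max(V-R,0)$. Values update multiplicatively,
$\Delta Q_i = \alpha V \cdot \frac{LFC_i+1}{2}(\delta^+-\delta^-)$, with
$\alpha = 0.1$ (RW) or $0.01$ (BP). A switch neuron leakily accumulates
negative prediction errors, $S' = \sigma S + (1-\sigma)\delta^-$
($\sigma = 0.5$ RW, $0.8$ BP); when $S' \ge 0.5$ it resets to zero and a
new module is sampled from a softmax over $Q_i + Inh_i$, where the
just-abandoned module receives inhibition $-2$ that decays by 10% per
trial. Note the built-in discrimination: a *fresh* module ($Q = 0.5$)
cannot sustain $S \ge 0.5$ even under constant errors, so the model settles
and learns; a previously *trained* module visited under the wrong rule has
$V \approx 1$, its errors are large, and the model leaves within a couple
of trials.

### Learning rules

Learning acts once per trial on the trial maxima $X_i = \max_t x_i(t)$.
The full RW model uses the co-activation-gated rule
$\Delta W_{io} = \beta (T_o - X_o) X_i X_o$ — the extra $X_o$ makes silent
(gated-out) modules ineligible, at a small plasticity cost; the
no-synchrony RW model uses the classic delta rule
$\Delta W_{io} = \beta (T_o - X_o) X_i$. The BP models use one
backpropagation step per trial on $X$ with a cross-entropy readout (output
delta $T_o - X_o$) and logistic hidden derivatives. A contrastive-divergence
(restricted Boltzmann machine) variant is declared as an extension hook
(`learn_rbm_step()`) but not implemented.

## Tasks and metrics

`make_one_dim_task()` builds the 360-trial reversal task (6 blocks, rule
order A B C A B C; rules are the three cyclic feature-to-response maps;
exact per-block balance by construction). `make_multi_dim_task()` builds
the 3600-trial cued task: $N$ stimulus dimensions of 3 features plus a cue
dimension marking the relevant one ($N + 3N$ input nodes; combinations
balanced per block up to the remainder that $600 \bmod 81$ leaves).

Accuracy is binned into 120 bins (3 trials for RW, 30 for BP).
*Plasticity* is mean accuracy over the first 5 bins of blocks 1–3;
*stability* is the first 5 bins of blocks 4–6 minus the last 5 bins of
blocks 1–3 (zero = perfect retention). Replication intervals are
$\pm 2\,SD/\sqrt{N_{rep}}$.

## Electrophysiology-style analyses

* `zero_lag_synchrony()` — Pearson correlation of excitatory traces at lag
  zero (+1 synchronized, −1 anti-phase), averaged over node pairs by
  `trial_synchrony()`.
* `dpac()` — debiased phase–amplitude coupling,
  $|\frac1h\sum_t a_t(e^{i\varphi_t}-\bar\Phi)|$ with
  $\bar\Phi = \frac1h\sum_t e^{i\varphi_t}$; theta phase comes from the
  analytic signal (FFT Hilbert transform) of the pMFC trace and gamma
  amplitude from the mean $|E_i|$ over Processing nodes, per 500-sample
  trial.
* `morlet_tfr()` — complex Morlet convolution,
  $e^{i2\pi ft}e^{-t^2/2\sigma^2}$, $\sigma = 4/(2\pi f)$, 1–10 Hz in 10
  steps; power is the squared magnitude. Signals are reflect-padded by the
  3$\sigma$ half-support; wavelets are used exactly as defined above, without
  amplitude normalization, so power is comparable across time but not
  calibrated across frequencies. `feedback_power_contrast()` averages raw
  (not dB) ITI power after errors minus after correct feedback.

## Design decisions

Several choices were genuinely open; the rationale for each:

**Frequency calibration.** The continuous-time reading "frequency =
$C/2\pi$" suggests $C = 2\pi f\,\Delta t$. Under forward-Euler updates the
per-step rotation is $\arctan(C/(1 - Damp\cdot J))$, and with the strong
gamma damping the indicator is active on ~43% of steps, inflating the
realized frequency to ~42.5 Hz. `coupling_for_frequency()` therefore
root-finds $C$ so the realized phase-advance frequency equals the target
(gamma $C \approx 0.476$, theta $C \approx 0.0628$); zero-crossing
estimates then reproduce 40 Hz and 5 Hz.

**Zero-lag rate cascade.** Within a time step, each layer reads the
*current* step's upstream activation (input → modules → outputs). A
one-step-lagged synchronous update would let a single large burst that
flips the sign of the phase field pair a pre-flip upstream activation with
a post-flip open gate of an anti-phased module — activation spikes of
0.5–0.7 through a nominally closed gate. With the cascade, the anti-phase
gate product $G(E)G(-E) \le 0.0023$ bounds leakage at every step, which is
what makes the gating protection (and the "correlation at phase lag zero"
reading of synchrony) exact.

**Input drive.** Active layer-1 feature nodes are driven directly
($x = input \cdot G(E)$, magnitude 1). Applying the bias-5 logistic to
input nodes would cap them at $f(-4) \approx 0.018$ and nothing downstream
could learn at the default weight-initialization scale, which is clearly
calibrated (uniform on $[0, bias/2]$) so that hidden net input minus bias
is centred near zero when inputs are of order one.

**Cross-entropy BP readout.** With a squared-error output delta
$(T-X)X(1-X)$, the outputs — which initialize saturated at the default
uniform$(0, 2.5)$ weights — have near-zero derivative and both BP variants
stay at chance for the entire task; the value signal then never rises and
the controller never switches. The cross-entropy delta $T - X$ is the
equally standard choice and restores learning at the study's scale. The
gradient-check test verifies the analytic updates against centered finite
differences of the cross-entropy loss.

**Hidden-module size (BP).** 8 nodes per module: each module must
represent the 9 cue-by-feature conjunctions of the 3-D task. With 4 per
module the no-synchrony network plateaus near chance at $\beta = 0.2$.

**Initial conditions.** Triplets start at radius $r_{min}$ with
independent uniform-random phases, so any later alignment is attributable
to the bursts. The pMFC starts at radius 1 — a novel task demands maximal
control, and an engaged controller organizes the module phases during the
very first inter-trial interval; if it instead started at its floor, a
replication whose random weights happen to be immediately accurate would
never err, never burst, and never desynchronize anything, leaving all
modules to co-learn the first rule. Module values start at $Q = 0.5$
("reward unknown"); $Q = 0$ would be absorbing under the multiplicative
value update.

**Ordering within a trial.** Dynamics (ITI with feedback bursts, then
stimulation) → readout and reward → value update → switch accumulation →
possible module choice (new pointer takes effect next trial) → synaptic
learning; inhibition decays at every trial end.

**Readout.** Argmax over response nodes' $X$; for the RW models,
same-response nodes are pooled across modules by max, so a gated-out
module (near-zero $X$) cannot outvote the synchronized one. Ties break to
the lowest index.

## What the simulations do and do not show

The task generators emulate the study's balanced, blocked reversal
designs exactly; they do not emulate stimulus noise, graded rewards,
response times, or inter-subject variability, so passing tests show the
mechanism works under the model's own idealized conditions, not that it
fits any particular dataset. All gamma oscillators share one exact
frequency; desynchronization-by-drift is absent, and protection between
bursting episodes relies on frozen phase relations.

Problem sizes used by the test suite: the behavioral checks run the full
360-trial RW task with 5 replications; the BP stability comparison runs a
1200-trial 3-D task with 3 replications; sweeps in tests use reduced grids
and trial counts (the sweep functions expose full-scale grids).
At the 1200-trial scale the full BP model's value signal cannot rise to
switch-capable levels within a 200-trial block at $\alpha = 0.01$
(it moves at most ~0.0025 per trial from 0.5), so full and no-synchrony
BP become indistinguishable there and the stability-ordering check fails;
at 3600 trials the ordering is clear (full $\approx -0.05$ with switches
vs no-synchrony $\approx -0.39$). We report this limitation rather than
altering the default $\alpha$.

## A worked RW example

```{r rw-example, eval = FALSE}
task <- make_one_dim_task(seed = 1)
sim <- run_simulation(task, "rw-full", beta = 0.2, seed = 1)
glance(sim)
autoplot(sim)

sim_tr <- run_simulation(task, "rw-full", beta = 0.2, seed = 1,
                         record_traces = TRUE)
trial_synchrony(sim_tr)   # input-module phase alignment per trial
dpac_by_trial(sim_tr)     # theta-gamma coupling per trial
```

## Known limitations

* The RBM module variant is a declared hook only.
* The controller can discover *that* a switch is needed, not *which*
  module is right: re-entry into a learned rule involves trial-and-error
  over modules, so the first bins after re-entry carry most of the
  stability loss.
* Morlet power is unnormalized across frequencies (see above).
* No inter-areal conduction delays or frequency jitter between gamma
  oscillators.
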