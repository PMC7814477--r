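---
title: "Training biologically constrained rate RNNs on cognitive tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training biologically constrained rate RNNs on cognitive tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogrnn)
```

## The model

`cogrnn` trains continuous-time rate recurrent neural networks on
parameterised cognitive tasks. The network state $x \in \mathbb{R}^{N}$
evolves as

$$\tau\, dx = \left(-x + W_{rec}\, r + b_{rec} + W_{in}\, u\right) dt +
\sqrt{2\tau}\,\sigma_{rec}\, d\xi, \qquad r = f(x),$$

with readout $z = W_{out}\, r + b_{out}$. Here $u$ is the task input, $f$ is
the transfer function (rectified linear by default), $\tau$ is the intrinsic
unit timescale and $d\xi$ is a standard Gaussian noise process. We integrate
with first-order Euler–Maruyama at step $dt$: writing $\alpha = dt/\tau$,

$$x_{t+1} = (1-\alpha)\, x_t + \alpha \left(W_{rec} f(x_t) + b_{rec} +
W_{in} u_t\right) + \sqrt{2\alpha}\,\sigma_{rec}\, \xi_t,$$

where $\xi_t \sim \mathcal{N}(0, I)$. The per-step noise scale
$\sqrt{2\alpha}\,\sigma_{rec}$ is the discrete counterpart of the
$\sqrt{2\tau}\,\sigma_{rec}$ diffusion term; for a unit with zero weights it
gives the discrete Ornstein–Uhlenbeck stationary variance
$\sigma_{rec}^2\, 2\alpha / (1-(1-\alpha)^2) = \sigma_{rec}^2\, 2/(2-\alpha)$,
which the test suite verifies to 5% over $10^5$ steps. This keeps the noise
level approximately invariant to the choice of $dt$.

Defaults are $dt = 10$ ms, $\tau = 100$ ms ($\alpha = 0.1$), $N = 50$
recurrent units and $\sigma_{rec} = 0.05$ — sizes at which every experiment
in this vignette trains in minutes on one CPU core.

## Connectivity constraints by reparameterisation

Three kinds of biological structure can be imposed, all expressed through
masks that map raw trainable parameters to *effective* weights
(`effective_weights()`):

* **Forbidden connections.** Binary connectivity masks zero entries of
  $W_{in}$, $W_{rec}$, $W_{out}$; `make_structured_masks()` provides
  no-autapse (zero diagonal) and two-region (dense blocks, sparse
  Bernoulli($p$) inter-region) recipes.
* **Dale's principle.** With a proportion `dales_ratio` of excitatory units,
  $W_{rec}^{e\!f\!f} = C \odot |W_{rec}^{raw}| \odot S$ where column $j$ of
  $S$ carries the sign of presynaptic unit $j$; output weights inherit the
  presynaptic signs, input weights stay unsigned. The sign attaches to the
  *outgoing* weights of each unit, which is what "entirely excitatory or
  entirely inhibitory outputs" means mechanistically.
* **Fixed synapses.** Trainability masks zero the gradients of selected raw
  parameters (`dale_fixed_ei` freezes all connections between units of
  opposite sign).

Constraints are enforced by reparameterisation rather than by projecting
weights back after each update, so they hold *exactly* at every iteration
and the chain rule through $|\cdot|$ and the sign structure stays
well-defined (the subgradient of $|\cdot|$ and of ReLU at 0 is taken as 0).
The acceptance tests check, after 500 training iterations under each
constraint regime, that forbidden entries are exactly zero, Dale column
signs are pure, and fixed raw entries are bit-identical to their initial
values.

Recurrent weights are initialised from a Gaussian rescaled to spectral
radius 1.1 (`init_spectral_gaussian()`); a scaled-identity initialiser
(`init_alpha_identity()`) is also provided. Input/output weights are
Gaussian with standard deviation $1/\sqrt{\text{fan-in}}$, biases and the
initial state are zero, and the initial state is not trained.

## Tasks

A task defines, for every time $t$ within a trial, the input, target output
and output-mask vectors (`trial_function()`), plus a per-trial parameter
sampler (`generate_trial_params()`) and a correctness rule. The mask weights
the loss in time and output channel: all bundled tasks use mask 1 during
fixation (penalising premature responses), 0 during stimulus presentation
and delays (the network is unconstrained while evidence is presented or
held), and 1 during the response window. Fixation targets are 0 on every
channel. Correctness is the argmax of the time-averaged output over the
response window, ties broken toward the lowest channel.

* `perceptual_discrimination()` — two-alternative forced choice. During the
  stimulus the two input channels have means $(1\pm c)/2$ (rewarded channel
  high), each with additive Gaussian noise of standard deviation
  $0.1\sqrt{2\cdot 100\,\text{ms}/dt}$ by default, chosen so the integrated
  noise is invariant to $dt$. Default epochs are fixation 200 ms, stimulus
  1400 ms, response 400 ms (a 2 s trial). The stimulus length matters: an
  ideal observer averaging the 140 stimulus samples has discriminability
  $d' = c\sqrt{T_{stim}}/(\sigma_{in}\sqrt{2}) \approx 1.87$ at $c = 0.1$,
  i.e. a ceiling of $\approx 97\%$ — comfortably above the 90% criterion
  used in the curriculum experiment. With a 500 ms stimulus the ceiling is
  $\approx 87\%$ and a 90% criterion would be unattainable in expectation,
  so we treat the long-stimulus timing as the reference condition.
* `delayed_discrimination()` — frequency comparison across a delay on one
  input channel; amplitudes are normalised by the largest frequency so
  inputs stay $O(1)$. Report $f_1 > f_2$ on channel 1, else channel 2.
* `delayed_match_to_category()` — sample and test directions drawn from
  $n_{dir}$ discrete directions (one input channel each), partitioned into
  equal-width categories, $\text{cat}(k) = \lfloor k\, n_{cat}/n_{dir}
  \rfloor$. The response target is the *category of the test stimulus* (one
  output channel per category); the match/non-match label
  ($\text{cat}(sample) = \text{cat}(test)$) is recorded in the trial
  parameters. An alternative reading of the task is a dedicated
  match/non-match readout; we chose the category report because it
  generalises cleanly to more than two categories, and for two categories
  the two readouts carry the same information.

Per-trial input noise is drawn as a full $T \times n_{in}$ matrix from the
trial's own seed, and `trial_function()` reconstructs that matrix and slices
one row. This keeps the time-resolved definition a pure function of
$(t, \text{params})$ while letting `assemble_trial()` vectorise over time;
the test suite verifies the two paths agree bit-for-bit.

`vary_task()` rebuilds a task with some constructor arguments overridden,
recomputing the number of time steps, epoch boundaries and channel counts —
networks are constructed *after* the task, so changing, say, the number of
categories automatically resizes the readout.

## Losses, gradients, optimizers

The training loss is the mask-weighted mean squared error by default
($\sum M \odot (z-y)^2 / \sum M$; 0 when the mask is identically zero), with
binary cross-entropy on logistic-squashed outputs as an alternative
(probabilities clipped to $[10^{-7}, 1-10^{-7}]$; the gradient is taken as
0 where the clip is active so analytic and numeric derivatives agree).
Optional penalties: L1 and L2 norms of the three *effective* weight
matrices and an L2 penalty on the mean squared firing rate. No
regularisation is used by default.

Gradients are computed by explicit reverse-mode differentiation through the
unrolled recurrence (backpropagation through time), including the chain
through the constraint reparameterisation. Noise realisations are held
fixed during a gradient evaluation (pathwise gradients). The primary
correctness gate is agreement with central finite differences (step
$10^{-5}$) to relative error below $10^{-4}$ on randomized small networks
across all constraint regimes, both losses and all regularizers; in
practice agreement is $\sim 10^{-7}$ or better.

Optimizers: stochastic gradient descent, Adam ($\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$, bias-corrected) and RMSProp
(decay 0.9), with optional global-norm gradient clipping. Defaults: Adam,
learning rate $10^{-3}$, batch 64, loss averaged over the batch so the
learning rate is batch-size invariant. Loss and accuracy are recorded on
*freshly sampled* evaluation batches (never training batches) every
`eval_every = 10` iterations with `eval_batch = 128` trials.

Every random stream of a run — initialisation, per-iteration trial
sampling, dynamics noise, evaluation — is derived from one `master_seed`
through named sub-streams, so a whole train-then-simulate pipeline is
bit-reproducible and changing the evaluation cadence never perturbs the
training randomness.

## Curriculum learning

A `curriculum()` is an ordered list of task stages with per-stage
performance thresholds (default 0.9) and an optional custom metric
(task accuracy by default). At each evaluation checkpoint the metric is
computed on the *current* stage's task; when it reaches (≥) the stage
threshold, training switches to the next stage, and reaching the final
stage's threshold stops training. We read the advancement rule as
"reaches" (≥) rather than strictly exceeds — with accuracy measured on a
finite batch the distinction is immaterial, and a threshold of exactly the
criterion value then behaves as expected. Optimizer state is *not* reset at
stage transitions, matching a single continuous training run. If the
iteration budget runs out first, the fit is returned with
`curriculum_state$complete = FALSE` and a warning.

`curriculum_comparison()` runs the paired task-shaping experiment: each of
`n_pairs` networks is trained twice from identical initial weights — once
through a coherence-decreasing curriculum (default
$0.7 \to 0.5 \to 0.3 \to 0.1$, 90% threshold) and once directly at the
final coherence — and iterations until 90% accuracy at coherence 0.1 are
compared with a one-sided paired Wilcoxon signed-rank test. Two measurement
choices matter and are deliberate:

* The two arms of a pair share **only** the initialisation. Sharing the
  full random stream would evaluate both arms on identical criterion
  batches and synchronise near-threshold crossings, producing artifactual
  exact ties.
* For this experiment the criterion is checked every 5 iterations on 256
  fresh trials (the package-wide defaults stay 10 and 128). Runs last a few
  tens of iterations at this scale, so a 10-iteration grid would quantise
  the measurand at about 20% of its value, and 256 trials keep the binomial
  standard error of the threshold test near 2%.

**What desk scale does and does not reproduce.** At these sizes (40
recurrent units, batch 64, Adam) the fixed-coherence arm reaches criterion
in roughly 30–100 iterations: after temporal averaging over a 1400 ms
stimulus the batch gradient of the discriminative component has a very high
signal-to-noise ratio even at coherence 0.1 (roughly
$c\sqrt{BT_{stim}}/(\sigma_{in}\sqrt 2) \approx 15$ per batch), and Adam's
per-parameter normalisation makes the learning speed nearly independent of
the coherence scale. The curriculum arm is consistently faster at the
median (about 10 iterations), with few or no inversions across pairs, but a
10-iteration median advantage against comparable run-to-run variability
does not reach $p < 0.01$ in a 10-pair signed-rank test (observed
$p \approx 0.03$–0.08 across seeds). The *direction* and the paired design
of the task-shaping effect reproduce at desk scale; its significance level
requires a regime in which direct low-coherence learning is slow, which
these small, efficiently trained networks do not enter.

## Simulator and analyses

`rnn_simulate()` is a standalone forward simulator sharing one recurrence
with the training engine (equality to the training forward pass, given the
same noise, is itself a test), plus perturbations: unit lesions (rows and
columns of the effective recurrent matrix and the readout columns zeroed),
additive state pulses over a time window, and one-shot Gaussian weight
noise.

`psychometric()` measures the fraction of choice-1 responses at signed
coherences (negative values reward choice 2) and fits
$p(c) = \lambda + (1-2\lambda)\,/\,(1+e^{-k(c-c_0)})$ — a logistic with
lapse rate $\lambda \in [0, 0.5]$ — by bounded least squares from a small
grid of starts. The logistic-with-lapse form is a convention chosen here;
any monotone sigmoid with a lapse parameter would serve.

`trial_averaged_states()` averages unit trajectories over *correct* trials
per coherence (correctness from the task's own rule), and `state_pca()`
concatenates the per-coherence averages along time, centres each unit's
column (no variance scaling) and extracts principal axes by SVD.

## Numerical choices and edge cases

* All-zero output mask: the masked losses return 0 rather than dividing by
  zero.
* Divergence guard: the forward pass raises on the first non-finite state;
  training aborts with a diagnostic on a non-finite loss.
* ReLU and $|\cdot|$ subgradients at 0 are 0 — a consistent, testable
  convention that also keeps Dale-constrained weights at raw value 0 from
  drifting.
* Correctness ties (equal time-averaged outputs) resolve to the lowest
  channel index.
* Trial epochs must be integer multiples of $dt$; the trial length is
  $T = \sum_k \text{round}(d_k/dt)$ steps.
* Weight archives store arrays at 17 significant digits in JSON, which
  round-trips IEEE doubles exactly.

## Known limitations

* No LSTM or spiking architectures, no adaptation or short-term plasticity,
  no reinforcement learning, and no inter-trial dependencies — each trial
  is trained independently.
* The synthetic tasks emulate epoch structure, evidence noise and category
  partitions of the laboratory paradigms, not full psychophysical detail
  (no reaction-time variants, no stimulus dimensions beyond the declared
  channels). Networks that pass these tests demonstrate correct mechanics
  of the training framework, not quantitative fits to animal behaviour.
* Training is plain single-threaded R; it is comfortable at tens of units
  and a few hundred time steps, and not intended for large-scale sweeps.
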