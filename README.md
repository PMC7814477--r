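# cogrnn

Training biologically constrained rate recurrent neural networks (RNNs) on
cognitive tasks, in R.

Task-trained RNNs are a standard modelling tool in systems and cognitive
neuroscience: a recurrent network is optimised to perform a laboratory task
(perceptual decisions, working memory, categorisation), and its dynamics and
connectivity are then analysed as hypotheses about neural circuit
mechanisms. `cogrnn` provides the full workflow for this in plain R:
modular task definitions, continuous-time rate dynamics, constraint-aware
gradient training, closed-loop curriculum learning (task shaping), and
simulator-based perturbation and psychometric analyses.

## The model

The network state `x` of `N` recurrent units follows

    tau dx = (-x + W_rec r + b_rec + W_in u) dt + sqrt(2 tau) sigma_rec dXi,
    r = f(x),     z = W_out r + b_out

with transfer function `f` (ReLU by default), integrated by Euler–Maruyama
at step `dt` (`alpha = dt/tau`). Training minimises a mask-weighted loss
(mean squared error by default) by exact backpropagation through time, with
optional L1/L2 weight and rate penalties, under connectivity constraints
that hold exactly at every iteration because they are built into the
parameterisation:

- **forbidden connections** (e.g. no autapses, two sparsely connected
  regions) via binary connectivity masks,
- **Dale's principle** — each unit's outgoing weights share its sign — via
  `|W| * sign` reparameterisation,
- **fixed synapses** (e.g. all E–I connections frozen) via trainability
  masks.

Three tasks ship with the package: perceptual discrimination
(two-alternative forced choice with coherence-scaled evidence), delayed
discrimination (frequency comparison across a delay) and delayed
match-to-category. Tasks are plain parameterised objects; `vary_task()`
rebuilds any of them with different durations, coherences, categories, etc.

## Worked example

Train a 30-unit network on perceptual discrimination and measure its
psychometric curve:

```r
library(cogrnn)

task <- perceptual_discrimination(coherences = c(0.7, 0.5, 0.3))
fit <- cogrnn(task, spec = network_spec(2, 2, n_rec = 30),
              control = train_config(n_iterations = 300, master_seed = 7))
print(fit)
#> Trained rate RNN
#>   task: <pd_task>, network: 2 in -> 30 rec -> 2 out (relu)
#>   300 iteration(s) run (adam, lr 0.001, batch 64)
#>   final eval: loss 0.003415, accuracy 1.000

psychometric(fit, coherences = c(0.15, 0.4, 0.7),
             trials_per_coherence = 80, seed = 98)
#> Psychometric fit: slope k = 36.28, bias c0 = 0.0605, lapse = 0.000
#>  signed_coherence n_trials frac_choice1
#>             -0.70       80       0.0000
#>             -0.40       80       0.0000
#>             -0.15       80       0.0000
#>              0.15       80       0.9625
#>              0.40       80       1.0000
#>              0.70       80       1.0000
```

The final evaluation line is the loss and accuracy on a fresh batch of 128
trials. In the psychometric table, negative signed coherences reward
choice 2, so a perfect observer has `frac_choice1` 0 on the left and 1 on
the right; the fitted slope `k`, bias `c0` and lapse rate parameterise a
logistic psychometric function. `coef(fit)` returns the effective
(constrained) weights, `simulate(fit, ...)` runs the stochastic dynamics on
fresh trials (optionally under lesions or pulse perturbations via
`perturbation()`), and `plot(fit)` shows the training trace.

Curriculum learning trains through a list of task stages, advancing when
accuracy reaches a threshold:

```r
cur <- make_coherence_curriculum(c(0.7, 0.5, 0.3, 0.1), threshold = 0.9)
fit <- cogrnn(curriculum = cur, spec = network_spec(2, 2, n_rec = 50),
              control = train_config(n_iterations = 2000, master_seed = 1))
```

and `curriculum_comparison()` runs the paired experiment — curriculum
versus fixed-difficulty training from identical initial weights — returning
per-pair iterations-to-criterion and a one-sided paired sign-rank p-value.

See the vignette (`vignettes/training-constrained-rate-rnns.Rmd`) for the
model equations, constraint machinery, parameter defaults and the design
rationale behind the task and experiment settings.

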