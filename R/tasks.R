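# Bundled cognitive tasks. Each constructor records its own arguments so
# vary_task() can rebuild a modified copy with all dependent quantities
# (T, epoch boundaries, channel counts) recomputed.

# Per-trial input noise is a T x n_in matrix drawn from the trial's own seed;
# trial_function() reconstructs the identical matrix and slices one row, so
# the vectorised assemblers match the per-time-point definition exactly.
trial_input_noise <- function(task, params) {
  if (task$input_noise_sd == 0) return(matrix(0, task$T, task$n_in))
  with_seed(derive_seed(params$trial_seed, "input_noise"),
            matrix(stats::rnorm(task$T * task$n_in, sd = task$input_noise_sd),
                   task$T, task$n_in))
}

draw_trial_seed <- function() sample.int(2147483646L, 1L)

# default input-noise sd: 0.1 * sqrt(2/alpha) with the reference alpha
# dt/100 ms, which keeps the integrated noise level dt-invariant
default_input_noise <- function(dt) 0.1 * sqrt(2 * 100 / dt)

## ---- Perceptual discrimination (two-alternative forced choice) ----------

#' Perceptual discrimination task
#'
#' Two-alternative forced-choice motion-discrimination analog. During the
#' stimulus epoch the two input channels carry noisy evidence with means
#' \code{(1+c)/2} on the rewarded channel and \code{(1-c)/2} on the other,
#' where \code{c} is the trial's coherence; at coherence 0 the channels are
#' statistically indistinguishable. The network must report the stronger
#' channel during the response epoch. The output mask is 1 during fixation
#' (premature responses are penalised), 0 throughout the stimulus (the
#' network is unconstrained while evidence accumulates) and 1 during the
#' response window.
#'
#' @param coherences coherence levels in \code{[0,1]} sampled uniformly
#'   across trials.
#' @param input_noise_sd standard deviation of the additive Gaussian input
#'   noise; the default \code{0.1*sqrt(2*100/dt)} keeps the integrated noise
#'   dt-invariant for a 100 ms unit timescale.
#' @param dt time step, ms.
#' @param fixation,stimulus,response epoch durations, ms.
#' @param directions rewarded directions to sample from (subset of
#'   \code{0:1}); direction 0 rewards output channel 1.
#' @return A task object of class \code{c("pd_task", "cogtask")} with
#'   \code{n_in = 2}, \code{n_out = 2}.
#' @export
perceptual_discrimination <- function(coherences = c(0.7, 0.5, 0.3, 0.1),
                                      input_noise_sd = NULL, dt = 10,
                                      fixation = 200, stimulus = 1400,
                                      response = 400, directions = 0:1) {
  if (!length(coherences)) stop("'coherences' must be nonempty")
  if (any(coherences < 0 | coherences > 1)) stop("coherences must lie in [0,1]")
  if (!length(directions) || !all(directions %in% 0:1))
    stop("'directions' must be a nonempty subset of 0:1")
  input_noise_sd <- input_noise_sd %||% default_input_noise(dt)
  if (input_noise_sd < 0) stop("'input_noise_sd' must be >= 0")
  new_cogtask("pd_task", n_in = 2L, n_out = 2L, dt = dt,
              epochs = list(fixation = fixation, stimulus = stimulus,
                            response = response),
              extra = list(coherences = coherences, directions = directions,
                           input_noise_sd = input_noise_sd,
                           constructor = "perceptual_discrimination",
                           args = list(coherences = coherences,
                                       input_noise_sd = input_noise_sd, dt = dt,
                                       fixation = fixation, stimulus = stimulus,
                                       response = response, directions = directions)))
}

#' @export
generate_trial_params.pd_task <- function(task, trial_index = 1L) {
  list(coherence = task$coherences[sample.int(length(task$coherences), 1L)],
       direction = task$directions[sample.int(length(task$directions), 1L)],
       trial_index = trial_index, trial_seed = draw_trial_seed())
}

pd_stim_means <- function(params) {
  c0 <- (1 + params$coherence) / 2
  c1 <- (1 - params$coherence) / 2
  if (params$direction == 0) c(c0, c1) else c(c1, c0)
}

#' @export
trial_function.pd_task <- function(task, t, params) {
  k <- time_to_step(task, t)
  if (!params$direction %in% 0:1) stop("invalid direction (must be 0 or 1)")
  if (is.null(params$coherence)) stop("params lacks required key 'coherence'")
  input <- c(0, 0); target <- c(0, 0); mask <- c(1, 1)
  if (k %in% task$epoch_idx$stimulus) {
    input <- pd_stim_means(params) + trial_input_noise(task, params)[k, ]
    mask <- c(0, 0)
  } else if (k %in% task$epoch_idx$response) {
    target[params$direction + 1L] <- 1
  }
  list(input = input, target = target, mask = mask)
}

#' @export
assemble_trial.pd_task <- function(task, params) {
  Tn <- task$T; stim <- task$epoch_idx$stimulus; resp <- task$epoch_idx$response
  if (!params$direction %in% 0:1) stop("invalid direction (must be 0 or 1)")
  inputs <- matrix(0, Tn, 2L)
  inputs[stim, ] <- rep(pd_stim_means(params), each = length(stim)) +
    trial_input_noise(task, params)[stim, ]
  targets <- matrix(0, Tn, 2L)
  targets[resp, params$direction + 1L] <- 1
  mask <- matrix(1, Tn, 2L)
  mask[stim, ] <- 0
  structure(list(inputs = inputs, targets = targets, mask = mask, params = params),
            class = "trial_tensors")
}

#' @export
rewarded_channel.pd_task <- function(task, params) params$direction + 1L

## ---- Delayed discrimination (vibrotactile frequency comparison) ---------

#' Delayed discrimination task
#'
#' Frequency-comparison working-memory task on a single input channel: a
#' first stimulus of frequency \code{f1} is presented, followed by an
#' unstimulated delay, then a second stimulus of frequency \code{f2}; the
#' network must report during the response epoch whether \code{f1 > f2}
#' (output channel 1) or \code{f1 < f2} (channel 2). Stimulus amplitudes are
#' normalised by the largest frequency in the pair list so inputs stay O(1).
#'
#' @param freq_pairs two-column matrix of \code{(f1, f2)} frequency pairs
#'   (Hz), \code{f1 != f2} in every row, sampled uniformly across trials.
#'   The default spans 10-34 Hz with both orders of each 8 Hz-separated pair.
#' @param input_noise_sd additive Gaussian input-noise sd during the
#'   stimulus epochs (default 0).
#' @param dt time step, ms.
#' @param fixation,stimulus,delay,response epoch durations, ms
#'   (\code{stimulus} applies to both stimuli).
#' @return A task object of class \code{c("dd_task", "cogtask")} with
#'   \code{n_in = 1}, \code{n_out = 2}.
#' @export
delayed_discrimination <- function(freq_pairs = NULL, input_noise_sd = 0,
                                   dt = 10, fixation = 100, stimulus = 300,
                                   delay = 500, response = 200) {
  if (is.null(freq_pairs)) {
    base <- cbind(f1 = c(10, 14, 18, 22, 26), f2 = c(18, 22, 26, 30, 34))
    freq_pairs <- rbind(base, base[, 2:1])
  }
  freq_pairs <- as.matrix(freq_pairs)
  if (ncol(freq_pairs) != 2L || !nrow(freq_pairs))
    stop("'freq_pairs' must be a nonempty two-column matrix")
  if (any(freq_pairs <= 0)) stop("frequencies must be positive")
  if (any(freq_pairs[, 1] == freq_pairs[, 2]))
    stop("every pair must have f1 != f2")
  if (input_noise_sd < 0) stop("'input_noise_sd' must be >= 0")
  new_cogtask("dd_task", n_in = 1L, n_out = 2L, dt = dt,
              epochs = list(fixation = fixation, stimulus1 = stimulus,
                            delay = delay, stimulus2 = stimulus,
                            response = response),
              extra = list(freq_pairs = freq_pairs, f_max = max(freq_pairs),
                           input_noise_sd = input_noise_sd,
                           constructor = "delayed_discrimination",
                           args = list(freq_pairs = freq_pairs,
                                       input_noise_sd = input_noise_sd, dt = dt,
                                       fixation = fixation, stimulus = stimulus,
                                       delay = delay, response = response)))
}

#' @export
generate_trial_params.dd_task <- function(task, trial_index = 1L) {
  i <- sample.int(nrow(task$freq_pairs), 1L)
  list(f1 = task$freq_pairs[i, 1], f2 = task$freq_pairs[i, 2],
       trial_index = trial_index, trial_seed = draw_trial_seed())
}

#' @export
trial_function.dd_task <- function(task, t, params) {
  if (is.null(params$f1) || is.null(params$f2))
    stop("params lacks required keys 'f1'/'f2'")
  if (params$f1 == params$f2) stop("f1 and f2 must differ")
  k <- time_to_step(task, t)
  input <- 0; target <- c(0, 0); mask <- c(1, 1)
  if (k %in% task$epoch_idx$stimulus1) {
    input <- params$f1 / task$f_max + trial_input_noise(task, params)[k, 1]
    mask <- c(0, 0)
  } else if (k %in% task$epoch_idx$stimulus2) {
    input <- params$f2 / task$f_max + trial_input_noise(task, params)[k, 1]
    mask <- c(0, 0)
  } else if (k %in% task$epoch_idx$delay) {
    mask <- c(0, 0)
  } else if (k %in% task$epoch_idx$response) {
    target[if (params$f1 > params$f2) 1L else 2L] <- 1
  }
  list(input = input, target = target, mask = mask)
}

#' @export
rewarded_channel.dd_task <- function(task, params) {
  if (params$f1 > params$f2) 1L else 2L
}

## ---- Delayed match-to-category --------------------------------------------

#' Delayed match-to-category task
#'
#' A sample stimulus direction (one of \code{n_directions} discrete
#' directions, one input channel each) is shown, remembered across a delay,
#' and followed by a test direction. Directions are partitioned into
#' \code{n_categories} equal-width categories,
#' \code{category(k) = floor(k * n_categories / n_directions)}. The network
#' reports the category of the test stimulus during the response epoch (one
#' output channel per category); the match/non-match label
#' (\code{category(sample) == category(test)}) is recorded in the trial
#' parameters.
#'
#' @param n_directions number of discrete stimulus directions (input
#'   channels); must be divisible by \code{n_categories}.
#' @param n_categories number of categories (output channels).
#' @param input_noise_sd additive Gaussian input-noise sd during sample and
#'   test epochs (default 0).
#' @param dt time step, ms.
#' @param fixation,sample,delay,test,response epoch durations, ms.
#' @return A task object of class \code{c("dmc_task", "cogtask")}.
#' @export
delayed_match_to_category <- function(n_directions = 8L, n_categories = 2L,
                                      input_noise_sd = 0, dt = 10,
                                      fixation = 100, sample = 300,
                                      delay = 500, test = 300, response = 200) {
  n_directions <- as.integer(n_directions); n_categories <- as.integer(n_categories)
  if (n_categories < 2L) stop("'n_categories' must be at least 2")
  if (n_directions < n_categories || n_directions %% n_categories != 0L)
    stop("'n_directions' must be a positive multiple of 'n_categories'")
  if (input_noise_sd < 0) stop("'input_noise_sd' must be >= 0")
  new_cogtask("dmc_task", n_in = n_directions, n_out = n_categories, dt = dt,
              epochs = list(fixation = fixation, sample = sample, delay = delay,
                            test = test, response = response),
              extra = list(n_directions = n_directions, n_categories = n_categories,
                           input_noise_sd = input_noise_sd,
                           constructor = "delayed_match_to_category",
                           args = list(n_directions = n_directions,
                                       n_categories = n_categories,
                                       input_noise_sd = input_noise_sd, dt = dt,
                                       fixation = fixation, sample = sample,
                                       delay = delay, test = test,
                                       response = response)))
}

#' Category of a direction index under the equal-width partition
#'
#' @param k 0-based direction index (vectorised).
#' @param n_directions,n_categories partition parameters.
#' @return 0-based category index.
#' @export
dmc_category <- function(k, n_directions, n_categories) {
  floor(k * n_categories / n_directions)
}

#' @export
generate_trial_params.dmc_task <- function(task, trial_index = 1L) {
  sample_dir <- sample.int(task$n_directions, 1L) - 1L
  test_dir <- sample.int(task$n_directions, 1L) - 1L
  list(sample_dir = sample_dir, test_dir = test_dir,
       sample_category = dmc_category(sample_dir, task$n_directions, task$n_categories),
       test_category = dmc_category(test_dir, task$n_directions, task$n_categories),
       match = dmc_category(sample_dir, task$n_directions, task$n_categories) ==
         dmc_category(test_dir, task$n_directions, task$n_categories),
       trial_index = trial_index, trial_seed = draw_trial_seed())
}

#' @export
trial_function.dmc_task <- function(task, t, params) {
  if (is.null(params$sample_dir) || is.null(params$test_dir))
    stop("params lacks required keys 'sample_dir'/'test_dir'")
  if (params$sample_dir < 0 || params$sample_dir >= task$n_directions ||
      params$test_dir < 0 || params$test_dir >= task$n_directions)
    stop("direction index out of range")
  k <- time_to_step(task, t)
  input <- numeric(task$n_in); target <- numeric(task$n_out)
  mask <- rep(1, task$n_out)
  if (k %in% task$epoch_idx$sample) {
    input[params$sample_dir + 1L] <- 1
    input <- input + trial_input_noise(task, params)[k, ]
    mask[] <- 0
  } else if (k %in% task$epoch_idx$test) {
    input[params$test_dir + 1L] <- 1
    input <- input + trial_input_noise(task, params)[k, ]
    mask[] <- 0
  } else if (k %in% task$epoch_idx$delay) {
    mask[] <- 0
  } else if (k %in% task$epoch_idx$response) {
    target[params$test_category + 1L] <- 1
  }
  list(input = input, target = target, mask = mask)
}

#' @export
rewarded_channel.dmc_task <- function(task, params) params$test_category + 1L
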