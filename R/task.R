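#' Cognitive task objects
#'
#' A cognitive task is an S3 object describing how single trials of a
#' behavioural experiment are generated as time-resolved input, target-output
#' and output-mask series. Every task carries input/output widths
#' (\code{n_in}, \code{n_out}), the time step \code{dt} (ms), the trial
#' duration (ms) and the derived number of time steps
#' \code{T = round(trial_duration/dt)}, plus an epoch schedule (fixation,
#' stimulus, response, ...) stored as index ranges into \code{1..T}.
#'
#' Concrete tasks implement three generics: [generate_trial_params()],
#' [trial_function()] and (optionally) a per-trial correctness rule used by
#' [accuracy()]. Trials are assembled into arrays by [assemble_trial()] and
#' [assemble_batch()].
#'
#' @name cogtask
#' @seealso [perceptual_discrimination()], [delayed_discrimination()],
#'   [delayed_match_to_category()]
NULL

# Common scaffolding for task constructors: widths, timing and epochs.
# epochs: named list of durations in ms, in temporal order.
new_cogtask <- function(class, n_in, n_out, dt, epochs, extra = list()) {
  stopifnot_scalar(dt, "dt")
  for (nm in names(epochs)) stopifnot_scalar(epochs[[nm]], nm)
  durations <- unlist(epochs)
  trial_duration <- sum(durations)
  Tn <- as.integer(round(trial_duration / dt))
  steps <- as.integer(round(durations / dt))
  if (sum(steps) != Tn) stop("epoch durations must be multiples of dt")
  ends <- cumsum(steps)
  starts <- c(1L, head(ends, -1L) + 1L)
  idx <- Map(function(s, e) if (e >= s) s:e else integer(0), starts, ends)
  names(idx) <- names(epochs)
  structure(c(list(n_in = as.integer(n_in), n_out = as.integer(n_out), dt = dt,
                   trial_duration = trial_duration, T = Tn,
                   epoch_ms = epochs, epoch_idx = idx), extra),
            class = c(class, "cogtask"))
}

# time (ms) -> 1-based step index; t in [0, trial_duration)
time_to_step <- function(task, t) {
  if (t < 0 || t >= task$trial_duration)
    stop(sprintf("time %g ms outside trial bounds [0, %g)", t, task$trial_duration))
  as.integer(floor(t / task$dt)) + 1L
}

#' @export
print.cogtask <- function(x, ...) {
  cat(sprintf("<%s> %d input / %d output channels, dt = %g ms, T = %d steps (%g ms)\n",
              class(x)[1], x$n_in, x$n_out, x$dt, x$T, x$trial_duration))
  cat("  epochs:", paste(sprintf("%s %g ms", names(x$epoch_ms), unlist(x$epoch_ms)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Draw the parameters of one trial
#'
#' Samples a complete parameter set (stimulus condition, correct choice,
#' per-trial noise seed) for trial \code{trial_index} of a task, using the
#' current RNG stream. The returned list always carries a \code{trial_seed}
#' so the trial can be re-assembled bit-identically on its own.
#'
#' @param task a task object.
#' @param trial_index integer index of the trial within its batch.
#' @return A named list of trial parameters.
#' @export
generate_trial_params <- function(task, trial_index = 1L) {
  UseMethod("generate_trial_params")
}

#' Time-resolved trial function
#'
#' Evaluates a task at a single time point, returning the instantaneous
#' input, target output and output-mask vectors. This is the defining
#' function of a task; [assemble_trial()] is exactly this function looped
#' over \code{t = 0, dt, ..., (T-1) dt}.
#'
#' @param task a task object.
#' @param t time within the trial, ms, in \code{[0, trial_duration)}.
#' @param params a parameter list from [generate_trial_params()].
#' @return List with numeric vectors \code{input} (length \code{n_in}),
#'   \code{target} and \code{mask} (length \code{n_out}).
#' @export
trial_function <- function(task, t, params) UseMethod("trial_function")

#' Assemble one trial into time-by-channel arrays
#'
#' @param task a task object.
#' @param params a parameter list from [generate_trial_params()].
#' @return List of class \code{"trial_tensors"} with matrices \code{inputs}
#'   (\code{T x n_in}), \code{targets} and \code{mask} (\code{T x n_out}),
#'   and the originating \code{params}.
#' @export
assemble_trial <- function(task, params) UseMethod("assemble_trial")

#' @export
assemble_trial.default <- function(task, params) {
  Tn <- task$T
  inputs <- matrix(0, Tn, task$n_in)
  targets <- matrix(0, Tn, task$n_out)
  mask <- matrix(0, Tn, task$n_out)
  for (k in seq_len(Tn)) {
    v <- trial_function(task, (k - 1L) * task$dt, params)
    inputs[k, ] <- v$input; targets[k, ] <- v$target; mask[k, ] <- v$mask
  }
  structure(list(inputs = inputs, targets = targets, mask = mask, params = params),
            class = "trial_tensors")
}

#' Assemble a batch of independent trials
#'
#' Draws \code{B} trial parameter sets (each with its own sub-seed derived
#' from \code{seed}) and stacks the assembled trials into batch arrays.
#'
#' @param task a task object.
#' @param B number of trials, at least 1.
#' @param seed integer master seed for the batch; identical seeds give
#'   bit-identical batches.
#' @return List of class \code{"cogrnn_batch"} with arrays \code{inputs}
#'   (\code{B x T x n_in}), \code{targets}, \code{mask}
#'   (\code{B x T x n_out}) and \code{params} (list of length \code{B}).
#' @export
assemble_batch <- function(task, B, seed) {
  if (B < 1) stop("batch size must be at least 1")
  B <- as.integer(B)
  params <- with_seed(seed, lapply(seq_len(B), function(b) generate_trial_params(task, b)))
  Tn <- task$T
  inputs <- array(0, c(B, Tn, task$n_in))
  targets <- array(0, c(B, Tn, task$n_out))
  mask <- array(0, c(B, Tn, task$n_out))
  for (b in seq_len(B)) {
    tt <- assemble_trial(task, params[[b]])
    inputs[b, , ] <- tt$inputs; targets[b, , ] <- tt$targets; mask[b, , ] <- tt$mask
  }
  structure(list(inputs = inputs, targets = targets, mask = mask,
                 params = params, task_class = class(task)[1]),
            class = "cogrnn_batch")
}

#' Fraction of correct trials
#'
#' Applies the task's per-trial correctness rule to network outputs and
#' returns the ratio of correct trials to total trials. For all bundled
#' tasks the rule is: the chosen channel is the argmax of the time-averaged
#' output over the response window (ties broken toward the lowest index),
#' and the trial is correct when it equals the rewarded channel.
#'
#' @param task a task object.
#' @param outputs \code{B x T x n_out} array of network outputs.
#' @param batch the batch the outputs were computed on.
#' @return Accuracy in \code{[0, 1]}.
#' @export
accuracy <- function(task, outputs, batch) UseMethod("accuracy")

#' @export
accuracy.cogtask <- function(task, outputs, batch) {
  if (is.matrix(outputs)) outputs <- array(outputs, c(1L, dim(outputs)))
  B <- dim(outputs)[1]
  stopifnot(B == length(batch$params), dim(outputs)[2] == task$T,
            dim(outputs)[3] == task$n_out)
  correct <- vapply(seq_len(B), function(b) {
    trial_correct(task, matrix(outputs[b, , ], task$T, task$n_out), batch$params[[b]])
  }, logical(1))
  mean(correct)
}

# Per-trial correctness rule; tasks must provide the rewarded channel.
trial_correct <- function(task, output, params) UseMethod("trial_correct")

#' @noRd
#' @export
trial_correct.cogtask <- function(task, output, params) {
  resp <- task$epoch_idx$response
  if (is.null(resp) || !length(resp))
    stop(sprintf("task '%s' defines no response window and no accuracy rule", class(task)[1]))
  choice <- response_choice(output, resp)
  choice == rewarded_channel(task, params)
}

# argmax of time-averaged output over the response window; ties -> lowest index
response_choice <- function(output, resp_idx) {
  m <- colMeans(output[resp_idx, , drop = FALSE])
  which.max(m)
}

rewarded_channel <- function(task, params) UseMethod("rewarded_channel")

#' Derive a modified copy of a task
#'
#' Rebuilds a task with some of its constructor arguments overridden,
#' recomputing every dependent quantity (number of time steps, epoch
#' boundaries, channel counts). The original task is unchanged.
#'
#' @param task a task object.
#' @param ... named overrides of the task's constructor arguments.
#' @return A new task object of the same class.
#' @export
vary_task <- function(task, ...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("overrides must be named")
  args <- task$args
  unknown <- setdiff(names(over), names(args))
  if (length(unknown))
    stop(sprintf("unknown task parameter(s): %s", paste(unknown, collapse = ", ")))
  args[names(over)] <- over
  do.call(task$constructor, args)
}
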