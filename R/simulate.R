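#' Perturbation specification for the standalone simulator
#'
#' @param kind \describe{
#'   \item{\code{"lesion_units"}}{silence units: their rows and columns of
#'     the effective recurrent matrix and their readout columns are zeroed.}
#'   \item{\code{"state_pulse"}}{add \code{magnitude} to the targeted units'
#'     state at every step with onset time in
#'     \code{[onset, onset + duration)} ms.}
#'   \item{\code{"weight_noise"}}{add i.i.d. Gaussian noise with sd
#'     \code{magnitude} to the effective recurrent matrix once before
#'     simulation.}}
#' @param targets unit indices (1-based) the perturbation applies to;
#'   ignored for \code{weight_noise}.
#' @param magnitude pulse height or noise sd.
#' @param onset,duration pulse timing, ms (for \code{state_pulse}).
#' @return An object of class \code{"perturbation"}.
#' @export
perturbation <- function(kind = c("lesion_units", "state_pulse", "weight_noise"),
                         targets = integer(0), magnitude = 0,
                         onset = 0, duration = 0) {
  kind <- match.arg(kind)
  if (duration < 0) stop("'duration' must be >= 0")
  structure(list(kind = kind, targets = as.integer(targets),
                 magnitude = magnitude, onset = onset, duration = duration),
            class = "perturbation")
}

apply_weight_perturbation <- function(eff, pert, n_rec) {
  if (is.null(pert)) return(eff)
  if (length(pert$targets) && any(pert$targets < 1 | pert$targets > n_rec))
    stop("perturbation targets outside 1..n_rec")
  if (pert$kind == "lesion_units") {
    eff$W_rec[pert$targets, ] <- 0
    eff$W_rec[, pert$targets] <- 0
    eff$W_out[, pert$targets] <- 0
  } else if (pert$kind == "weight_noise") {
    eff$W_rec <- eff$W_rec +
      matrix(stats::rnorm(n_rec * n_rec, sd = pert$magnitude), n_rec, n_rec)
  }
  eff
}

pulse_matrix <- function(pert, spec, Tn) {
  if (is.null(pert) || pert$kind != "state_pulse") return(NULL)
  pulse <- matrix(0, spec$n_rec, Tn)
  steps <- which((seq_len(Tn) - 1L) * spec$dt >= pert$onset &
                   (seq_len(Tn) - 1L) * spec$dt < pert$onset + pert$duration)
  pulse[pert$targets, steps] <- pert$magnitude
  pulse
}

#' Standalone forward simulator
#'
#' Simulates the network on given trial inputs, decoupled from the training
#' machinery, optionally under a [perturbation()]. Without a perturbation
#' and given the same noise draws this reproduces [rnn_forward()] exactly
#' (the two share one recurrence), which makes lesion and perturbation
#' studies directly comparable to the trained behaviour.
#'
#' @param weights,masks raw weights and masks (e.g. from a fit or
#'   [load_weights()]).
#' @param spec a [network_spec()].
#' @param inputs \code{T x n_in} matrix or \code{B x T x n_in} array.
#' @param noise optional \code{B x T x n_rec} standard-normal array; drawn
#'   from the current RNG stream when \code{NULL} and \code{sigma_rec > 0}.
#' @param pert optional [perturbation()].
#' @return List with \code{states}, \code{rates} and \code{outputs} arrays.
#' @export
rnn_simulate <- function(weights, masks, spec, inputs, noise = NULL, pert = NULL) {
  if (is.matrix(inputs)) inputs <- array(inputs, c(1L, dim(inputs)))
  if (dim(inputs)[3] != spec$n_in)
    stop(sprintf("inputs have %d channels but the spec declares n_in = %d",
                 dim(inputs)[3], spec$n_in))
  check_shapes(weights, masks, spec)
  B <- dim(inputs)[1]; Tn <- dim(inputs)[2]
  eff <- effective_weights(weights, masks)
  eff <- apply_weight_perturbation(eff, pert, spec$n_rec)
  if (is.null(noise) && spec$sigma_rec > 0)
    noise <- array(stats::rnorm(B * Tn * spec$n_rec), c(B, Tn, spec$n_rec))
  Np <- if (is.null(noise)) NULL else aperm(noise, c(3, 1, 2))
  fc <- forward_core(aperm(inputs, c(3, 1, 2)), eff, spec, noise = Np,
                     x0 = weights$x0, pulse = pulse_matrix(pert, spec, Tn))
  list(states = aperm(fc$X, c(2, 3, 1)), rates = aperm(fc$R, c(2, 3, 1)),
       outputs = aperm(fc$Z, c(2, 3, 1)))
}

#' Simulate a fitted network on fresh trials
#'
#' Draws \code{nsim} fresh trials from the task and runs the stochastic
#' dynamics, optionally under a [perturbation()].
#'
#' @param object a fitted [cogrnn()] object.
#' @param nsim number of trials.
#' @param seed integer seed (trial sampling and dynamics noise).
#' @param task task to draw trials from (default: the training task).
#' @param pert optional [perturbation()].
#' @param ... unused.
#' @return List with \code{states}, \code{rates}, \code{outputs} and the
#'   sampled \code{batch}.
#' @export
simulate.cogrnn <- function(object, nsim = 1, seed = 1L, task = NULL,
                            pert = NULL, ...) {
  task <- task %||% object$task
  batch <- assemble_batch(task, nsim, seed = derive_seed(seed, "trials"))
  noise <- draw_dyn_noise(object$spec, nsim, task$T, derive_seed(seed, "dyn"))
  sim <- rnn_simulate(object$weights, object$masks, object$spec, batch$inputs,
                      noise = noise, pert = pert)
  c(sim, list(batch = batch))
}
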