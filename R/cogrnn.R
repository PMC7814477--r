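#' Train a biologically constrained rate RNN on a cognitive task
#'
#' The central fitting function of the package. Runs gradient-based training
#' of a continuous-time rate recurrent network on a cognitive task (or a
#' curriculum of tasks): at each iteration a fresh batch of trials is
#' sampled, the stochastic dynamics are unrolled, the masked loss and its
#' gradients (backpropagation through time) are computed, trainability
#' constraints are applied, and the optimizer updates the raw parameters.
#' Connectivity constraints (forbidden connections, Dale's principle, fixed
#' synapses) hold exactly at every iteration because they are enforced by
#' reparameterisation, not projection.
#'
#' Loss and task accuracy are recorded on freshly sampled evaluation batches
#' every \code{eval_every} iterations. With a curriculum, the accuracy of
#' the current stage governs advancement, and reaching the final stage's
#' threshold stops training early. The whole run is reproducible from
#' \code{control$master_seed}, which fans out into independent sub-streams
#' for initialisation, trial sampling, dynamics noise and evaluation.
#'
#' @param task a task object; may be omitted when \code{curriculum} is given
#'   (the first stage is then used to size the network).
#' @param spec a [network_spec()]; defaults to a 50-unit network sized to
#'   the task's channel counts.
#' @param loss a [loss_spec()].
#' @param control a [train_config()].
#' @param curriculum optional [curriculum()] governing task shaping.
#' @param init optional list \code{(weights, masks)} as returned by
#'   [default_initializer()]; drawn from the run's init stream when missing.
#'   Passing an explicit \code{init} lets several training arms start from
#'   identical weights.
#' @param masks optional mask set overriding \code{init$masks} (e.g. from
#'   [make_structured_masks()]).
#' @return An object of class \code{"cogrnn"}: a list with the final raw
#'   \code{weights}, the \code{masks}, the network \code{spec}, the
#'   \code{task}, \code{loss}, \code{control} and \code{curriculum} used,
#'   the \code{curriculum_state}, and \code{trace}, a data frame with one
#'   row per evaluation (\code{iteration}, \code{loss}, \code{accuracy},
#'   \code{stage}).
#' @examples
#' task <- perceptual_discrimination(coherences = 0.5)
#' fit <- cogrnn(task, spec = network_spec(2, 2, n_rec = 20),
#'               control = train_config(n_iterations = 30, master_seed = 1))
#' tail(fit$trace, 2)
#' @export
cogrnn <- function(task = NULL, spec = NULL, loss = loss_spec(),
                   control = train_config(), curriculum = NULL,
                   init = NULL, masks = NULL) {
  if (is.null(task)) {
    if (is.null(curriculum)) stop("either 'task' or 'curriculum' must be given")
    task <- curriculum$stages[[1]]
  }
  stopifnot(inherits(task, "cogtask"))
  if (is.null(spec))
    spec <- network_spec(n_in = task$n_in, n_out = task$n_out)
  if (spec$n_in != task$n_in || spec$n_out != task$n_out)
    stop(sprintf("network spec is %d in / %d out but the task needs %d / %d",
                 spec$n_in, spec$n_out, task$n_in, task$n_out))
  if (!is.null(curriculum))
    for (st in curriculum$stages)
      if (st$n_in != spec$n_in || st$n_out != spec$n_out || st$T != task$T)
        stop("all curriculum stages must share channel counts and trial length")
  seed0 <- control$master_seed
  if (is.null(init))
    init <- with_seed(derive_seed(seed0, "init"), default_initializer(spec))
  weights <- init$weights
  masks <- masks %||% init$masks
  check_shapes(weights, masks, spec)

  trainable <- c("W_in_raw", "W_rec_raw", "W_out_raw", "b_rec", "b_out")
  opt_state <- optimizer_init(control, weights[trainable])
  cur_state <- if (is.null(curriculum)) NULL else curriculum_state()
  metric_fn <- if (is.null(curriculum)) NULL else curriculum$metric %||% default_metric

  n_ev <- if (control$n_iterations > 0) control$n_iterations %/% control$eval_every else 0
  tr_it <- integer(0); tr_loss <- numeric(0); tr_acc <- numeric(0); tr_stage <- integer(0)
  stopped_at <- NA_integer_

  it <- 0L
  while (it < control$n_iterations) {
    it <- it + 1L
    cur_task <- if (is.null(curriculum)) task else curriculum$stages[[cur_state$stage_index]]
    batch <- assemble_batch(cur_task, control$batch_size,
                            seed = derive_seed(seed0, "batch", it))
    noise <- draw_dyn_noise(spec, control$batch_size, cur_task$T,
                            derive_seed(seed0, "noise", it))
    fb <- compute_gradients(weights, masks, batch, spec, loss, noise = noise)
    if (!is.finite(fb$loss))
      stop(sprintf("training aborted: non-finite loss at iteration %d", it))
    grads <- apply_constraints_to_grads(fb$grads, masks)
    upd <- optimizer_step(opt_state, weights[trainable], grads, control)
    opt_state <- upd$state
    weights[trainable] <- upd$params

    if (it %% control$eval_every == 0L) {
      ev <- evaluate_once(weights, masks, spec, cur_task, loss,
                          control$eval_batch, derive_seed(seed0, "eval", it))
      tr_it <- c(tr_it, it); tr_loss <- c(tr_loss, ev$loss)
      tr_acc <- c(tr_acc, ev$accuracy)
      tr_stage <- c(tr_stage, if (is.null(curriculum)) 1L else cur_state$stage_index)
      if (!is.null(curriculum) && !cur_state$complete) {
        mv <- if (is.null(curriculum$metric)) ev$accuracy else
          metric_fn(ev$outputs, ev$batch, cur_task)
        if (should_advance(cur_state, mv, curriculum)) {
          cur_state <- advance(cur_state, curriculum, it)
          if (cur_state$complete) { stopped_at <- it; break }
        }
      }
    }
  }
  if (!is.null(curriculum) && !cur_state$complete)
    warning("iteration budget exhausted before the curriculum completed")

  structure(list(weights = weights, masks = masks, spec = spec, task = task,
                 loss = loss, control = control, curriculum = curriculum,
                 curriculum_state = cur_state,
                 trace = data.frame(iteration = tr_it, loss = tr_loss,
                                    accuracy = tr_acc, stage = tr_stage),
                 stopped_at = stopped_at, n_iterations_run = it,
                 call = match.call()),
            class = "cogrnn")
}

draw_dyn_noise <- function(spec, B, Tn, seed) {
  if (spec$sigma_rec == 0) return(NULL)
  with_seed(seed, array(stats::rnorm(B * Tn * spec$n_rec), c(B, Tn, spec$n_rec)))
}

check_shapes <- function(weights, masks, spec) {
  with(spec, {
    stopifnot(all(dim(weights$W_in_raw) == c(n_rec, n_in)),
              all(dim(weights$W_rec_raw) == c(n_rec, n_rec)),
              all(dim(weights$W_out_raw) == c(n_out, n_rec)),
              length(weights$b_rec) == n_rec, length(weights$b_out) == n_out,
              length(weights$x0) == n_rec,
              all(dim(masks$conn_rec) == c(n_rec, n_rec)),
              all(dim(masks$conn_in) == c(n_rec, n_in)),
              all(dim(masks$conn_out) == c(n_out, n_rec)),
              is.null(masks$dale_signs) || length(masks$dale_signs) == n_rec)
  })
  invisible(TRUE)
}

#' Evaluate loss and accuracy on fresh trials
#'
#' Samples a fresh batch from the task, runs the stochastic forward pass and
#' returns the total loss and task accuracy.
#'
#' @param weights,masks,spec network parameters (or pass a fitted
#'   [cogrnn()] object as \code{weights} with \code{masks} and \code{spec}
#'   missing).
#' @param task a task object.
#' @param loss a [loss_spec()].
#' @param n_trials evaluation batch size.
#' @param seed integer seed for trial sampling and dynamics noise.
#' @return List with \code{loss}, \code{accuracy}, \code{outputs} and the
#'   \code{batch}.
#' @export
evaluate <- function(weights, masks = NULL, spec = NULL, task = NULL,
                     loss = loss_spec(), n_trials = 500L, seed = 1L) {
  if (inherits(weights, "cogrnn")) {
    fit <- weights
    task <- task %||% fit$task
    evaluate_once(fit$weights, fit$masks, fit$spec, task, loss, n_trials, seed)
  } else {
    evaluate_once(weights, masks, spec, task, loss, n_trials, seed)
  }
}

evaluate_once <- function(weights, masks, spec, task, loss, n_trials, seed) {
  batch <- assemble_batch(task, n_trials, seed = derive_seed(seed, "trials"))
  noise <- draw_dyn_noise(spec, n_trials, task$T, derive_seed(seed, "dyn"))
  fwd <- rnn_forward(batch$inputs, weights, masks, spec, noise = noise)
  l <- total_loss(fwd$outputs, batch$targets, batch$mask, weights, masks,
                  fwd$rates, loss)
  list(loss = l, accuracy = accuracy(task, fwd$outputs, batch),
       outputs = fwd$outputs, batch = batch)
}
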