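#' @export
print.cogrnn <- function(x, ...) {
  cat("Trained rate RNN\n")
  cat(sprintf("  task: <%s>, network: %d in -> %d rec -> %d out (%s%s)\n",
              class(x$task)[1], x$spec$n_in, x$spec$n_rec, x$spec$n_out,
              x$spec$transfer,
              if (is.null(x$spec$dales_ratio)) "" else
                sprintf(", Dale %.0f%% E", 100 * x$spec$dales_ratio)))
  cat(sprintf("  %d iteration(s) run (%s, lr %g, batch %d)\n",
              x$n_iterations_run, x$control$optimizer,
              x$control$learning_rate, x$control$batch_size))
  if (nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final eval: loss %.4g, accuracy %.3f\n", last$loss, last$accuracy))
  }
  if (!is.null(x$curriculum_state)) {
    cs <- x$curriculum_state
    cat(sprintf("  curriculum: stage %d/%d, %s\n", cs$stage_index,
                length(x$curriculum$stages),
                if (cs$complete) sprintf("completed at iteration %d", x$stopped_at)
                else "incomplete"))
  }
  invisible(x)
}

#' @export
summary.cogrnn <- function(object, ...) {
  out <- list(fit = object, trace = object$trace,
              advancements = object$curriculum_state$advancement_iterations,
              eff = effective_weights(object$weights, object$masks))
  class(out) <- "summary.cogrnn"
  out
}

#' @export
print.summary.cogrnn <- function(x, ...) {
  print(x$fit)
  eff <- x$eff
  cat(sprintf("  |W_rec| spectral radius: %.3f; %d/%d recurrent connections nonzero\n",
              max(Mod(eigen(eff$W_rec, only.values = TRUE)$values)),
              sum(eff$W_rec != 0), length(eff$W_rec)))
  if (length(x$advancements))
    cat("  stage advancements at iterations:",
        paste(x$advancements, collapse = ", "), "\n")
  if (nrow(x$trace) > 1) {
    cat("  trace (first/last evaluations):\n")
    print(utils::head(x$trace, 2), row.names = FALSE)
    print(utils::tail(x$trace, 2), row.names = FALSE)
  }
  invisible(x)
}

#' Effective weights of a fitted network
#'
#' Returns the constrained weights the dynamics actually use (forbidden
#' connections zeroed, Dale signs applied), not the raw parameters.
#'
#' @param object a fitted [cogrnn()] object.
#' @param ... unused.
#' @export
coef.cogrnn <- function(object, ...) {
  effective_weights(object$weights, object$masks)
}

#' Deterministic network responses on fresh trials
#'
#' Runs the fitted network forward with the dynamics noise switched off
#' (\code{sigma_rec = 0}); use [simulate.cogrnn()] for stochastic
#' trajectories.
#'
#' @param object a fitted [cogrnn()] object.
#' @param task task to draw trials from (default: the training task).
#' @param n_trials number of fresh trials.
#' @param seed seed for trial sampling.
#' @param type \code{"outputs"}, \code{"rates"} or \code{"states"}.
#' @param ... unused.
#' @return The requested \code{B x T x .} array, with the batch attached as
#'   attribute \code{"batch"}.
#' @export
predict.cogrnn <- function(object, task = NULL, n_trials = 1L, seed = 1L,
                           type = c("outputs", "rates", "states"), ...) {
  type <- match.arg(type)
  task <- task %||% object$task
  batch <- assemble_batch(task, n_trials, seed = seed)
  spec0 <- object$spec; spec0$sigma_rec <- 0
  fwd <- rnn_forward(batch$inputs, object$weights, object$masks, spec0)
  structure(fwd[[type]], batch = batch)
}

#' Masked residuals on fresh trials
#'
#' Output-minus-target differences on a freshly sampled batch, multiplied by
#' the task's output mask, so entries outside the penalised epochs are 0.
#'
#' @param object a fitted [cogrnn()] object.
#' @param n_trials number of fresh trials.
#' @param seed seed for trial sampling.
#' @param ... unused.
#' @export
residuals.cogrnn <- function(object, n_trials = 32L, seed = 1L, ...) {
  outputs <- predict(object, n_trials = n_trials, seed = seed)
  batch <- attr(outputs, "batch")
  (unclass(outputs) - batch$targets) * batch$mask
}

#' Training trace plot
#'
#' Loss and evaluation accuracy against training iteration; curriculum stage
#' advancements are marked with vertical dashed lines.
#'
#' @param x a fitted [cogrnn()] object.
#' @param ... passed to \code{plot}.
#' @export
plot.cogrnn <- function(x, ...) {
  tr <- x$trace
  if (!nrow(tr)) stop("no evaluations recorded (n_iterations < eval_every)")
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$iteration, tr$loss, type = "l", xlab = "iteration",
                 ylab = "loss", ...)
  adv <- x$curriculum_state$advancement_iterations
  if (length(adv)) graphics::abline(v = adv, lty = 2, col = "grey50")
  graphics::plot(tr$iteration, tr$accuracy, type = "l", ylim = c(0, 1),
                 xlab = "iteration", ylab = "accuracy", ...)
  if (length(adv)) graphics::abline(v = adv, lty = 2, col = "grey50")
  invisible(x)
}
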