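#' Training configuration
#'
#' @param optimizer \code{"adam"} (default), \code{"sgd"} or
#'   \code{"rmsprop"}.
#' @param learning_rate step size.
#' @param n_iterations number of weight updates.
#' @param batch_size trials per training batch.
#' @param eval_every iterations between performance recordings (loss and
#'   accuracy on a fresh evaluation batch).
#' @param eval_batch trials per evaluation batch.
#' @param grad_clip_norm optional global-norm gradient clipping threshold.
#' @param master_seed integer seed from which every random stream of the run
#'   (initialisation, trial sampling, dynamics noise, evaluation) is derived.
#' @return An object of class \code{"train_config"}.
#' @export
train_config <- function(optimizer = c("adam", "sgd", "rmsprop"),
                         learning_rate = 0.001, n_iterations = 500L,
                         batch_size = 64L, eval_every = 10L, eval_batch = 128L,
                         grad_clip_norm = NULL, master_seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot_scalar(learning_rate, "learning_rate")
  if (n_iterations < 0) stop("'n_iterations' must be >= 0")
  for (nm in c("batch_size", "eval_every", "eval_batch"))
    if (get(nm) < 1) stop(sprintf("'%s' must be >= 1", nm))
  if (!is.null(grad_clip_norm)) stopifnot_scalar(grad_clip_norm, "grad_clip_norm")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 n_iterations = as.integer(n_iterations),
                 batch_size = as.integer(batch_size),
                 eval_every = as.integer(eval_every),
                 eval_batch = as.integer(eval_batch),
                 grad_clip_norm = grad_clip_norm,
                 master_seed = as.integer(master_seed)),
            class = "train_config")
}

#' Initialise optimizer state
#'
#' @param cfg a [train_config()].
#' @param params named list of parameter arrays.
#' @return Opaque state list consumed by [optimizer_step()].
#' @export
optimizer_init <- function(cfg, params) {
  zeros <- lapply(params, function(p) p * 0)
  switch(cfg$optimizer,
         sgd = list(t = 0L),
         adam = list(t = 0L, m = zeros, v = zeros),
         rmsprop = list(t = 0L, v = zeros))
}

clip_global_norm <- function(grads, max_norm) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (gn > max_norm) grads <- lapply(grads, function(g) g * (max_norm / gn))
  grads
}

#' One optimizer update
#'
#' Applies stochastic gradient descent, Adam (beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8, with bias correction) or RMSProp (decay 0.9, eps = 1e-8) to a
#' named list of parameters. When \code{grad_clip_norm} is set, gradients
#' are first rescaled so their global L2 norm does not exceed it.
#'
#' @param state optimizer state from [optimizer_init()].
#' @param params named list of parameter arrays.
#' @param grads matching named list of gradients.
#' @param cfg a [train_config()].
#' @return List with updated \code{state} and \code{params}.
#' @export
optimizer_step <- function(state, params, grads, cfg) {
  if (!is.null(cfg$grad_clip_norm))
    grads <- clip_global_norm(grads, cfg$grad_clip_norm)
  lr <- cfg$learning_rate
  state$t <- state$t + 1L
  if (cfg$optimizer == "sgd") {
    for (k in names(grads)) params[[k]] <- params[[k]] - lr * grads[[k]]
  } else if (cfg$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (k in names(grads)) {
      state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grads[[k]]
      state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * grads[[k]]^2
      mhat <- state$m[[k]] / (1 - b1^state$t)
      vhat <- state$v[[k]] / (1 - b2^state$t)
      params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
  } else { # rmsprop
    rho <- 0.9; eps <- 1e-8
    for (k in names(grads)) {
      state$v[[k]] <- rho * state$v[[k]] + (1 - rho) * grads[[k]]^2
      params[[k]] <- params[[k]] - lr * grads[[k]] / (sqrt(state$v[[k]]) + eps)
    }
  }
  list(state = state, params = params)
}
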