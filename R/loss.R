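#' Loss specification
#'
#' Selects the base loss and regularisation strengths applied during
#' training. By default the loss is the masked mean squared error and no
#' regularisation is used.
#'
#' @param loss \code{"mse"} (masked mean squared error, default) or
#'   \code{"bce"} (masked binary cross-entropy on logistic-squashed outputs).
#' @param lambda_l1_w L1 penalty coefficient on the effective synaptic
#'   weights (input, recurrent and output matrices).
#' @param lambda_l2_w L2 penalty coefficient on the effective synaptic
#'   weights.
#' @param lambda_l2_rate L2 penalty coefficient on the post-nonlinearity
#'   firing rates \code{r}, averaged over batch, time and units.
#' @return An object of class \code{"loss_spec"}.
#' @export
loss_spec <- function(loss = c("mse", "bce"), lambda_l1_w = 0,
                      lambda_l2_w = 0, lambda_l2_rate = 0) {
  loss <- match.arg(loss)
  if (lambda_l1_w < 0 || lambda_l2_w < 0 || lambda_l2_rate < 0)
    stop("regularisation coefficients must be >= 0")
  structure(list(loss = loss, lambda_l1_w = lambda_l1_w,
                 lambda_l2_w = lambda_l2_w, lambda_l2_rate = lambda_l2_rate),
            class = "loss_spec")
}

#' Masked mean squared error
#'
#' \code{sum(mask * (outputs - targets)^2) / sum(mask)}; returns 0 when the
#' mask is identically zero. The mask restricts the penalty to task-specified
#' epochs (e.g., it is zero during the stimulus period, leaving the network
#' unconstrained there).
#'
#' @param outputs,targets,mask arrays of identical shape.
#' @export
masked_mse <- function(outputs, targets, mask) {
  stopifnot(all(dim(outputs) == dim(targets)), all(dim(outputs) == dim(mask)))
  ms <- sum(mask)
  if (ms == 0) return(0)
  sum(mask * (outputs - targets)^2) / ms
}

BCE_CLIP <- 1e-7

#' Masked binary cross-entropy
#'
#' Squashes the raw outputs through the logistic function, clips the
#' probabilities to \code{[1e-7, 1 - 1e-7]}, and returns the mask-weighted
#' mean of \code{-(y log p + (1-y) log(1-p))}.
#'
#' @param outputs raw (pre-squashing) network outputs.
#' @param targets values in \code{[0,1]}.
#' @param mask nonnegative weights, same shape.
#' @export
masked_bce <- function(outputs, targets, mask) {
  stopifnot(all(dim(outputs) == dim(targets)), all(dim(outputs) == dim(mask)))
  if (any(targets < 0 | targets > 1)) stop("targets must lie in [0,1]")
  ms <- sum(mask)
  if (ms == 0) return(0)
  p <- pmin(pmax(1 / (1 + exp(-outputs)), BCE_CLIP), 1 - BCE_CLIP)
  sum(mask * -(targets * log(p) + (1 - targets) * log(1 - p))) / ms
}

#' Regularisation penalty
#'
#' \code{lambda_l1_w * sum(|W_eff|) + lambda_l2_w * sum(W_eff^2)} over the
#' three effective weight matrices, plus \code{lambda_l2_rate * mean(r^2)}
#' over batch, time and units. Penalties act on the effective (constrained)
#' weights, not the raw parameters.
#'
#' @param weights,masks raw weights and masks.
#' @param rates firing-rate array from a forward pass (or \code{NULL} when
#'   only weight penalties are wanted).
#' @param spec a [loss_spec()].
#' @export
regularization_penalty <- function(weights, masks, rates, spec) {
  eff <- effective_weights(weights, masks)
  Ws <- list(eff$W_in, eff$W_rec, eff$W_out)
  pen <- spec$lambda_l1_w * sum(vapply(Ws, function(W) sum(abs(W)), 0)) +
    spec$lambda_l2_w * sum(vapply(Ws, function(W) sum(W^2), 0))
  if (spec$lambda_l2_rate > 0 && !is.null(rates))
    pen <- pen + spec$lambda_l2_rate * mean(rates^2)
  pen
}

#' Total training loss
#'
#' Base masked loss plus [regularization_penalty()].
#'
#' @inheritParams regularization_penalty
#' @param outputs,targets,mask output, target and mask arrays.
#' @export
total_loss <- function(outputs, targets, mask, weights, masks, rates, spec) {
  base <- switch(spec$loss,
                 mse = masked_mse(outputs, targets, mask),
                 bce = masked_bce(outputs, targets, mask))
  base + regularization_penalty(weights, masks, rates, spec)
}
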