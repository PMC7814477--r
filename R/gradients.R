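# Explicit reverse-mode differentiation (backpropagation through time) of the
# total loss through the unrolled Euler-Maruyama recurrence, the readout, the
# transfer function and the constraint reparameterisation. Noise realisations
# are treated as constants (pathwise gradients), fixed per forward pass.

# Forward + loss + gradients on internal-layout arrays.
# U: n_in x B x T; Y, M: n_out x B x T; noise: n_rec x B x T or NULL.
# Returns loss, gradients wrt raw parameters, and the forward results.
backprop_core <- function(weights, masks, net_spec, U, Y, M, noise, loss_spec) {
  eff <- effective_weights(weights, masks)
  fc <- forward_core(U, eff, net_spec, noise = noise, x0 = weights$x0)
  X <- fc$X; R <- fc$R; Z <- fc$Z
  n_rec <- net_spec$n_rec; n_in <- net_spec$n_in; n_out <- net_spec$n_out
  B <- dim(U)[2]; Tn <- dim(U)[3]
  a <- net_spec$alpha; kind <- net_spec$transfer

  msum <- sum(M)
  if (loss_spec$loss == "mse") {
    base <- if (msum == 0) 0 else sum(M * (Z - Y)^2) / msum
    dZ <- if (msum == 0) array(0, dim(Z)) else 2 * M * (Z - Y) / msum
  } else {
    P <- 1 / (1 + exp(-Z))
    clipped <- P < BCE_CLIP | P > 1 - BCE_CLIP
    Pc <- pmin(pmax(P, BCE_CLIP), 1 - BCE_CLIP)
    base <- if (msum == 0) 0 else
      sum(M * -(Y * log(Pc) + (1 - Y) * log(1 - Pc))) / msum
    dZ <- if (msum == 0) array(0, dim(Z)) else M * (P - Y) / msum
    dZ[clipped] <- 0 # gradient of the clipped constant
  }
  loss <- base + regularization_penalty(weights, masks, R, loss_spec)

  rate_coef <- if (loss_spec$lambda_l2_rate > 0)
    2 * loss_spec$lambda_l2_rate / length(R) else 0

  gW_in <- matrix(0, n_rec, n_in); gW_rec <- matrix(0, n_rec, n_rec)
  gW_out <- matrix(0, n_out, n_rec)
  gb_rec <- numeric(n_rec); gb_out <- numeric(n_out)
  tWout <- t(eff$W_out); tWrec <- t(eff$W_rec)
  r0 <- transfer(matrix(weights$x0, n_rec, B), kind)
  gnext <- NULL
  for (t in Tn:1) {
    dz <- matrix(dZ[, , t], n_out, B)
    r_t <- matrix(R[, , t], n_rec, B)
    gW_out <- gW_out + dz %*% t(r_t)
    gb_out <- gb_out + rowSums(dz)
    h <- tWout %*% dz # dL/dr_t
    if (rate_coef > 0) h <- h + rate_coef * r_t
    if (!is.null(gnext)) h <- h + a * (tWrec %*% gnext)
    fp <- transfer_deriv(matrix(X[, , t], n_rec, B), r_t, kind)
    gx <- fp * h # dL/dx_t
    if (!is.null(gnext)) gx <- gx + (1 - a) * gnext
    r_prev <- if (t == 1L) r0 else matrix(R[, , t - 1L], n_rec, B)
    gW_rec <- gW_rec + gx %*% t(r_prev)
    gW_in <- gW_in + gx %*% t(matrix(U[, , t], n_in, B))
    gb_rec <- gb_rec + rowSums(gx)
    gnext <- gx
  }
  gW_rec <- a * gW_rec; gW_in <- a * gW_in; gb_rec <- a * gb_rec

  # regularizer gradients act on the effective weights
  if (loss_spec$lambda_l1_w > 0 || loss_spec$lambda_l2_w > 0) {
    reg <- function(W) loss_spec$lambda_l1_w * sign(W) + 2 * loss_spec$lambda_l2_w * W
    gW_in <- gW_in + reg(eff$W_in)
    gW_rec <- gW_rec + reg(eff$W_rec)
    gW_out <- gW_out + reg(eff$W_out)
  }

  # chain from effective to raw weights through conn masks and, under Dale's
  # principle, through |.| and the presynaptic sign (subgradient 0 at raw = 0)
  s <- masks$dale_signs
  gW_in <- gW_in * masks$conn_in
  if (is.null(s)) {
    gW_rec <- gW_rec * masks$conn_rec
    gW_out <- gW_out * masks$conn_out
  } else {
    gW_rec <- gW_rec * masks$conn_rec * rep(s, each = n_rec) * sign(weights$W_rec_raw)
    gW_out <- gW_out * masks$conn_out * rep(s, each = n_out) * sign(weights$W_out_raw)
  }
  grads <- list(W_in_raw = gW_in, W_rec_raw = gW_rec, W_out_raw = gW_out,
                b_rec = gb_rec, b_out = gb_out)
  for (g in grads) if (!all(is.finite(g))) stop("non-finite gradient encountered")
  list(loss = loss, grads = grads, Z = Z, R = R)
}

#' Gradients of the total loss via backpropagation through time
#'
#' Computes exact reverse-mode gradients of [total_loss()] with respect to
#' every raw trainable parameter, propagating through the unrolled
#' recurrence, the transfer function and the constraint reparameterisation
#' of [effective_weights()]. Noise draws are held fixed for the evaluation.
#' ReLU and absolute-value subgradients at 0 are taken as 0.
#'
#' @param weights,masks raw weights and masks.
#' @param batch a batch from [assemble_batch()].
#' @param net_spec a [network_spec()].
#' @param loss a [loss_spec()].
#' @param noise optional \code{B x T x n_rec} array of standard-normal
#'   draws; \code{NULL} (with \code{sigma_rec > 0}) draws from the current
#'   RNG stream.
#' @return List with \code{loss} (total loss value) and \code{grads}, a list
#'   of arrays shaped like \code{W_in_raw}, \code{W_rec_raw},
#'   \code{W_out_raw}, \code{b_rec}, \code{b_out}.
#' @export
compute_gradients <- function(weights, masks, batch, net_spec, loss, noise = NULL) {
  U <- aperm(batch$inputs, c(3, 1, 2))
  Y <- aperm(batch$targets, c(3, 1, 2))
  M <- aperm(batch$mask, c(3, 1, 2))
  B <- dim(batch$inputs)[1]; Tn <- dim(batch$inputs)[2]
  if (is.null(noise) && net_spec$sigma_rec > 0)
    noise <- array(stats::rnorm(B * Tn * net_spec$n_rec), c(B, Tn, net_spec$n_rec))
  Np <- if (is.null(noise)) NULL else aperm(noise, c(3, 1, 2))
  res <- backprop_core(weights, masks, net_spec, U, Y, M, Np, loss)
  list(loss = res$loss, grads = res$grads)
}

#' Zero gradients of fixed (non-plastic) parameters
#'
#' Applies the trainability masks: gradient entries whose train mask is 0
#' are zeroed so the corresponding raw parameters never change.
#'
#' @param grads gradient list from [compute_gradients()].
#' @param masks a mask set.
#' @export
apply_constraints_to_grads <- function(grads, masks) {
  grads$W_in_raw <- grads$W_in_raw * masks$train_in
  grads$W_rec_raw <- grads$W_rec_raw * masks$train_rec
  grads$W_out_raw <- grads$W_out_raw * masks$train_out
  grads$b_rec <- grads$b_rec * masks$train_b_rec
  grads$b_out <- grads$b_out * masks$train_b_out
  grads
}
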