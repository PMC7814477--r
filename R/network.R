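#' Network specification for a continuous-time rate RNN
#'
#' Collects the architecture and dynamics hyperparameters of a rate network
#' whose state \eqn{x} evolves as
#' \deqn{\tau\, dx = (-x + W_{rec} r + b_{rec} + W_{in} u)\,dt +
#'       \sqrt{2\tau}\,\sigma_{rec}\, d\xi, \quad r = f(x),}
#' discretised by first-order Euler--Maruyama with step \code{dt}, so that
#' with \eqn{\alpha = dt/\tau} the per-step noise scale is
#' \eqn{\sqrt{2\alpha}\,\sigma_{rec}}.
#'
#' @param n_in number of input channels.
#' @param n_out number of output channels.
#' @param n_rec number of recurrent units.
#' @param dt simulation time step, ms. Must satisfy \code{0 < dt <= tau}.
#' @param tau intrinsic timescale of the recurrent units, ms.
#' @param sigma_rec standard deviation of the recurrent state noise.
#' @param transfer transfer function mapping state to firing rate:
#'   \code{"relu"} (default), \code{"tanh"} or \code{"sigmoid"}.
#' @param dales_ratio proportion of excitatory units in \code{(0,1)}, or
#'   \code{NULL} (default) for an unconstrained network. When set, the first
#'   \code{ceiling(dales_ratio * n_rec)} units are excitatory and the rest
#'   inhibitory (Dale's principle).
#'
#' @return An object of class \code{"network_spec"}.
#' @seealso [default_initializer()], [cogrnn()]
#' @export
network_spec <- function(n_in, n_out, n_rec = 50L, dt = 10, tau = 100,
                         sigma_rec = 0.05, transfer = c("relu", "tanh", "sigmoid"),
                         dales_ratio = NULL) {
  transfer <- match.arg(transfer)
  stopifnot_scalar(n_in, "n_in"); stopifnot_scalar(n_out, "n_out")
  stopifnot_scalar(n_rec, "n_rec"); stopifnot_scalar(dt, "dt")
  stopifnot_scalar(tau, "tau")
  if (sigma_rec < 0) stop("'sigma_rec' must be >= 0")
  if (dt > tau) stop("'dt' must not exceed 'tau' (alpha = dt/tau must be in (0,1])")
  if (!is.null(dales_ratio)) {
    if (dales_ratio <= 0 || dales_ratio >= 1)
      stop("'dales_ratio' must lie strictly between 0 and 1")
  }
  structure(list(n_in = as.integer(n_in), n_rec = as.integer(n_rec),
                 n_out = as.integer(n_out), dt = dt, tau = tau,
                 alpha = dt / tau, sigma_rec = sigma_rec, transfer = transfer,
                 dales_ratio = dales_ratio),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("Rate-RNN spec: %d in -> %d rec -> %d out\n", x$n_in, x$n_rec, x$n_out))
  cat(sprintf("  dt = %g ms, tau = %g ms (alpha = %g), sigma_rec = %g, transfer = %s\n",
              x$dt, x$tau, x$alpha, x$sigma_rec, x$transfer))
  if (!is.null(x$dales_ratio))
    cat(sprintf("  Dale's principle: %.0f%% excitatory units\n", 100 * x$dales_ratio))
  invisible(x)
}

#' Gaussian recurrent initialisation with fixed spectral radius
#'
#' Draws an i.i.d. standard-Gaussian matrix and rescales it so its largest
#' absolute eigenvalue equals \code{radius} (default 1.1), the conventional
#' slightly supercritical starting point for trainable rate networks.
#'
#' @param n_rec number of recurrent units.
#' @param radius target spectral radius.
#' @return An \code{n_rec x n_rec} matrix with spectral radius \code{radius}.
#' @export
init_spectral_gaussian <- function(n_rec, radius = 1.1) {
  stopifnot_scalar(n_rec, "n_rec"); stopifnot_scalar(radius, "radius")
  W <- matrix(stats::rnorm(n_rec * n_rec), n_rec, n_rec)
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rho == 0) stop("degenerate draw: zero matrix has no spectral radius to rescale")
  W * (radius / rho)
}

#' Scaled-identity recurrent initialisation
#'
#' Returns \code{alpha * I}, an initialisation that starts the recurrent
#' dynamics as independent leaky integrators.
#'
#' @param n_rec number of recurrent units.
#' @param alpha scale applied to the identity matrix.
#' @export
init_alpha_identity <- function(n_rec, alpha) {
  stopifnot_scalar(n_rec, "n_rec")
  stopifnot_scalar(alpha, "alpha", positive = FALSE)
  diag(alpha, n_rec, n_rec)
}

#' Default weight and mask initialiser
#'
#' Initialises recurrent weights from [init_spectral_gaussian()], input and
#' output weights i.i.d. Gaussian with standard deviation
#' \code{1/sqrt(fan-in)}, all biases and the initial state at zero,
#' connectivity masks all-to-all, and all parameters plastic. When the spec
#' carries a \code{dales_ratio}, a Dale sign vector is attached with
#' \code{ceiling(dales_ratio * n_rec)} excitatory (+1) entries first.
#'
#' @param spec a [network_spec()].
#' @param radius spectral radius for the recurrent initialisation.
#' @return A list with components \code{weights} (class \code{"weight_set"}:
#'   \code{W_in_raw}, \code{W_rec_raw}, \code{W_out_raw}, \code{b_rec},
#'   \code{b_out}, \code{x0}) and \code{masks} (class \code{"mask_set"}:
#'   \code{conn_*}, \code{train_*}, \code{dale_signs}).
#' @export
default_initializer <- function(spec, radius = 1.1) {
  stopifnot(inherits(spec, "network_spec"))
  n_rec <- spec$n_rec; n_in <- spec$n_in; n_out <- spec$n_out
  w <- structure(list(
    W_in_raw  = matrix(stats::rnorm(n_rec * n_in, sd = 1 / sqrt(n_in)), n_rec, n_in),
    W_rec_raw = init_spectral_gaussian(n_rec, radius),
    W_out_raw = matrix(stats::rnorm(n_out * n_rec, sd = 1 / sqrt(n_rec)), n_out, n_rec),
    b_rec = numeric(n_rec), b_out = numeric(n_out), x0 = numeric(n_rec)
  ), class = "weight_set")
  dale <- NULL
  if (!is.null(spec$dales_ratio)) {
    n_exc <- ceiling(spec$dales_ratio * n_rec)
    dale <- c(rep(1, n_exc), rep(-1, n_rec - n_exc))
  }
  m <- structure(list(
    conn_in  = matrix(1, n_rec, n_in),
    conn_rec = matrix(1, n_rec, n_rec),
    conn_out = matrix(1, n_out, n_rec),
    train_in = matrix(1, n_rec, n_in),
    train_rec = matrix(1, n_rec, n_rec),
    train_out = matrix(1, n_out, n_rec),
    train_b_rec = rep(1, n_rec), train_b_out = rep(1, n_out),
    dale_signs = dale
  ), class = "mask_set")
  list(weights = w, masks = m)
}

#' Structured connectivity and trainability masks
#'
#' Applies a named mask recipe to an existing mask set:
#' \describe{
#'   \item{\code{no_autapse}}{forbids self-connections (zero diagonal of
#'     \code{conn_rec}).}
#'   \item{\code{two_region}}{two densely connected populations with sparse
#'     Bernoulli(\code{p_inter}) connections between them; \code{sizes} must
#'     sum to \code{n_rec}. Emulates long-range interactions between areas.}
#'   \item{\code{dale_fixed_ei}}{with Dale signs present, freezes every
#'     connection between units of opposite sign (E-to-I and I-to-E fixed at
#'     their initial weights; within-population connections stay plastic).}
#' }
#'
#' @param masks a mask set from [default_initializer()].
#' @param kind recipe name.
#' @param sizes integer vector of region sizes (for \code{two_region}).
#' @param p_inter inter-region connection probability in \code{[0,1]}
#'   (for \code{two_region}).
#' @return The modified mask set.
#' @export
make_structured_masks <- function(masks, kind = c("no_autapse", "two_region", "dale_fixed_ei"),
                                  sizes = NULL, p_inter = 0.05) {
  kind <- match.arg(kind)
  stopifnot(inherits(masks, "mask_set"))
  n_rec <- nrow(masks$conn_rec)
  if (kind == "no_autapse") {
    diag(masks$conn_rec) <- 0
  } else if (kind == "two_region") {
    if (is.null(sizes) || length(sizes) < 2L)
      stop("'two_region' needs a vector of at least two region sizes")
    if (sum(sizes) != n_rec)
      stop(sprintf("region sizes sum to %d but n_rec is %d", sum(sizes), n_rec))
    if (p_inter < 0 || p_inter > 1) stop("'p_inter' must lie in [0,1]")
    region <- rep(seq_along(sizes), sizes)
    inter <- outer(region, region, "!=")
    conn <- matrix(1, n_rec, n_rec)
    conn[inter] <- stats::rbinom(sum(inter), 1L, p_inter)
    masks$conn_rec <- masks$conn_rec * conn
  } else { # dale_fixed_ei
    if (is.null(masks$dale_signs))
      stop("'dale_fixed_ei' requires Dale signs (set dales_ratio in the network spec)")
    s <- masks$dale_signs
    opposite <- outer(s, s, "!=") # [i,j]: post-synaptic unit i, pre-synaptic j
    masks$train_rec[opposite] <- 0
  }
  masks
}

#' Effective synaptic weights under connectivity constraints
#'
#' Maps raw trainable parameters to the weights the dynamics actually use.
#' Forbidden connections (connectivity mask 0) are zeroed. Under Dale's
#' principle the recurrent and output weights are reparameterised as
#' \code{conn * abs(raw) * sign(presynaptic unit)}, so each recurrent unit's
#' outgoing weights all share its sign at every training iteration; input
#' weights are unsigned.
#'
#' @param weights a weight set.
#' @param masks a mask set.
#' @return List with \code{W_in}, \code{W_rec}, \code{W_out}, \code{b_rec},
#'   \code{b_out}.
#' @export
effective_weights <- function(weights, masks) {
  s <- masks$dale_signs
  if (is.null(s)) {
    W_rec <- masks$conn_rec * weights$W_rec_raw
    W_out <- masks$conn_out * weights$W_out_raw
  } else {
    W_rec <- masks$conn_rec * abs(weights$W_rec_raw) * rep(s, each = nrow(masks$conn_rec))
    W_out <- masks$conn_out * abs(weights$W_out_raw) * rep(s, each = nrow(masks$conn_out))
  }
  list(W_in = masks$conn_in * weights$W_in_raw, W_rec = W_rec, W_out = W_out,
       b_rec = weights$b_rec, b_out = weights$b_out)
}

#' Transfer functions
#'
#' Elementwise state-to-rate nonlinearity. \code{"relu"} is
#' \code{pmax(x, 0)}; at exactly 0 its subgradient is taken as 0.
#'
#' @param x state vector/matrix/array.
#' @param kind one of \code{"relu"}, \code{"tanh"}, \code{"sigmoid"}.
#' @export
transfer <- function(x, kind = "relu") {
  switch(kind,
         relu = pmax(x, 0),
         tanh = tanh(x),
         sigmoid = 1 / (1 + exp(-x)),
         stop(sprintf("unknown transfer function '%s'", kind)))
}

# derivative f'(x), expressed where convenient via r = f(x)
transfer_deriv <- function(x, r, kind) {
  switch(kind,
         relu = (x > 0) + 0,
         tanh = 1 - r * r,
         sigmoid = r * (1 - r),
         stop(sprintf("unknown transfer function '%s'", kind)))
}

#' Single Euler--Maruyama step of the rate dynamics
#'
#' Advances the state one time step:
#' \code{x' = (1-alpha) x + alpha (W_rec r + b_rec + W_in u) +
#' sqrt(2 alpha) sigma_rec noise}, with \code{r = f(x)} and
#' \code{alpha = dt/tau}. The standard-normal \code{noise} vector is injected
#' by the caller so trajectories are exactly reproducible and testable.
#'
#' @param x current state (length \code{n_rec}, or \code{n_rec x B} matrix).
#' @param u input at this step (length \code{n_in}, or \code{n_in x B}).
#' @param weights,masks raw weights and masks; effective weights are formed
#'   internally (or pass a precomputed [effective_weights()] list as
#'   \code{weights} with \code{masks = NULL}).
#' @param spec a [network_spec()].
#' @param noise standard-normal draw(s), same shape as \code{x}.
#' @export
rnn_step <- function(x, u, weights, masks, spec, noise = 0) {
  eff <- if (is.null(masks)) weights else effective_weights(weights, masks)
  a <- spec$alpha
  r <- transfer(x, spec$transfer)
  xn <- (1 - a) * x + a * (eff$W_rec %*% r + eff$b_rec + eff$W_in %*% u) +
    sqrt(2 * a) * spec$sigma_rec * noise
  if (!all(is.finite(xn))) stop("network state diverged (non-finite values)")
  drop(xn)
}

# Core recurrence shared by training, prediction and the simulator.
# U: n_in x B x T; noise: n_rec x B x T (already standard-normal) or NULL.
# pulse: optional n_rec x T matrix added to x after each step (perturbations).
# Returns internal-layout arrays X, R (n_rec x B x T) and Z (n_out x B x T).
forward_core <- function(U, eff, spec, noise = NULL, x0 = NULL, pulse = NULL) {
  n_in <- dim(U)[1]; B <- dim(U)[2]; Tn <- dim(U)[3]
  n_rec <- nrow(eff$W_rec); n_out <- nrow(eff$W_out)
  a <- spec$alpha; ns <- sqrt(2 * a) * spec$sigma_rec
  X <- array(0, c(n_rec, B, Tn)); R <- array(0, c(n_rec, B, Tn))
  Z <- array(0, c(n_out, B, Tn))
  x <- matrix(x0 %||% numeric(n_rec), n_rec, B)
  for (t in seq_len(Tn)) {
    r <- transfer(x, spec$transfer)
    x <- (1 - a) * x + a * (eff$W_rec %*% r + eff$b_rec + eff$W_in %*% matrix(U[, , t], n_in, B))
    if (!is.null(noise)) x <- x + ns * matrix(noise[, , t], n_rec, B)
    if (!is.null(pulse)) x <- x + pulse[, t]
    if (!all(is.finite(x))) stop(sprintf("network state diverged at step %d", t))
    X[, , t] <- x
    rt <- transfer(x, spec$transfer)
    R[, , t] <- rt
    Z[, , t] <- eff$W_out %*% rt + eff$b_out
  }
  list(X = X, R = R, Z = Z)
}

#' Forward pass of the network over a batch of trials
#'
#' Unrolls the stochastic rate dynamics over every trial in a batch and reads
#' out \code{z = W_out r + b_out} at each step.
#'
#' @param inputs a \code{B x T x n_in} array (or a \code{T x n_in} matrix for
#'   a single trial).
#' @param weights,masks raw weights and masks.
#' @param spec a [network_spec()].
#' @param noise optional \code{B x T x n_rec} array of standard-normal draws;
#'   if \code{NULL} and \code{sigma_rec > 0}, draws are taken from the
#'   current RNG stream.
#' @return List with arrays \code{states}, \code{rates}
#'   (\code{B x T x n_rec}) and \code{outputs} (\code{B x T x n_out}).
#' @export
rnn_forward <- function(inputs, weights, masks, spec, noise = NULL) {
  if (is.matrix(inputs)) inputs <- array(inputs, c(1L, dim(inputs)))
  stopifnot(length(dim(inputs)) == 3L, dim(inputs)[3] == spec$n_in)
  B <- dim(inputs)[1]; Tn <- dim(inputs)[2]
  U <- aperm(inputs, c(3, 1, 2))
  if (is.null(noise) && spec$sigma_rec > 0)
    noise <- array(stats::rnorm(B * Tn * spec$n_rec), c(B, Tn, spec$n_rec))
  Np <- if (is.null(noise)) NULL else aperm(noise, c(3, 1, 2))
  eff <- effective_weights(weights, masks)
  fc <- forward_core(U, eff, spec, noise = Np, x0 = weights$x0)
  list(states = aperm(fc$X, c(2, 3, 1)), rates = aperm(fc$R, c(2, 3, 1)),
       outputs = aperm(fc$Z, c(2, 3, 1)))
}
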