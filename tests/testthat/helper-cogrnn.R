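# Shared helpers: a short perceptual-discrimination task for fast tests, a
# central finite-difference gradient checker, and a cached trained network
# reused by the analysis tests.

with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}

# independent brute-force re-assembly: loop trial_function over t
loop_assemble <- function(task, params) {
  rows <- lapply(seq_len(task$T) - 1L, function(k)
    trial_function(task, k * task$dt, params))
  list(inputs = do.call(rbind, lapply(rows, `[[`, "input")),
       targets = do.call(rbind, lapply(rows, `[[`, "target")),
       mask = do.call(rbind, lapply(rows, `[[`, "mask")))
}

short_pd <- function(coherences = 0.5, ...) {
  perceptual_discrimination(coherences = coherences, fixation = 20,
                            stimulus = 60, response = 20, ...)
}

# worst relative error between BPTT gradients and central finite differences,
# probed on up to `probe` trainable entries per parameter
fd_worst_rel <- function(weights, masks, batch, spec, loss, noise,
                         eps = 1e-5, probe = 10) {
  res <- compute_gradients(weights, masks, batch, spec, loss, noise = noise)
  lossfun <- function(w) compute_gradients(w, masks, batch, spec, loss,
                                           noise = noise)$loss
  train_of <- list(W_in_raw = masks$train_in, W_rec_raw = masks$train_rec,
                   W_out_raw = masks$train_out, b_rec = masks$train_b_rec,
                   b_out = masks$train_b_out)
  worst <- 0
  for (nm in names(train_of)) {
    idx <- which(train_of[[nm]] == 1)
    if (!length(idx)) next
    idx <- idx[unique(round(seq(1, length(idx), length.out = min(probe, length(idx)))))]
    for (i in idx) {
      wp <- weights; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- weights; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (lossfun(wp) - lossfun(wm)) / (2 * eps)
      an <- res$grads[[nm]][i]
      worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
    }
  }
  worst
}

# random small network + batch for gradient checking
random_grad_case <- function(seed, n_rec, Tn, dale = FALSE, conn = FALSE,
                             fixed = FALSE, lossname = "mse",
                             regs = c(0, 0, 0)) {
  set.seed(seed)
  spec <- network_spec(n_in = 2, n_out = 2, n_rec = n_rec, dt = 10, tau = 100,
                       sigma_rec = 0.1, dales_ratio = if (dale) 0.6 else NULL)
  init <- default_initializer(spec)
  w <- init$weights; m <- init$masks
  w$b_rec <- rnorm(n_rec, 0, 0.1); w$b_out <- rnorm(2, 0, 0.1)
  if (conn) m$conn_rec[sample(n_rec^2, n_rec)] <- 0
  if (fixed) m$train_rec[sample(n_rec^2, n_rec)] <- 0
  resp_steps <- max(1, round(0.3 * Tn))
  stim_steps <- max(1, Tn - 1 - resp_steps)
  fix_steps <- Tn - stim_steps - resp_steps
  task <- perceptual_discrimination(coherences = 0.5, fixation = 10 * max(1, fix_steps),
                                    stimulus = 10 * stim_steps,
                                    response = 10 * resp_steps)
  batch <- assemble_batch(task, 2, seed = seed + 1)
  set.seed(seed + 2)
  noise <- array(rnorm(2 * Tn * n_rec), c(2, Tn, n_rec))
  list(weights = w, masks = m, batch = batch, spec = spec,
       loss = loss_spec(lossname, lambda_l1_w = regs[1], lambda_l2_w = regs[2],
                        lambda_l2_rate = regs[3]),
       noise = noise)
}

# hand-built all-zero network of arbitrary widths (class-tagged like the
# initialiser's output)
zero_network <- function(n_in, n_rec, n_out) {
  w <- structure(list(W_in_raw = matrix(0, n_rec, n_in),
                      W_rec_raw = matrix(0, n_rec, n_rec),
                      W_out_raw = matrix(0, n_out, n_rec),
                      b_rec = numeric(n_rec), b_out = numeric(n_out),
                      x0 = numeric(n_rec)), class = "weight_set")
  m <- structure(list(conn_in = matrix(1, n_rec, n_in),
                      conn_rec = matrix(1, n_rec, n_rec),
                      conn_out = matrix(1, n_out, n_rec),
                      train_in = matrix(1, n_rec, n_in),
                      train_rec = matrix(1, n_rec, n_rec),
                      train_out = matrix(1, n_out, n_rec),
                      train_b_rec = rep(1, n_rec), train_b_out = rep(1, n_out),
                      dale_signs = NULL), class = "mask_set")
  list(weights = w, masks = m)
}

# A modestly trained perceptual-discrimination network shared across analysis
# tests (trained once per test run, then cached).
.fit_cache <- new.env(parent = emptyenv())
trained_pd_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    task <- perceptual_discrimination(coherences = c(0.7, 0.5, 0.3),
                                      fixation = 100, stimulus = 600,
                                      response = 200)
    .fit_cache$fit <- cogrnn(task, spec = network_spec(2, 2, n_rec = 30),
                             control = train_config(n_iterations = 300,
                                                    master_seed = 7))
  }
  .fit_cache$fit
}
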