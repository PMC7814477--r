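test_that("spectral-radius initialiser hits its target across seeds and sizes", {
  for (seed in 1:10) {
    set.seed(seed)
    W <- init_spectral_gaussian(50)
    rho <- max(Mod(eigen(W, only.values = TRUE)$values))
    expect_lt(abs(rho - 1.1) / 1.1, 1e-9)
  }
  set.seed(1)
  expect_equal(abs(init_spectral_gaussian(1, radius = 0.7)[1, 1]), 0.7)
  # eigenvalues of a 3x3 draw match the roots of its characteristic polynomial
  set.seed(3)
  W <- init_spectral_gaussian(3)
  ev <- sort(Mod(eigen(W, only.values = TRUE)$values))
  # coefficients of det(W - x I) computed by hand from trace/minors/det
  c2 <- -sum(diag(W))
  c1 <- sum(vapply(1:3, function(i) det(W[-i, -i, drop = FALSE]), 0))
  c0 <- -det(W)
  roots <- polyroot(c(c0, c1, c2, 1))
  expect_equal(ev, sort(Mod(roots)), tolerance = 1e-8)
})

test_that("alpha-identity initialiser scales the identity", {
  expect_equal(init_alpha_identity(4, 1), diag(4))
  expect_equal(init_alpha_identity(3, 0), matrix(0, 3, 3))
  for (a in c(-2, 0.5, 3)) {
    rho <- max(Mod(eigen(init_alpha_identity(5, a), only.values = TRUE)$values))
    expect_equal(rho, abs(a))
  }
})

test_that("default initialiser gives zero biases, all-to-all masks, Dale counts", {
  spec <- network_spec(2, 2, n_rec = 10, dales_ratio = 0.8)
  set.seed(2)
  init <- default_initializer(spec)
  expect_equal(init$weights$b_rec, numeric(10))
  expect_equal(init$weights$b_out, numeric(2))
  expect_equal(init$weights$x0, numeric(10))
  expect_true(all(init$masks$conn_rec == 1) && all(init$masks$conn_in == 1) &&
                all(init$masks$conn_out == 1))
  expect_true(all(init$masks$train_rec == 1))
  expect_equal(sum(init$masks$dale_signs == 1), 8)
  expect_equal(sum(init$masks$dale_signs == -1), 2)
})

test_that("structured mask recipes shape connectivity and plasticity", {
  spec <- network_spec(2, 2, n_rec = 5)
  set.seed(4)
  m <- default_initializer(spec)$masks
  m2 <- make_structured_masks(m, "no_autapse")
  expect_equal(sum(diag(m2$conn_rec)), 0)
  expect_equal(m2$conn_rec[upper.tri(m2$conn_rec)],
               m$conn_rec[upper.tri(m$conn_rec)])

  spec2 <- network_spec(2, 2, n_rec = 50)
  set.seed(5)
  m <- default_initializer(spec2)$masks
  m2 <- make_structured_masks(m, "two_region", sizes = c(30, 20), p_inter = 0)
  expect_equal(m2$conn_rec[1:30, 1:30], matrix(1, 30, 30))
  expect_equal(m2$conn_rec[31:50, 31:50], matrix(1, 20, 20))
  expect_true(all(m2$conn_rec[1:30, 31:50] == 0))
  expect_true(all(m2$conn_rec[31:50, 1:30] == 0))
  expect_error(make_structured_masks(m, "two_region", sizes = c(30, 10)),
               "sum to 40")

  spec3 <- network_spec(2, 2, n_rec = 10, dales_ratio = 0.8)
  set.seed(6)
  m <- default_initializer(spec3)$masks
  m2 <- make_structured_masks(m, "dale_fixed_ei")
  expect_equal(sum(m2$train_rec == 0), 2 * 8 * 2) # E->I and I->E blocks
  s <- m2$dale_signs
  fixed <- which(m2$train_rec == 0, arr.ind = TRUE)
  expect_true(all(s[fixed[, 1]] != s[fixed[, 2]]))
})

test_that("effective weights honour connectivity masks and Dale sign purity", {
  spec <- network_spec(2, 2, n_rec = 8, dales_ratio = 0.75)
  set.seed(7)
  init <- default_initializer(spec)
  w <- init$weights; m <- init$masks
  m$conn_rec[2, 3] <- 0
  eff <- effective_weights(w, m)
  expect_equal(eff$W_rec[2, 3], 0)
  s <- m$dale_signs
  for (j in 1:8) {
    expect_true(all(eff$W_rec[, j] * s[j] >= 0))
    expect_true(all(eff$W_out[, j] * s[j] >= 0))
  }
  # without masks or Dale, effective weights are the raw weights
  spec2 <- network_spec(2, 2, n_rec = 4)
  set.seed(8)
  init2 <- default_initializer(spec2)
  eff2 <- effective_weights(init2$weights, init2$masks)
  expect_identical(eff2$W_rec, init2$weights$W_rec_raw)
  expect_identical(eff2$W_in, init2$weights$W_in_raw)
})

test_that("transfer functions are correct elementwise and relu is idempotent", {
  expect_equal(transfer(c(-2, 3), "relu"), c(0, 3))
  expect_equal(transfer(0, "tanh"), 0)
  expect_equal(transfer(0, "sigmoid"), 0.5)
  expect_error(transfer(1, "softplus"), "unknown")
  set.seed(9)
  x <- rnorm(100)
  expect_identical(transfer(transfer(x, "relu"), "relu"), transfer(x, "relu"))
})

test_that("a single step reproduces closed-form leak and fixed points", {
  spec <- network_spec(n_in = 1, n_out = 1, n_rec = 1, dt = 10, tau = 100,
                       sigma_rec = 0)
  w <- structure(list(W_in_raw = matrix(0), W_rec_raw = matrix(0),
                      W_out_raw = matrix(0), b_rec = 0, b_out = 0, x0 = 0),
                 class = "weight_set")
  m <- structure(list(conn_in = matrix(1), conn_rec = matrix(1),
                      conn_out = matrix(1), train_in = matrix(1),
                      train_rec = matrix(1), train_out = matrix(1),
                      train_b_rec = 1, train_b_out = 1, dale_signs = NULL),
                 class = "mask_set")
  expect_equal(rnn_step(1, 0, w, m, spec), 0.9) # pure leak with alpha = 0.1
  w$W_rec_raw <- matrix(1)
  expect_equal(rnn_step(1, 0, w, m, spec), 1) # relu identity fixed point
})

test_that("with zero weights and no noise the state decays as (1-alpha)^t", {
  fx <- fixture_network(n_rec = 3, seed = 11)
  w <- fx$weights
  w$W_in_raw[] <- 0; w$W_rec_raw[] <- 0; w$x0 <- c(1, -2, 0.5)
  spec <- network_spec(2, 2, n_rec = 3, sigma_rec = 0)
  inputs <- array(0, c(1, 20, 2))
  fwd <- rnn_forward(inputs, w, fx$masks, spec)
  for (t in 1:20)
    expect_equal(fwd$states[1, t, ], 0.9^t * c(1, -2, 0.5))
})

test_that("forward pass matches sequential single steps plus readout", {
  fx <- fixture_network(n_rec = 3, seed = 13)
  spec <- fx$spec
  task <- short_pd()
  b <- assemble_batch(task, 1, seed = 14)
  set.seed(15)
  noise <- array(rnorm(task$T * 3), c(1, task$T, 3))
  fwd <- rnn_forward(b$inputs, fx$weights, fx$masks, spec, noise = noise)
  # independently scripted recurrence
  eff <- effective_weights(fx$weights, fx$masks)
  x <- fx$weights$x0
  for (t in seq_len(task$T)) {
    x <- rnn_step(x, b$inputs[1, t, ], eff, NULL, spec, noise = noise[1, t, ])
    z <- drop(eff$W_out %*% transfer(x, spec$transfer) + eff$b_out)
    expect_equal(fwd$states[1, t, ], x, tolerance = 1e-12)
    expect_equal(fwd$outputs[1, t, ], z, tolerance = 1e-12)
  }
  # zero weights -> outputs identically zero
  w0 <- fx$weights
  w0$W_in_raw[] <- 0; w0$W_rec_raw[] <- 0; w0$W_out_raw[] <- 0
  fwd0 <- rnn_forward(b$inputs, w0, fx$masks, spec, noise = noise)
  expect_true(all(fwd0$outputs == 0))
  # sigma_rec = 0 makes the forward pass deterministic
  spec0 <- spec; spec0$sigma_rec <- 0
  f1 <- rnn_forward(b$inputs, fx$weights, fx$masks, spec0)
  f2 <- rnn_forward(b$inputs, fx$weights, fx$masks, spec0)
  expect_identical(f1$outputs, f2$outputs)
})

test_that("stationary state variance matches the discrete OU prediction", {
  spec <- network_spec(n_in = 1, n_out = 1, n_rec = 1, dt = 10, tau = 100,
                       sigma_rec = 0.3)
  a <- spec$alpha
  net <- zero_network(1, 1, 1)
  w <- net$weights; m <- net$masks
  n_steps <- 2e4
  set.seed(17)
  noise <- array(rnorm(n_steps), c(1, n_steps, 1))
  fwd <- rnn_forward(array(0, c(1, n_steps, 1)), w, m, spec, noise = noise)
  v_emp <- stats::var(fwd$states[1, -(1:500), 1])
  v_theory <- spec$sigma_rec^2 * 2 * a / (1 - (1 - a)^2)
  expect_lt(abs(v_emp - v_theory) / v_theory, 0.1)
})
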