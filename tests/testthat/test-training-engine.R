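test_that("masked losses match elementwise hand loops", {
  set.seed(21)
  Z <- array(rnorm(2 * 5 * 2), c(2, 5, 2))
  Y <- array(runif(2 * 5 * 2), c(2, 5, 2))
  M <- array(rbinom(2 * 5 * 2, 1, 0.6), c(2, 5, 2))
  # scripted loops
  num <- 0; den <- 0; bce <- 0
  for (i in 1:2) for (t in 1:5) for (k in 1:2) {
    num <- num + M[i, t, k] * (Z[i, t, k] - Y[i, t, k])^2
    p <- 1 / (1 + exp(-Z[i, t, k]))
    bce <- bce + M[i, t, k] * -(Y[i, t, k] * log(p) + (1 - Y[i, t, k]) * log(1 - p))
    den <- den + M[i, t, k]
  }
  expect_equal(masked_mse(Z, Y, M), num / den)
  expect_equal(masked_bce(Z, Y, M), bce / den)
  expect_equal(masked_mse(Y, Y, M), 0)
  expect_equal(masked_mse(array(3, c(1, 1, 1)), array(1, c(1, 1, 1)),
                          array(1, c(1, 1, 1))), 4)
  expect_equal(masked_bce(array(0, c(1, 1, 1)), array(1, c(1, 1, 1)),
                          array(1, c(1, 1, 1))), log(2))
  expect_equal(masked_mse(Z, Y, M * 0), 0)
  expect_equal(masked_bce(Z, Y, M * 0), 0)
  expect_error(masked_bce(Z, Y + 2, M), "\\[0,1\\]")
})

test_that("regularisation penalties match independent norm computations", {
  fx <- fixture_network(n_rec = 4, seed = 23)
  w <- fx$weights; m <- fx$masks
  expect_equal(regularization_penalty(w, m, NULL, loss_spec()), 0)
  # single weight of 3, lambda_l2_w = 1 -> penalty 9
  w0 <- w
  w0$W_in_raw[] <- 0; w0$W_rec_raw[] <- 0; w0$W_out_raw[] <- 0
  w0$W_rec_raw[2, 3] <- 3
  expect_equal(regularization_penalty(w0, m, NULL, loss_spec(lambda_l2_w = 1)), 9)
  set.seed(24)
  rates <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  ls <- loss_spec(lambda_l1_w = 0.3, lambda_l2_w = 0.7, lambda_l2_rate = 0.2)
  eff <- effective_weights(w, m)
  manual <- 0.3 * (sum(abs(eff$W_in)) + sum(abs(eff$W_rec)) + sum(abs(eff$W_out))) +
    0.7 * (sum(eff$W_in^2) + sum(eff$W_rec^2) + sum(eff$W_out^2)) +
    0.2 * mean(rates^2)
  expect_equal(regularization_penalty(w, m, rates, ls), manual)
  # total loss is the sum of the two independently computed terms
  Z <- array(rnorm(8), c(2, 2, 2)); Y <- array(runif(8), c(2, 2, 2))
  M <- array(1, c(2, 2, 2))
  expect_equal(total_loss(Z, Y, M, w, m, rates, ls),
               masked_mse(Z, Y, M) + regularization_penalty(w, m, rates, ls))
  expect_equal(total_loss(Z, Y, M, w, m, rates, loss_spec()), masked_mse(Z, Y, M))
})

test_that("BPTT gradients match central finite differences across regimes", {
  cases <- expand.grid(dale = c(FALSE, TRUE), conn = c(FALSE, TRUE),
                       loss = c("mse", "bce"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    regs <- if (i %% 2 == 0) c(0.01, 0.01, 0.01) else c(0, 0, 0)
    cs <- random_grad_case(300 + i, n_rec = c(2, 3, 5)[1 + i %% 3],
                           Tn = c(3, 5, 10)[1 + i %% 3],
                           dale = cases$dale[i], conn = cases$conn[i],
                           fixed = (i %% 2 == 1), lossname = cases$loss[i],
                           regs = regs)
    worst <- fd_worst_rel(cs$weights, cs$masks, cs$batch, cs$spec, cs$loss,
                          cs$noise, probe = 6)
    expect_lt(worst, 1e-4)
  }
})

test_that("gradients vanish where constraints forbid learning", {
  cs <- random_grad_case(401, n_rec = 5, Tn = 5, dale = TRUE, conn = TRUE)
  res <- compute_gradients(cs$weights, cs$masks, cs$batch, cs$spec, cs$loss,
                           noise = cs$noise)
  expect_true(all(res$grads$W_rec_raw[cs$masks$conn_rec == 0] == 0))
  # flat minimum: zero weights, zero inputs, zero targets
  fx <- fixture_network(n_rec = 3, seed = 25)
  w0 <- fx$weights
  w0$W_in_raw[] <- 0; w0$W_rec_raw[] <- 0; w0$W_out_raw[] <- 0
  task <- short_pd(coherences = 0, input_noise_sd = 0)
  b <- assemble_batch(task, 2, seed = 26)
  b$inputs[] <- 0; b$targets[] <- 0
  spec0 <- network_spec(2, 2, n_rec = 3, sigma_rec = 0)
  res0 <- compute_gradients(w0, fx$masks, b, spec0, loss_spec())
  for (g in res0$grads) expect_true(all(g == 0))
  # trainability masks zero the fixed entries
  m <- fx$masks; m$train_rec[] <- 0
  res1 <- compute_gradients(fx$weights, m, b, spec0, loss_spec())
  g1 <- apply_constraints_to_grads(res1$grads, m)
  expect_true(all(g1$W_rec_raw == 0))
  m$train_rec[] <- 1
  expect_equal(apply_constraints_to_grads(res1$grads, m), res1$grads)
})

test_that("optimizer updates follow their published rules", {
  cfg_sgd <- train_config("sgd", learning_rate = 0.1)
  st <- optimizer_init(cfg_sgd, list(p = 1))
  up <- optimizer_step(st, list(p = 1), list(p = 2), cfg_sgd)
  expect_equal(up$params$p, 0.8)
  # zero gradient leaves parameters unchanged for every optimizer
  for (opt in c("sgd", "adam", "rmsprop")) {
    cfg <- train_config(opt)
    st <- optimizer_init(cfg, list(p = matrix(1:4, 2)))
    up <- optimizer_step(st, list(p = matrix(1:4, 2)), list(p = matrix(0, 2, 2)), cfg)
    expect_equal(up$params$p, matrix(1:4, 2))
  }
  # 10 adam steps on f(p) = p^2 from p = 1 vs a scripted reference
  cfg <- train_config("adam", learning_rate = 0.05)
  st <- optimizer_init(cfg, list(p = 1)); p <- 1
  for (i in 1:10) {
    up <- optimizer_step(st, list(p = p), list(p = 2 * p), cfg)
    st <- up$state; p <- up$params$p
  }
  pr <- 1; m <- 0; v <- 0
  for (i in 1:10) {
    g <- 2 * pr
    m <- 0.9 * m + 0.1 * g; v <- 0.999 * v + 0.001 * g^2
    pr <- pr - 0.05 * (m / (1 - 0.9^i)) / (sqrt(v / (1 - 0.999^i)) + 1e-8)
  }
  expect_equal(p, pr, tolerance = 1e-12)
  # rmsprop scripted reference
  cfg <- train_config("rmsprop", learning_rate = 0.05)
  st <- optimizer_init(cfg, list(p = 1)); p <- 1
  for (i in 1:5) {
    up <- optimizer_step(st, list(p = p), list(p = 2 * p), cfg)
    st <- up$state; p <- up$params$p
  }
  pr <- 1; v <- 0
  for (i in 1:5) {
    g <- 2 * pr
    v <- 0.9 * v + 0.1 * g^2
    pr <- pr - 0.05 * g / (sqrt(v) + 1e-8)
  }
  expect_equal(p, pr, tolerance = 1e-12)
  # global-norm clipping rescales long gradients
  cfg <- train_config("sgd", learning_rate = 1, grad_clip_norm = 1)
  st <- optimizer_init(cfg, list(p = c(0, 0)))
  up <- optimizer_step(st, list(p = c(0, 0)), list(p = c(3, 4)), cfg)
  expect_equal(up$params$p, -c(3, 4) / 5)
})

test_that("training respects constraints and is reproducible", {
  task <- short_pd(coherences = 0.5)
  spec <- network_spec(2, 2, n_rec = 12, dales_ratio = 0.75)
  ctrl <- train_config(n_iterations = 60, eval_every = 20, batch_size = 16,
                       eval_batch = 32, master_seed = 31)
  set.seed(31)
  init <- default_initializer(spec)
  init$masks$conn_rec[1, 2] <- 0
  init$masks$train_rec[3, 4] <- 0
  fit <- cogrnn(task, spec = spec, control = ctrl, init = init)
  # n_iterations = 0 returns the initial weights untouched
  fit0 <- cogrnn(task, spec = spec, control = train_config(n_iterations = 0,
                                                           master_seed = 31),
                 init = init)
  expect_identical(fit0$weights, init$weights)
  # forbidden entry stays exactly zero, fixed raw entry bit-identical
  eff <- coef(fit)
  expect_identical(eff$W_rec[1, 2], 0)
  expect_identical(fit$weights$W_rec_raw[3, 4], init$weights$W_rec_raw[3, 4])
  # Dale sign purity after training
  s <- init$masks$dale_signs
  for (j in 1:12) expect_true(all(eff$W_rec[, j] * s[j] >= 0))
  # determinism: identical master seed, identical trace and weights
  fit2 <- cogrnn(task, spec = spec, control = ctrl, init = init)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$weights, fit2$weights)
  expect_s3_class(fit$trace, "data.frame")
  expect_equal(fit$trace$iteration, c(20, 40, 60))
  expect_true(all(fit$trace$accuracy >= 0 & fit$trace$accuracy <= 1))
})

test_that("evaluation loss decreases over default perceptual-discrimination training", {
  for (seed in 1:3) {
    task <- short_pd(coherences = 0.5)
    fit <- cogrnn(task, spec = network_spec(2, 2, n_rec = 20),
                  control = train_config(n_iterations = 100, eval_every = 10,
                                         master_seed = seed))
    ls <- fit$trace$loss
    expect_lt(stats::median(tail(ls, 3)), stats::median(head(ls, 3)))
  }
})
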