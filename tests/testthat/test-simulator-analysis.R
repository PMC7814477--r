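test_that("standalone simulator reproduces the training forward pass exactly", {
  task <- short_pd()
  for (seed in 1:20) {
    dale <- seed %% 2 == 0
    fx <- fixture_network(n_rec = 6, seed = 60 + seed,
                          dales_ratio = if (dale) 0.8 else NULL)
    b <- assemble_batch(task, 3, seed = 80 + seed)
    set.seed(100 + seed)
    noise <- array(rnorm(3 * task$T * 6), c(3, task$T, 6))
    fwd <- rnn_forward(b$inputs, fx$weights, fx$masks, fx$spec, noise = noise)
    sim <- rnn_simulate(fx$weights, fx$masks, fx$spec, b$inputs, noise = noise)
    expect_equal(sim$outputs, fwd$outputs, tolerance = 1e-14)
    expect_equal(sim$states, fwd$states, tolerance = 1e-14)
  }
})

test_that("lesioning all units leaves only the output bias", {
  fx <- fixture_network(n_rec = 5, seed = 90)
  fx$weights$b_out <- c(0.3, -0.2)
  task <- short_pd()
  b <- assemble_batch(task, 2, seed = 91)
  set.seed(92)
  noise <- array(rnorm(2 * task$T * 5), c(2, task$T, 5))
  sim <- rnn_simulate(fx$weights, fx$masks, fx$spec, b$inputs, noise = noise,
                      pert = perturbation("lesion_units", targets = 1:5))
  expect_true(all(abs(sweep(sim$outputs, 3, c(0.3, -0.2))) == 0))
  # lesioning a unit whose effective weights are already zero changes nothing
  fx2 <- fixture_network(n_rec = 5, seed = 93)
  fx2$weights$W_rec_raw[3, ] <- 0; fx2$weights$W_rec_raw[, 3] <- 0
  fx2$weights$W_out_raw[, 3] <- 0; fx2$weights$W_in_raw[3, ] <- 0
  base <- rnn_simulate(fx2$weights, fx2$masks, fx2$spec, b$inputs, noise = noise)
  les <- rnn_simulate(fx2$weights, fx2$masks, fx2$spec, b$inputs, noise = noise,
                      pert = perturbation("lesion_units", targets = 3))
  expect_equal(les$outputs, base$outputs, tolerance = 1e-14)
  expect_error(rnn_simulate(fx$weights, fx$masks, fx$spec, b$inputs,
                            pert = perturbation("lesion_units", targets = 9)),
               "targets")
})

test_that("a state pulse on an isolated unit decays with the leak", {
  spec <- network_spec(n_in = 1, n_out = 1, n_rec = 1, dt = 10, tau = 100,
                       sigma_rec = 0)
  net <- zero_network(1, 1, 1)
  w <- net$weights; m <- net$masks
  Tn <- 30
  pert <- perturbation("state_pulse", targets = 1, magnitude = 2,
                       onset = 50, duration = 10) # exactly step index 6
  sim <- rnn_simulate(w, m, spec, matrix(0, Tn, 1), pert = pert)
  x <- sim$states[1, , 1]
  expect_equal(x[1:5], rep(0, 5))
  # closed-form leak of the injected charge: 2 * 0.9^(t-6) afterwards
  expect_equal(x[6:Tn], 2 * 0.9^(0:(Tn - 6)))
})

test_that("weight noise perturbs the recurrent matrix once, reproducibly", {
  fx <- fixture_network(n_rec = 4, seed = 95)
  fx$weights$W_in_raw <- abs(fx$weights$W_in_raw) # keep units above threshold
  task <- short_pd()
  b <- assemble_batch(task, 1, seed = 96)
  spec0 <- fx$spec; spec0$sigma_rec <- 0
  s1 <- with_seed(97, rnn_simulate(fx$weights, fx$masks, spec0, b$inputs,
                                   pert = perturbation("weight_noise", magnitude = 0.5)))
  s2 <- with_seed(97, rnn_simulate(fx$weights, fx$masks, spec0, b$inputs,
                                   pert = perturbation("weight_noise", magnitude = 0.5)))
  base <- rnn_simulate(fx$weights, fx$masks, spec0, b$inputs)
  expect_identical(s1$outputs, s2$outputs)
  expect_false(isTRUE(all.equal(s1$outputs, base$outputs)))
})

test_that("psychometric curves of a trained network are sigmoid in signed coherence", {
  fit <- trained_pd_fit()
  psy <- psychometric(fit, coherences = c(0.15, 0.4, 0.7),
                      trials_per_coherence = 80, seed = 98)
  expect_s3_class(psy, "psychometric_fit")
  fr <- psy$data$frac_choice1
  expect_gt(fr[length(fr)], 0.85) # strong positive coherence -> choice 1
  expect_lt(fr[1], 0.15)          # strong negative coherence -> choice 2
  expect_gt(psy$k, 0)
  expect_lt(abs(psy$c0), 0.15)    # unbiased task generator
  expect_true(psy$lapse >= 0 && psy$lapse <= 0.5)
  # fitted logistic is monotone for k > 0 and bounded by the lapse rate
  expect_true(all(diff(psy$fitted) >= 0))
  expect_true(all(psy$fitted >= psy$lapse - 1e-12 &
                    psy$fitted <= 1 - psy$lapse + 1e-12))
})

test_that("trial-averaged traces equal a scripted groupby mean", {
  set.seed(99)
  states <- array(rnorm(10 * 4 * 3), c(10, 4, 3))
  coh <- rep(c(0.1, 0.5), each = 5)
  correct <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)
  avg <- trial_averaged_states(states, coh, correct)
  expect_equal(dim(avg), c(2, 4, 3))
  for (i in 1:2) {
    sel <- which(coh == c(0.1, 0.5)[i] & correct)
    manual <- apply(states[sel, , , drop = FALSE], c(2, 3), mean)
    expect_equal(matrix(avg[i, , ], 4, 3), manual)
  }
  # single correct trial: the average is that trial
  avg1 <- trial_averaged_states(states[1:2, , , drop = FALSE], c(0.2, 0.2),
                                c(TRUE, FALSE))
  expect_equal(matrix(avg1[1, , ], 4, 3), matrix(states[1, , ], 4, 3))
  expect_error(trial_averaged_states(states, coh, rep(FALSE, 10)), "no correct")
})

test_that("state PCA matches an independent covariance eigendecomposition", {
  set.seed(101)
  avg <- array(rnorm(3 * 20 * 6), c(3, 20, 6))
  pca <- state_pca(avg)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_equal(sum(pca$var_explained), 1)
  # oracle: eigendecomposition of the covariance of the concatenated matrix
  mat <- do.call(rbind, lapply(1:3, function(i) matrix(avg[i, , ], 20, 6)))
  cent <- scale(mat, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(cent))
  expect_equal(pca$var_explained, eig$values / sum(eig$values), tolerance = 1e-8)
  for (j in 1:2) {
    proj_oracle <- cent %*% eig$vectors[, j]
    expect_lt(min(max(abs(pca$projections[[j]] - proj_oracle)),
                  max(abs(pca$projections[[j]] + proj_oracle))), 1e-8)
  }
  # perfectly collinear data loads entirely on the first component
  line <- outer(seq_len(10), c(1, 2, -1))
  avg_line <- array(0, c(1, 10, 3)); avg_line[1, , ] <- line
  pca_line <- state_pca(avg_line)
  expect_equal(pca_line$var_explained[1], 1)
  expect_error(state_pca(array(0, c(2, 5, 3))), "rank-0")
})

test_that("end-to-end analysis on a trained network recovers coherence structure", {
  fit <- trained_pd_fit()
  sim <- simulate(fit, nsim = 60, seed = 103)
  coh <- vapply(sim$batch$params, `[[`, 0, "coherence")
  correct <- vapply(seq_len(60), function(i) {
    ch <- which.max(colMeans(sim$outputs[i, fit$task$epoch_idx$response, ]))
    ch == sim$batch$params[[i]]$direction + 1
  }, logical(1))
  expect_gt(mean(correct), 0.7)
  avg <- trial_averaged_states(sim$states, coh, correct)
  expect_equal(dim(avg)[1], 3)
  pca <- state_pca(avg)
  expect_gt(sum(pca$var_explained[1:2]), 0.5)
})
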