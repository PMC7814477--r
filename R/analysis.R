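# Behavioural and state-space analyses of trained networks: psychometric
# curves, correct-trial averaged traces, and PCA of the averaged activity.

logistic_lapse <- function(c, k, c0, lapse) {
  lapse + (1 - 2 * lapse) / (1 + exp(-k * (c - c0)))
}

#' Psychometric curve of a trained network
#'
#' Simulates the network at a range of signed coherences (positive values
#' reward choice 1, negative values reward choice 2), computes the fraction
#' of trials on which it chose channel 1, and fits a logistic psychometric
#' function with a lapse rate by bounded least squares:
#' \deqn{p(\mathrm{choice\ 1} \mid c) = \lambda + (1 - 2\lambda) /
#'   (1 + e^{-k (c - c_0)}).}
#'
#' @param object a fitted [cogrnn()] object trained on
#'   [perceptual_discrimination()].
#' @param coherences unsigned coherence levels; the curve is measured at
#'   \code{c(-rev(levels), levels)}.
#' @param trials_per_coherence trials simulated per signed level.
#' @param seed integer seed.
#' @return An object of class \code{"psychometric_fit"}: list with
#'   \code{data} (data frame \code{signed_coherence}, \code{n_trials},
#'   \code{frac_choice1}), fitted \code{k}, \code{c0}, \code{lapse}, and
#'   \code{fitted} values at the measured levels.
#' @export
psychometric <- function(object, coherences = c(0.1, 0.3, 0.5, 0.7),
                         trials_per_coherence = 100L, seed = 1L) {
  stopifnot(inherits(object, "cogrnn"), inherits(object$task, "pd_task"))
  if (trials_per_coherence < 1) stop("'trials_per_coherence' must be >= 1")
  levels <- sort(unique(c(-coherences, coherences)))
  frac <- vapply(seq_along(levels), function(i) {
    sc <- levels[i]
    dirs <- if (sc > 0) 0L else if (sc < 0) 1L else 0:1
    stage <- vary_task(object$task, coherences = abs(sc), directions = dirs)
    sim <- simulate(object, nsim = trials_per_coherence,
                    seed = derive_seed(seed, "psy", i), task = stage)
    resp <- stage$epoch_idx$response
    choices <- vapply(seq_len(trials_per_coherence), function(b) {
      response_choice(matrix(sim$outputs[b, , ], stage$T, stage$n_out), resp)
    }, integer(1))
    mean(choices == 1L)
  }, 0)
  dat <- data.frame(signed_coherence = levels,
                    n_trials = trials_per_coherence, frac_choice1 = frac)
  sse <- function(p) sum((logistic_lapse(levels, p[1], p[2], p[3]) - frac)^2)
  starts <- expand.grid(k = c(2, 5, 10, 20), c0 = 0, lapse = c(0.01, 0.1))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(as.numeric(starts[i, ]), sse, method = "L-BFGS-B",
                 lower = c(-100, -1, 0), upper = c(100, 1, 0.5))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  structure(list(data = dat, k = best$par[1], c0 = best$par[2],
                 lapse = best$par[3], sse = best$value,
                 fitted = logistic_lapse(levels, best$par[1], best$par[2],
                                         best$par[3])),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Psychometric fit: slope k = %.2f, bias c0 = %.4f, lapse = %.3f\n",
              x$k, x$c0, x$lapse))
  print(x$data, row.names = FALSE)
  invisible(x)
}

#' @export
plot.psychometric_fit <- function(x, ...) {
  graphics::plot(x$data$signed_coherence, x$data$frac_choice1, ylim = c(0, 1),
                 xlab = "signed coherence", ylab = "fraction choice 1", ...)
  cs <- seq(min(x$data$signed_coherence), max(x$data$signed_coherence),
            length.out = 200)
  graphics::lines(cs, logistic_lapse(cs, x$k, x$c0, x$lapse))
  invisible(x)
}

#' Correct-trial averaged state traces by coherence
#'
#' Averages unit state trajectories over correct trials, separately per
#' coherence level.
#'
#' @param states \code{B x T x n_rec} array of state trajectories.
#' @param coherence length-\code{B} vector of trial coherences.
#' @param correct length-\code{B} logical vector of per-trial correctness
#'   (from the task's accuracy rule).
#' @return Array \code{(n_coherences, T, n_rec)}; coherence levels (sorted)
#'   in the dimnames of the first margin.
#' @export
trial_averaged_states <- function(states, coherence, correct) {
  stopifnot(length(dim(states)) == 3L, dim(states)[1] == length(coherence),
            length(coherence) == length(correct))
  levels <- sort(unique(coherence))
  out <- array(0, c(length(levels), dim(states)[2], dim(states)[3]),
               dimnames = list(levels, NULL, NULL))
  for (i in seq_along(levels)) {
    sel <- which(coherence == levels[i] & correct)
    if (!length(sel))
      stop(sprintf("no correct trials at coherence %g", levels[i]))
    out[i, , ] <- apply(states[sel, , , drop = FALSE], c(2, 3), mean)
  }
  out
}

#' PCA of trial-averaged population activity
#'
#' Concatenates the per-coherence averaged traces along time into a
#' \code{(n_coherences * T) x n_rec} matrix, centres each unit's column and
#' extracts principal axes by singular value decomposition.
#'
#' @param avg_traces array from [trial_averaged_states()].
#' @return List with \code{components} (\code{n_rec x n_components} loading
#'   matrix), \code{var_explained} (non-increasing fractions summing to 1)
#'   and \code{projections} (scores on the top two components, with the
#'   coherence block of each row in column \code{block}).
#' @export
state_pca <- function(avg_traces) {
  stopifnot(length(dim(avg_traces)) == 3L)
  n_coh <- dim(avg_traces)[1]; Tn <- dim(avg_traces)[2]
  mat <- do.call(rbind, lapply(seq_len(n_coh), function(i)
    matrix(avg_traces[i, , ], Tn, dim(avg_traces)[3])))
  if (all(mat == 0)) stop("rank-0 input: all traces are identically zero")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(components = pc$rotation, var_explained = ve,
       projections = cbind(as.data.frame(pc$x[, 1:min(2, ncol(pc$x)), drop = FALSE]),
                           block = rep(seq_len(n_coh), each = Tn)))
}
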