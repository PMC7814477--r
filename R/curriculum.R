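#' Curriculum (task shaping) specification
#'
#' An ordered list of task stages with per-stage performance thresholds.
#' During training the performance metric (task accuracy by default) is
#' evaluated on the current stage's task at every evaluation checkpoint;
#' when it reaches the stage's threshold the next stage becomes the training
#' task. Reaching the final stage's threshold stops training.
#'
#' @param stages nonempty list of task objects, in training order.
#' @param thresholds numeric vector of per-stage thresholds in \code{[0,1]},
#'   recycled to one per stage (default 0.9).
#' @param metric optional function \code{(outputs, batch, task) -> numeric}
#'   replacing task accuracy as the advancement measure.
#' @return An object of class \code{"curriculum"}.
#' @export
curriculum <- function(stages, thresholds = 0.9, metric = NULL) {
  if (!is.list(stages) || !length(stages)) stop("'stages' must be a nonempty list of tasks")
  if (!all(vapply(stages, inherits, logical(1), "cogtask")))
    stop("every stage must be a task object")
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must lie in [0,1]")
  thresholds <- rep_len(thresholds, length(stages))
  if (!is.null(metric)) stopifnot(is.function(metric))
  structure(list(stages = stages, thresholds = thresholds, metric = metric),
            class = "curriculum")
}

#' @export
print.curriculum <- function(x, ...) {
  cat(sprintf("Curriculum with %d stage(s):\n", length(x$stages)))
  for (i in seq_along(x$stages))
    cat(sprintf("  %d. <%s> threshold %.2f\n", i, class(x$stages[[i]])[1], x$thresholds[i]))
  invisible(x)
}

#' Fresh curriculum state
#'
#' @return List with \code{stage_index} (1-based), \code{advancement_iterations}
#'   and \code{complete}.
#' @export
curriculum_state <- function() {
  list(stage_index = 1L, advancement_iterations = integer(0), complete = FALSE)
}

#' Should the curriculum advance?
#'
#' TRUE when the metric has reached (\code{>=}) the current stage's
#' threshold.
#'
#' @param state a curriculum state.
#' @param metric_value current performance measure.
#' @param spec a [curriculum()].
#' @export
should_advance <- function(state, metric_value, spec) {
  if (state$complete) stop("curriculum already complete")
  metric_value >= spec$thresholds[state$stage_index]
}

#' Advance the curriculum one stage
#'
#' Records the iteration at which the advancement fired; advancing past the
#' last stage marks the curriculum complete.
#'
#' @param state a curriculum state.
#' @param spec a [curriculum()].
#' @param iteration training iteration at which the threshold was reached.
#' @export
advance <- function(state, spec, iteration) {
  if (state$complete) stop("cannot advance a complete curriculum")
  state$advancement_iterations <- c(state$advancement_iterations, as.integer(iteration))
  state$stage_index <- state$stage_index + 1L
  if (state$stage_index > length(spec$stages)) {
    state$complete <- TRUE
    state$stage_index <- length(spec$stages)
  }
  state
}

#' Default curriculum metric: task accuracy
#'
#' @param outputs network outputs on an evaluation batch.
#' @param batch the evaluation batch.
#' @param task the current stage's task.
#' @export
default_metric <- function(outputs, batch, task) accuracy(task, outputs, batch)

#' Paired comparison of curriculum versus fixed-difficulty training
#'
#' Runs the task-shaping experiment: \code{n_pairs} networks are randomly
#' initialised, and each is trained twice from the identical initial weights
#' — once with a coherence-decreasing curriculum and once directly at the
#' final (hardest) coherence — until it reaches the accuracy criterion at
#' the final coherence. Iterations-to-criterion are compared with a
#' one-sided paired Wilcoxon signed-rank test (alternative: the curriculum
#' arm reaches criterion in fewer iterations).
#'
#' @param n_pairs number of paired initialisations.
#' @param coherences curriculum stages, decreasing difficulty last (the last
#'   entry defines the criterion task for both arms).
#' @param threshold per-stage accuracy threshold (and criterion).
#' @param spec a [network_spec()] for both arms.
#' @param base_task template [perceptual_discrimination()] task.
#' @param control a [train_config()]; its \code{n_iterations} caps each run
#'   (runs that never reach criterion are scored at the cap) and its
#'   \code{master_seed} seeds the whole experiment.
#' @return List with \code{results} (data frame: \code{pair},
#'   \code{iterations_curriculum}, \code{iterations_control}),
#'   \code{p_value}, and the two fitted model lists (\code{fits_curriculum},
#'   \code{fits_control}).
#' @export
curriculum_comparison <- function(n_pairs = 10, coherences = c(0.7, 0.5, 0.3, 0.1),
                                  threshold = 0.9, spec = NULL,
                                  base_task = perceptual_discrimination(),
                                  control = train_config(n_iterations = 2000L,
                                                         eval_every = 5L,
                                                         eval_batch = 256L)) {
  if (is.null(spec))
    spec <- network_spec(base_task$n_in, base_task$n_out, n_rec = 40L)
  cur_full <- make_coherence_curriculum(coherences, threshold, base_task)
  cur_fixed <- make_coherence_curriculum(coherences[length(coherences)],
                                         threshold, base_task)
  seed0 <- control$master_seed
  one_arm <- function(curr, init, run_seed) {
    ctrl <- control; ctrl$master_seed <- run_seed
    fit <- suppressWarnings(cogrnn(curriculum = curr, spec = spec,
                                   control = ctrl, init = init))
    list(fit = fit,
         iters = if (fit$curriculum_state$complete) fit$stopped_at
         else control$n_iterations)
  }
  fits_c <- vector("list", n_pairs); fits_f <- vector("list", n_pairs)
  it_c <- it_f <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    # arms share the initialisation only; training and evaluation streams
    # are independent so near-threshold crossings cannot synchronise
    init <- with_seed(derive_seed(seed0, "pair_init", i), default_initializer(spec))
    a <- one_arm(cur_full, init, derive_seed(seed0, "pair_run_cur", i))
    b <- one_arm(cur_fixed, init, derive_seed(seed0, "pair_run_fix", i))
    fits_c[[i]] <- a$fit; fits_f[[i]] <- b$fit
    it_c[i] <- a$iters; it_f[i] <- b$iters
  }
  p <- suppressWarnings(stats::wilcox.test(it_c, it_f, paired = TRUE,
                                           alternative = "less")$p.value)
  list(results = data.frame(pair = seq_len(n_pairs),
                            iterations_curriculum = it_c,
                            iterations_control = it_f),
       p_value = p, fits_curriculum = fits_c, fits_control = fits_f)
}

#' Coherence-decreasing perceptual-discrimination curriculum
#'
#' One perceptual-discrimination stage per coherence level (each stage
#' trains at a single coherence), with a uniform advancement threshold —
#' e.g. \code{c(0.7, 0.5, 0.3, 0.1)} trains at progressively weaker
#' evidence as performance improves, and training stops when the threshold
#' is reached at the final (hardest) coherence.
#'
#' @param coherences coherence levels in decreasing-difficulty order.
#' @param threshold accuracy threshold for every stage.
#' @param base_task template [perceptual_discrimination()] task supplying
#'   all other parameters.
#' @return A [curriculum()].
#' @export
make_coherence_curriculum <- function(coherences, threshold = 0.9,
                                      base_task = perceptual_discrimination()) {
  if (!length(coherences)) stop("'coherences' must be nonempty")
  if (any(coherences < 0 | coherences > 1)) stop("coherences must lie in [0,1]")
  stopifnot(inherits(base_task, "pd_task"))
  stages <- lapply(coherences, function(co) vary_task(base_task, coherences = co))
  curriculum(stages, thresholds = threshold)
}
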