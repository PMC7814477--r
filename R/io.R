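# Persistence and run configuration: lossless JSON weight archives, CSV
# training traces, and flat YAML/JSON run configs with documented defaults.

WEIGHTS_FORMAT_VERSION <- 1L

#' Save network weights, masks and spec to a JSON archive
#'
#' Arrays are written at 17 significant digits, so a save/load round trip is
#' bit-exact. A format version tag is embedded and checked on load.
#'
#' @param weights,masks,spec the network to persist.
#' @param path output file path (conventionally \code{.json}).
#' @export
save_weights <- function(weights, masks, spec, path) {
  check_shapes(weights, masks, spec)
  enc <- function(x) {
    if (is.null(x)) NULL
    else if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else list(dim = length(x), data = as.numeric(x))
  }
  obj <- list(format = "cogrnn-weights", version = WEIGHTS_FORMAT_VERSION,
              spec = unclass(spec),
              weights = lapply(unclass(weights), enc),
              masks = lapply(unclass(masks), enc))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Load a weight archive written by [save_weights()]
#'
#' @param path archive path.
#' @return List with \code{weights}, \code{masks} and \code{spec}.
#' @export
load_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cogrnn-weights"))
    stop("not a cogrnn weight archive")
  if (obj$version != WEIGHTS_FORMAT_VERSION)
    stop(sprintf("weight archive version %s not supported (expected %d)",
                 obj$version, WEIGHTS_FORMAT_VERSION))
  dec <- function(e) {
    if (is.null(e) || (is.list(e) && !length(e))) return(NULL)
    if (prod(e$dim) != length(e$data))
      stop("corrupt weight archive: array data does not match its declared shape")
    if (length(e$dim) == 2L) matrix(e$data, e$dim[1], e$dim[2]) else as.numeric(e$data)
  }
  sp <- obj$spec
  spec <- network_spec(n_in = sp$n_in, n_out = sp$n_out, n_rec = sp$n_rec,
                       dt = sp$dt, tau = sp$tau, sigma_rec = sp$sigma_rec,
                       transfer = sp$transfer, dales_ratio = sp$dales_ratio)
  weights <- structure(lapply(obj$weights, dec), class = "weight_set")
  masks <- structure(lapply(obj$masks, dec), class = "mask_set")
  check_shapes(weights, masks, spec) # detects shape corruption
  list(weights = weights, masks = masks, spec = spec)
}

#' Write a training trace to CSV
#'
#' @param fit a fitted [cogrnn()] object (or its \code{trace} data frame).
#' @param path output CSV path.
#' @export
save_trace <- function(fit, path) {
  tr <- if (inherits(fit, "cogrnn")) fit$trace else fit
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

TASK_CONSTRUCTORS <- c(perceptual_discrimination = "perceptual_discrimination",
                       delayed_discrimination = "delayed_discrimination",
                       delayed_match_to_category = "delayed_match_to_category")

build_task_from_config <- function(section) {
  name <- section$name
  if (is.null(name) || !name %in% names(TASK_CONSTRUCTORS))
    stop(sprintf("unknown task name '%s' (task.name must be one of: %s)",
                 name %||% "<missing>", paste(names(TASK_CONSTRUCTORS), collapse = ", ")))
  ctor <- get(TASK_CONSTRUCTORS[[name]], mode = "function")
  args <- section[setdiff(names(section), "name")]
  known <- names(formals(ctor))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop(sprintf("unknown key(s) in task section: %s",
                 paste0("task.", unknown, collapse = ", ")))
  if (!is.null(args$freq_pairs)) args$freq_pairs <- do.call(rbind, args$freq_pairs)
  do.call(ctor, args)
}

keep_known <- function(section, fn, prefix) {
  unknown <- setdiff(names(section), names(formals(fn)))
  if (length(unknown))
    stop(sprintf("unknown key(s) in %s section: %s", prefix,
                 paste0(prefix, ".", unknown, collapse = ", ")))
  section
}

#' Load and resolve a run configuration
#'
#' Reads a flat YAML or JSON document with sections \code{task} (a task
#' \code{name} plus constructor arguments), \code{network}
#' ([network_spec()] keys, widths defaulting to the task's), \code{training}
#' ([train_config()] and [loss_spec()] keys) and optionally
#' \code{curriculum} (\code{coherences} + \code{threshold} for a
#' [make_coherence_curriculum()]). Unset keys fall back to the documented
#' defaults; unknown keys and inconsistent widths are errors naming the
#' offending key. The fully resolved configuration is stored in the result
#' (field \code{resolved}) and echoed to \code{output_dir} when one is set.
#'
#' @param path configuration file (\code{.yaml}/\code{.yml}/\code{.json}).
#' @return An object of class \code{"run_config"} with the constructed
#'   \code{task}, \code{spec}, \code{loss}, \code{control},
#'   \code{curriculum}, \code{output_dir} and \code{resolved}.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known_sections <- c("task", "network", "training", "curriculum",
                      "output_dir", "master_seed")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown))
    stop(sprintf("unknown config section(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(raw$task)) stop("config must have a 'task' section")
  task <- build_task_from_config(raw$task)

  net <- raw$network %||% list()
  net <- keep_known(net, network_spec, "network")
  if (!is.null(net$n_in) && net$n_in != task$n_in)
    stop(sprintf("network.n_in (%d) conflicts with the task's n_in (%d)",
                 net$n_in, task$n_in))
  if (!is.null(net$n_out) && net$n_out != task$n_out)
    stop(sprintf("network.n_out (%d) conflicts with the task's n_out (%d)",
                 net$n_out, task$n_out))
  net$n_in <- task$n_in; net$n_out <- task$n_out
  spec <- do.call(network_spec, net)

  tr <- raw$training %||% list()
  loss_keys <- intersect(names(tr), names(formals(loss_spec)))
  loss <- do.call(loss_spec, tr[loss_keys])
  ctrl_args <- tr[setdiff(names(tr), loss_keys)]
  ctrl_args <- keep_known(ctrl_args, train_config, "training")
  if (!is.null(raw$master_seed)) ctrl_args$master_seed <- raw$master_seed
  control <- do.call(train_config, ctrl_args)

  curr <- NULL
  if (!is.null(raw$curriculum)) {
    cu <- raw$curriculum
    unknown <- setdiff(names(cu), c("coherences", "threshold"))
    if (length(unknown))
      stop(sprintf("unknown key(s) in curriculum section: %s",
                   paste0("curriculum.", unknown, collapse = ", ")))
    if (!inherits(task, "pd_task"))
      stop("the built-in coherence curriculum requires a perceptual_discrimination task")
    curr <- make_coherence_curriculum(cu$coherences, cu$threshold %||% 0.9,
                                      base_task = task)
  }
  resolved <- list(task = c(list(name = raw$task$name), task$args),
                   network = unclass(spec)[names(formals(network_spec))[
                     names(formals(network_spec)) %in% names(unclass(spec))]],
                   training = c(unclass(control), unclass(loss)),
                   curriculum = raw$curriculum,
                   output_dir = raw$output_dir,
                   master_seed = control$master_seed)
  resolved <- drop_nulls(resolved)
  cfg <- structure(list(task = task, spec = spec, loss = loss, control = control,
                        curriculum = curr, output_dir = raw$output_dir,
                        resolved = resolved),
                   class = "run_config")
  if (!is.null(raw$output_dir)) {
    dir.create(raw$output_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(resolved, file.path(raw$output_dir, "resolved_config.yaml"))
  }
  cfg
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

#' Execute a run configuration
#'
#' Trains the configured network and, when an \code{output_dir} is set,
#' writes the weight archive (\code{weights.json}) and training trace
#' (\code{trace.csv}) there.
#'
#' @param cfg a [load_config()] result or a path to a config file.
#' @return The fitted [cogrnn()] object, invisibly.
#' @export
run_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  fit <- cogrnn(cfg$task, spec = cfg$spec, loss = cfg$loss,
                control = cfg$control, curriculum = cfg$curriculum)
  if (!is.null(cfg$output_dir)) {
    save_weights(fit$weights, fit$masks, fit$spec,
                 file.path(cfg$output_dir, "weights.json"))
    save_trace(fit, file.path(cfg$output_dir, "trace.csv"))
  }
  invisible(fit)
}

#' Tiny deterministic fixture network
#'
#' A fully deterministic miniature network (default 4 recurrent units, 2
#' inputs, 2 outputs) regenerable bit-identically from its seed; used for
#' round-trip and regression testing.
#'
#' @param n_rec number of recurrent units (at most a handful).
#' @param seed integer seed.
#' @param dales_ratio optional Dale ratio for the fixture spec.
#' @return List with \code{weights}, \code{masks} and \code{spec}.
#' @export
fixture_network <- function(n_rec = 4L, seed = 42L, dales_ratio = NULL) {
  spec <- network_spec(n_in = 2L, n_out = 2L, n_rec = n_rec, dt = 10, tau = 100,
                       sigma_rec = 0.05, dales_ratio = dales_ratio)
  init <- with_seed(seed, default_initializer(spec))
  c(init, list(spec = spec))
}
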