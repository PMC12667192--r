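# Configuration loading, experiment recipes and result serialization:
# the glue that turns the modules into reproducible experiment runs.

#' Default experiment configuration
#'
#' Fully resolved configuration tree: model overrides, controller
#' parameters and thresholds, cerebellar rates, belt speeds, objective
#' weights and desired duration, optimizer settings, numerical settings.
#'
#' @export
default_config <- function() {
  list(
    model = list(),                     # overrides of default_model_config()
    controller = list(params = as.list(default_spinal_params()),
                      t_left = 0.55, t_right = 0.55),
    cerebellum = list(enabled = TRUE, alpha = 0.002, beta = 0.02,
                      error_metric = "sva"),
    belts = list(left = 1.0, right = 0.5),
    objective = list(weights = unclass(objective_weights()), t_des = 80,
                     ub_mode = "integral"),
    optimizer = list(lambda = 16, sigma = 1, max_gen = 1500,
                     stagnation_window = 500, stagnation_tol = 1e-4,
                     n_runs = 10),
    simulation = list(duration = 80, dt = 2e-4, out_dt = 0.01)
  )
}

known_config_keys <- function(template, prefix = "") {
  out <- character(0)
  for (k in names(template)) {
    key <- paste0(prefix, k)
    out <- c(out, key)
    if (is.list(template[[k]]))
      out <- c(out, known_config_keys(template[[k]], paste0(key, "$")))
  }
  out
}

#' Load and validate a configuration file
#'
#' JSON configuration; missing entries take defaults, unknown keys are an
#' error (listing the offending keys). An empty file yields the full
#' default configuration.
#'
#' @param path path to a JSON config file, or NULL for pure defaults.
#' @param overrides optional list merged on top (same validation).
#' @return validated configuration list with attribute `hash`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (nzchar(trimws(txt)))
      user <- jsonlite::fromJSON(txt, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  }
  user <- utils::modifyList(user, overrides)
  tmpl <- default_config()
  # reject unknown keys at the two top levels
  check_keys <- function(u, t, prefix = "") {
    unknown <- setdiff(names(u), names(t))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste0(prefix, unknown, collapse = ", "))
    for (k in names(u)) {
      if (is.list(u[[k]]) && is.list(t[[k]]) &&
          !(k %in% c("params", "model")))  # free-form subtrees
        check_keys(u[[k]], t[[k]], paste0(prefix, k, "$"))
    }
  }
  check_keys(user, tmpl)
  cfg <- utils::modifyList(tmpl, user)
  w <- unlist(cfg$objective$weights)
  if (any(w < 0)) stop("configuration validation error: negative weight")
  if (cfg$cerebellum$alpha < 0 || cfg$cerebellum$beta < 0)
    stop("configuration validation error: negative cerebellar rate")
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Hash of a configuration
#'
#' Deterministic content hash recorded in every result file, so outputs
#' can be traced to the configuration that produced them.
#'
#' @param cfg configuration list.
#' @export
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 14)
  # small FNV-1a over the serialized text (no external digest dependency)
  h <- 0
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", h)
}

#' Named experiment presets
#'
#' "split-belt-with-cerebellum": 80 s, belts 1.0/0.5, cerebellar rates
#' alpha = 0.002, beta = 0.02. "split-belt-reflex-only": same with the
#' cerebellum disabled. "rate-grid": beta in {0.01, 0.04} crossed with
#' alpha in {0.01, 0.05}. "belt-ramp": staged right-belt slowdown
#' 0.9 -> 0.5. "surrogate": desk-scale stride-map run.
#'
#' @param name preset name.
#' @return configuration list (plus preset-specific fields).
#' @export
recipe_preset <- function(name = c("split-belt-with-cerebellum",
                                   "split-belt-reflex-only",
                                   "rate-grid", "belt-ramp", "surrogate")) {
  name <- match.arg(name)
  cfg <- default_config()
  cfg$preset <- name
  switch(name,
    "split-belt-with-cerebellum" = {
      cfg$cerebellum$enabled <- TRUE
      cfg$n_seeds <- 10
    },
    "split-belt-reflex-only" = {
      cfg$cerebellum$enabled <- FALSE
      cfg$n_seeds <- 10
    },
    "rate-grid" = {
      cfg$cerebellum$enabled <- TRUE
      cfg$grid <- list(alpha = c(0.01, 0.05), beta = c(0.01, 0.04))
      cfg$n_seeds <- 3
    },
    "belt-ramp" = {
      cfg$ramp_speeds <- seq(0.9, 0.5, by = -0.1)
    },
    "surrogate" = {
      cfg$surrogate <- list(n_strides = 200)
    })
  cfg
}

#' Load packaged controller parameters
#'
#' Reads a parameter JSON (named spinal values, thresholds, optional
#' cerebellar rates and optional limit-cycle initial state) such as the
#' packaged coarse-optimized walkers shipped under `extdata`. All
#' packaged parameter files carry the `_synthetic` suffix: they were
#' produced by this package's own reduced optimization protocol, not by
#' any external source.
#'
#' @param which shorthand for a packaged file: "split" (split-belt
#'   walker, 2:1 belts) or "tied" (symmetric tied-belt walker with a
#'   packaged limit-cycle initial state).
#' @param path explicit JSON file path (overrides `which`).
#' @return list with `controller` (a [spinal_controller()]), `rates`
#'   (alpha, beta), and `init`/`phases0`/`elapsed0` when the file
#'   carries an initial state (NULL otherwise).
#' @export
load_params <- function(which = c("split", "tied"), path = NULL) {
  if (is.null(path)) {
    which <- match.arg(which)
    fname <- switch(which,
                    split = "walker_params_synthetic.json",
                    tied = "walker_tied_symmetric_synthetic.json")
    path <- system.file("extdata", fname, package = "gaitadapt")
  }
  if (!nzchar(path) || !file.exists(path))
    stop("parameter file not found")
  pj <- jsonlite::fromJSON(path)
  ctrl <- spinal_controller(unlist(pj$spinal), pj$t_left, pj$t_right)
  out <- list(controller = ctrl,
              rates = list(alpha = pj$alpha %||% 0.002,
                           beta = pj$beta %||% 0.02),
              init = NULL, phases0 = NULL, elapsed0 = NULL)
  if (!is.null(pj$init)) {
    out$init <- list(q = pj$init$q, qd = pj$init$qd, a = pj$init$a,
                     lce = pj$init$lce)
    out$phases0 <- pj$init$phase
    out$elapsed0 <- pj$init$elapsed
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an experiment recipe
#'
#' Executes a preset (or custom) configuration for one seed and writes a
#' results directory: configuration snapshot, per-stride tables,
#' cerebellum log, trajectory summary, objective breakdown and a run
#' log. Simulation recipes use the packaged walker parameters unless the
#' configuration carries its own.
#'
#' @param recipe a [recipe_preset()] name or configuration list.
#' @param seed integer seed.
#' @param out_dir results directory.
#' @param duration optional override of the simulated duration (s).
#' @param quick logical: shrink the surrogate/simulation scale for smoke
#'   tests.
#' @return invisible list of result objects (also written to disk).
#' @export
run_recipe <- function(recipe, seed = 1L, out_dir = tempfile("run_"),
                       duration = NULL, quick = FALSE) {
  cfg <- if (is.character(recipe)) recipe_preset(recipe) else recipe
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = 14)
  log <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log), add = TRUE)
  wl <- function(...) writeLines(paste0(...), log)
  wl("recipe: ", cfg$preset %||% "custom", "  seed: ", seed,
     "  config_hash: ", hash)
  wl("package gaitadapt ",
     as.character(utils::packageVersion("gaitadapt")),
     "  R ", R.version.string)
  results <- list(config_hash = hash)

  if (identical(cfg$preset, "surrogate")) {
    n <- if (quick) 50 else cfg$surrogate$n_strides %||% 200
    run <- simulate_strides(stride_map(),
                            cerebellum_state(cfg$cerebellum$alpha,
                                             cfg$cerebellum$beta),
                            n, seed = seed)
    tab <- run$strides
    tab$config_hash <- hash
    utils::write.csv(tab, file.path(out_dir, "strides.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(run$log, config_hash = hash),
                     file.path(out_dir, "cerebellum_log.csv"),
                     row.names = FALSE)
    results$strides <- run$strides
    results$log <- run$log
    wl("surrogate run: ", nrow(run$strides), " strides")
    return(invisible(results))
  }

  pp <- load_params()
  ctrl <- pp$controller
  cereb <- NULL
  if (isTRUE(cfg$cerebellum$enabled)) {
    cereb <- cerebellum_state(cfg$cerebellum$alpha, cfg$cerebellum$beta,
                              error_metric = cfg$cerebellum$error_metric)
  }
  dur <- duration %||% (if (quick) 10 else cfg$simulation$duration)
  belts <- belt_config(cfg$belts$left, cfg$belts$right)
  tr <- simulate_gait(build_default_model(cfg$model), ctrl, cereb,
                      duration = dur, belts = belts)
  write_trajectory(tr, out_dir, config_hash = hash)
  if (nrow(tr$extra$steps) >= 4) {
    st <- traj_stride_table(tr)
    st$config_hash <- hash
    utils::write.csv(st, file.path(out_dir, "strides.csv"),
                     row.names = FALSE)
    results$strides <- st
  }
  if (!is.null(cereb) && !is.null(tr$extra$cereb_log)) {
    utils::write.csv(cbind(tr$extra$cereb_log, config_hash = hash),
                     file.path(out_dir, "cerebellum_log.csv"),
                     row.names = FALSE)
  }
  br <- suppressWarnings(
    objective_evaluate(tr, do.call(objective_weights,
                                   cfg$objective$weights),
                       t_des = dur, ub_mode = cfg$objective$ub_mode))
  jsonlite::write_json(c(unclass(br), list(config_hash = hash)),
                       file.path(out_dir, "objective.json"),
                       auto_unbox = TRUE, digits = NA)
  results$trajectory <- tr
  results$objective <- br
  wl("simulation: t_end ", tr$t_end, " (", tr$stop_reason, "), ",
     sum(tr$events$type == "HS"), " heel strikes")
  invisible(results)
}

#' Command-line entry point
#'
#' `gaitadapt <command> [--key value ...]` with commands `simulate`,
#' `surrogate`, `rate-grid`, `analyze`. Intended for
#' `Rscript -e 'gaitadapt::run_cli()' <args>`.
#'
#' @param args character vector (default: command line).
#' @return exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: gaitadapt simulate|surrogate|rate-grid|analyze",
        "[--seed N] [--out DIR] [--config FILE] [--alpha A] [--beta B]",
        "[--strides N] [--duration S] [--reflex-only]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list(seed = 1L, out = "results", config = NULL,
              alpha = 0.002, beta = 0.02, strides = 200, duration = NULL,
              reflex_only = FALSE)
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--reflex-only") { opt$reflex_only <- TRUE; i <- i + 1; next }
    key <- sub("^--", "", a)
    key <- gsub("-", "_", key)
    if (!key %in% names(opt)) stop("unknown option: ", a)
    opt[[key]] <- utils::type.convert(args[i + 1], as.is = TRUE)
    i <- i + 2
  }
  switch(cmd,
    surrogate = {
      cfg <- recipe_preset("surrogate")
      cfg$cerebellum$alpha <- opt$alpha
      cfg$cerebellum$beta <- opt$beta
      cfg$surrogate$n_strides <- opt$strides
      run_recipe(cfg, seed = opt$seed, out_dir = opt$out)
    },
    simulate = {
      name <- if (opt$reflex_only) "split-belt-reflex-only"
              else "split-belt-with-cerebellum"
      cfg <- recipe_preset(name)
      if (!is.null(opt$config)) cfg <- utils::modifyList(
        cfg, load_config(opt$config))
      run_recipe(cfg, seed = opt$seed, out_dir = opt$out,
                 duration = opt$duration)
    },
    `rate-grid` = {
      sweep <- rate_sweep(stride_map(), alphas = c(0.01, 0.05),
                          betas = c(0.01, 0.04),
                          n_strides = opt$strides, seed = opt$seed)
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(sweep, file.path(opt$out, "rate_grid.csv"),
                       row.names = FALSE)
    },
    analyze = {
      st <- utils::read.csv(file.path(opt$out, "strides.csv"))
      fit <- fit_exponential(st$sla)
      jsonlite::write_json(
        list(a = fit$a, b = fit$b, c = fit$c, sse = fit$sse),
        file.path(opt$out, "sla_fit.json"), auto_unbox = TRUE, digits = NA)
    },
    stop("unknown command: ", cmd))
  invisible(0L)
}
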