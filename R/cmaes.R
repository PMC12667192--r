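# CMA-ES harness: standard (mu/mu_w, lambda) covariance matrix adaptation
# evolution strategy, the staged belt-speed ramp with warm starts, and
# manual parameter readjustment between stages.

#' Optimization configuration
#'
#' @param lambda population size (default 16).
#' @param sigma initial step size in the normalized parameter space
#'   (default 1).
#' @param max_gen maximum number of generations (1500 for main runs;
#'   tests use far fewer).
#' @param stagnation_window generations over which fitness improvement is
#'   monitored (default 500).
#' @param stagnation_tol minimum improvement of the window-averaged best
#'   fitness (default 1e-4).
#' @param seed RNG seed for the strategy.
#' @param scale per-parameter scale: the strategy operates on
#'   `x / scale`, so `sigma = 1` is meaningful across heterogeneous
#'   parameters. Scalar or vector.
#' @param lower,upper optional box bounds in original units; candidates
#'   are evaluated clamped with a quadratic out-of-box penalty.
#' @export
optimization_config <- function(lambda = 16L, sigma = 1, max_gen = 1500L,
                                stagnation_window = 500L,
                                stagnation_tol = 1e-4,
                                seed = 1L, scale = 1,
                                lower = -Inf, upper = Inf) {
  stopifnot(lambda >= 2, sigma > 0, max_gen >= 1)
  structure(list(lambda = as.integer(lambda), sigma = sigma,
                 max_gen = as.integer(max_gen),
                 stagnation_window = as.integer(stagnation_window),
                 stagnation_tol = stagnation_tol,
                 seed = as.integer(seed), scale = scale,
                 lower = lower, upper = upper),
            class = "optimization_config")
}

#' Run CMA-ES
#'
#' Minimizes `objective_fn(x)` starting from `x0`. Candidates with
#' non-finite objective values are assigned the worst finite score of
#' their generation (or a large constant) and logged. Terminates at
#' `max_gen` or when the best fitness, averaged over the stagnation
#' window, improves by less than `stagnation_tol`.
#'
#' @param objective_fn function(numeric vector) -> scalar to minimize.
#' @param x0 initial mean in original parameter units.
#' @param config an [optimization_config()].
#' @param verbose print per-generation progress every `verbose`
#'   generations (0 = silent).
#' @return list with `par` (best-ever parameters), `value`, `history`
#'   (data.frame: gen, best, mean, sigma, best_so_far), `n_eval`,
#'   `stop_reason`, `n_nonfinite`.
#' @export
run_cmaes <- function(objective_fn, x0, config = optimization_config(),
                      verbose = 0) {
  n <- length(x0)
  stopifnot(n >= 1)
  scale <- rep_len(config$scale, n)
  lower <- rep_len(config$lower, n) / scale
  upper <- rep_len(config$upper, n) / scale
  lambda <- config$lambda
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- x0 / scale
  sigma <- config$sigma
  C <- diag(n); B <- diag(n); D <- rep(1, n)
  ps <- numeric(n); pc <- numeric(n)
  eigen_ok <- TRUE

  set.seed(config$seed)
  best_val <- Inf; best_par <- m
  hist <- vector("list", config$max_gen)
  n_eval <- 0L; n_nonfinite <- 0L
  stop_reason <- "max_gen"
  par_names <- names(x0)
  eval_z <- function(z) {
    # z in scaled space; clamp into box, quadratic penalty on violation
    zc <- pmin(pmax(z, lower), upper)
    pen <- sum((z - zc)^2)
    x <- zc * scale
    names(x) <- par_names
    v <- objective_fn(x)
    if (!is.finite(v)) return(NA_real_)
    v + pen
  }

  gen <- 0L
  for (gen in seq_len(config$max_gen)) {
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                     # N(0, C) samples
    X <- m + sigma * Y
    vals <- apply(X, 2, eval_z)
    n_eval <- n_eval + lambda
    bad <- !is.finite(vals)
    if (any(bad)) {
      n_nonfinite <- n_nonfinite + sum(bad)
      worst <- if (all(bad)) 1e18 else max(vals[!bad]) + 1
      vals[bad] <- worst
    }
    ord <- order(vals)
    sel <- ord[seq_len(mu)]
    if (vals[ord[1]] < best_val) {
      best_val <- vals[ord[1]]
      best_par <- X[, ord[1]]
    }
    y_w <- drop(Y[, sel, drop = FALSE] %*% w)
    m <- m + sigma * y_w
    # step-size path (C^{-1/2} y = B z)
    z_w <- drop(Z[, sel, drop = FALSE] %*% w)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(B %*% z_w)
    hsig <- as.numeric(
      sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * y_w
    Ysel <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * (Ysel %*% (w * t(Ysel)))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 1e6)
    eg <- eigen(C, symmetric = TRUE)
    if (any(eg$values <= 0) || !all(is.finite(eg$values))) {
      # numerical degeneracy: reset covariance
      C <- diag(n); B <- diag(n); D <- rep(1, n)
    } else {
      B <- eg$vectors; D <- sqrt(eg$values)
    }
    hist[[gen]] <- c(gen = gen, best = vals[ord[1]],
                     mean = mean(vals), sigma = sigma,
                     best_so_far = best_val)
    if (verbose > 0 && gen %% verbose == 0)
      message(sprintf("gen %d: best %.6g (best-ever %.6g) sigma %.3g",
                      gen, vals[ord[1]], best_val, sigma))
    # stagnation: window-averaged per-generation best improved < tol
    win <- config$stagnation_window
    if (gen >= win) {
      h <- vapply(hist[seq_len(gen)], function(r) r[["best_so_far"]],
                  numeric(1))
      recent <- h[seq(gen - win + 1L, gen)]
      if (max(recent) - min(recent) < config$stagnation_tol) {
        stop_reason <- "stagnation"
        break
      }
    }
  }
  hist <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  best_z <- pmin(pmax(best_par, lower), upper)
  best_x <- best_z * scale
  names(best_x) <- par_names
  list(par = best_x, value = best_val,
       history = as.data.frame(hist), n_eval = n_eval,
       stop_reason = stop_reason, n_nonfinite = n_nonfinite)
}

#' Staged belt-speed ramp with warm starts
#'
#' Finds split-belt controller parameters by gradually slowing the right
#' belt from the tied speed to the target in fixed decrements, each stage
#' warm-started from the previous stage's best parameters.
#'
#' @param start_params tied-belt solution used as the first warm start.
#' @param objective_factory function(right_speed) returning the objective
#'   function for that stage (closing over everything else).
#' @param speeds vector of right-belt speeds, e.g. `seq(0.9, 0.5, by = -0.1)`
#'   when the tied speed is 1.0.
#' @param config an [optimization_config()] applied per stage.
#' @param check function(par, right_speed) -> logical: stage acceptance
#'   (a full-duration walker); on failure the protocol halts with a stage
#'   report. Default accepts everything.
#' @param verbose passed to [run_cmaes()].
#' @return list with `stages` (per-stage list of speed, par, value,
#'   warm_start), `par` (final best), `completed`.
#' @export
belt_ramp_protocol <- function(start_params, objective_factory,
                               speeds = seq(0.9, 0.5, by = -0.1),
                               config = optimization_config(),
                               check = NULL, verbose = 0) {
  par <- start_params
  stages <- list()
  for (k in seq_along(speeds)) {
    sp <- speeds[k]
    fn <- objective_factory(sp)
    cfg <- config
    cfg$seed <- config$seed + k  # distinct stream per stage
    res <- run_cmaes(fn, par, cfg, verbose = verbose)
    ok <- if (is.null(check)) TRUE else isTRUE(check(res$par, sp))
    stages[[k]] <- list(speed = sp, par = res$par, value = res$value,
                        warm_start = par, ok = ok)
    if (!ok) {
      return(list(stages = stages, par = res$par, completed = FALSE,
                  failed_speed = sp))
    }
    par <- res$par
  }
  list(stages = stages, par = par, completed = TRUE)
}

#' Manual readjustment of named controller parameters
#'
#' Replaces selected entries of a named parameter vector, leaving all
#' others untouched; used to seed the split-belt initial guess with
#' hand-tuned stance force reflex and hip-flexor length reflex gains.
#'
#' @param params named numeric vector.
#' @param overrides named list/vector of replacement values.
#' @return params with overrides applied; attribute `overridden` lists
#'   the names changed.
#' @export
manual_readjustment <- function(params, overrides) {
  if (length(overrides) == 0) return(params)
  ov <- unlist(overrides)
  unknown <- setdiff(names(ov), names(params))
  if (length(unknown))
    stop("manual_readjustment: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  params[names(ov)] <- ov
  attr(params, "overridden") <- names(ov)
  params
}
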