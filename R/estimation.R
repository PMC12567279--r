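# Weighted least-squares parameter estimation with multi-start Nelder-Mead.
# Parameters are fitted in log space (all are positive scale parameters);
# restarts are drawn log-uniformly within the bounds from the seed.

#' Fit specification
#'
#' @param parameters character vector of compound fields to fit (any of
#'   `"k_absorption"`, `"q_gut"`, `"kp_scalar"`)
#' @param bounds named list of `c(lower, upper)` per parameter
#' @param weighting `"1/obs^2"` (proportional error, default), `"1/obs"`, or
#'   `"uniform"`
#' @param n_restarts number of Nelder-Mead restarts
#' @param seed integer seed for restart draws
#' @param maxit maximum Nelder-Mead iterations per restart
#' @return an object of class `fit_spec`
#' @export
fit_spec <- function(parameters = c("k_absorption", "q_gut", "kp_scalar"),
                     bounds = list(k_absorption = c(0.05, 1),
                                   q_gut = c(1.5, 20),
                                   kp_scalar = c(0.2, 4)),
                     weighting = "1/obs^2", n_restarts = 100, seed = 1,
                     maxit = 500) {
  if (n_restarts < 1) stop_domain("n_restarts must be at least 1")
  weighting <- match.arg(weighting, c("1/obs^2", "1/obs", "uniform"))
  stopifnot(all(parameters %in% names(bounds)))
  if (any(vapply(bounds, function(b) any(b <= 0) || b[2] <= b[1], logical(1))))
    stop_domain("bounds must be positive with upper > lower")
  structure(list(parameters = parameters, bounds = bounds[parameters],
                 weighting = weighting, n_restarts = n_restarts, seed = seed,
                 maxit = maxit), class = "fit_spec")
}

set_compound_params <- function(compound, values) {
  for (nm in names(values)) compound[[nm]] <- values[[nm]]
  compound
}

#' Fit compound parameters to observed concentration-time data
#'
#' Minimizes the weighted residual sum of squares
#' `sum(w_i * (obs_i - pred_i)^2)` (default `w = 1/obs^2`, matching a
#' proportional error model) over the chosen parameters with Nelder-Mead in
#' log-parameter space, restarted from log-uniform draws within the bounds.
#'
#' @param observed data.frame with columns `time_h` and `conc` (ng/mL);
#'   must contain more points than fitted parameters
#' @param compound a [compound_record()] supplying all non-fitted parameters
#' @param physiology a [build_physiology()] snapshot
#' @param regimen a [dose_regimen()] matching the observations
#' @param spec a [fit_spec()]
#' @param settings a [sim_settings()] used for model evaluations during the
#'   fit (the default is tuned for speed)
#' @return object of class `fit_result`: list with `estimates` (named
#'   vector), `objective`, `restarts` (per-restart data.frame), `converged`
#' @export
fit_parameters <- function(observed, compound, physiology, regimen,
                           spec = fit_spec(),
                           settings = fast_settings()) {
  if (nrow(observed) < length(spec$parameters) + 1)
    stop_domain("need at least ", length(spec$parameters) + 1,
                " observations")
  w <- switch(spec$weighting,
              "1/obs^2" = 1 / observed$conc^2,
              "1/obs" = 1 / observed$conc,
              uniform = rep(1, nrow(observed)))

  lb <- log(vapply(spec$bounds, `[`, numeric(1), 1))
  ub <- log(vapply(spec$bounds, `[`, numeric(1), 2))

  objective <- function(log_theta) {
    # box constraint: evaluate at the clamped point with a quadratic
    # penalty, so flat directions cannot drift outside the bounds
    clamped <- pmin(pmax(log_theta, lb), ub)
    penalty <- 1e4 * sum((log_theta - clamped)^2)
    theta <- exp(clamped)
    names(theta) <- spec$parameters
    cmp <- set_compound_params(compound, theta)
    pred <- tryCatch({
      prof <- simulate_individual(cmp, physiology, regimen, settings)
      stats::approx(prof$time, prof$maternal_plasma,
                    xout = observed$time_h)$y
    }, error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) return(1e12)
    sum(w * (observed$conc - pred)^2) + penalty
  }
  set.seed(spec$seed)
  starts <- vapply(seq_along(lb), function(j)
    stats::runif(spec$n_restarts, lb[j], ub[j]), numeric(spec$n_restarts))
  if (spec$n_restarts == 1) starts <- matrix(starts, nrow = 1)

  restarts <- vector("list", spec$n_restarts)
  for (i in seq_len(spec$n_restarts)) {
    fit <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                        control = list(maxit = spec$maxit,
                                       reltol = 1e-10))
    par_in <- exp(pmin(pmax(fit$par, lb), ub))
    restarts[[i]] <- data.frame(
      restart = i, objective = fit$value, converged = fit$convergence == 0,
      t(stats::setNames(par_in, spec$parameters)))
  }
  restarts <- do.call(rbind, restarts)
  if (!any(restarts$objective < 1e12))
    stop("all restarts failed; see the restart trace", call. = FALSE)
  best <- restarts[which.min(restarts$objective), ]
  structure(list(
    estimates = stats::setNames(as.numeric(best[spec$parameters]),
                                spec$parameters),
    objective = best$objective,
    restarts = restarts,
    converged = best$converged
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective", signif(x$objective, 4), "over",
      nrow(x$restarts), "restarts\n")
  print(signif(x$estimates, 4))
  invisible(x)
}
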