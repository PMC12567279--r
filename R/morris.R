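# Morris elementary-effects global sensitivity screening (one-at-a-time
# trajectories on a p-level grid). Implemented here directly: mu* (mean
# absolute elementary effect) ranks parameter influence; sigma flags
# interaction/nonlinearity.

#' Morris elementary-effects screening
#'
#' Runs `r` randomized one-at-a-time trajectories over a `levels`-point grid
#' in the unit hypercube, maps points into the given parameter ranges, and
#' summarizes each output by the mean absolute elementary effect (mu*) and
#' the standard deviation of elementary effects (sigma).
#'
#' @param model function taking a named parameter vector and returning a
#'   named numeric vector of outputs (e.g. Cmax and AUC)
#' @param ranges named list of `c(lower, upper)` parameter ranges
#' @param r number of trajectories (>= 4)
#' @param levels number of grid levels (even; default 4)
#' @param seed integer seed for trajectory generation
#' @return object of class `morris_result`: list of per-output data.frames
#'   (`parameter`, `mu_star`, `sigma`, `rank`) plus `n_failed`
#' @export
morris_screening <- function(model, ranges, r = 20, levels = 4, seed = 1) {
  if (r < 4) stop_domain("at least 4 trajectories required")
  if (any(vapply(ranges, function(z) diff(z) <= 0, logical(1))))
    stop_domain("all parameter ranges must have positive width")
  k <- length(ranges)
  pnames <- names(ranges)
  delta <- levels / (2 * (levels - 1))
  base_levels <- seq(0, 1 - delta, length.out = levels / 2)

  lower <- vapply(ranges, `[`, numeric(1), 1)
  width <- vapply(ranges, function(z) diff(z), numeric(1))
  eval_model <- function(x01) {
    x <- lower + width * x01
    names(x) <- pnames
    tryCatch(model(x), error = function(e) NULL)
  }

  set.seed(seed)
  ee <- list()     # per output: k x r matrix
  n_failed <- 0
  for (traj in seq_len(r)) {
    x <- base_levels[sample.int(length(base_levels), k, replace = TRUE)]
    dir <- sample(c(-1, 1), k, replace = TRUE)
    # shift so every step stays inside [0, 1]
    x <- ifelse(dir > 0, x, x + delta)
    order_idx <- sample.int(k)
    y_prev <- eval_model(x)
    for (i in order_idx) {
      x_new <- x
      x_new[i] <- x[i] + dir[i] * delta
      y_new <- eval_model(x_new)
      if (is.null(y_prev) || is.null(y_new)) {
        n_failed <- n_failed + 1
      } else {
        e <- (y_new - y_prev) / (dir[i] * delta)
        for (out in names(e)) {
          if (is.null(ee[[out]]))
            ee[[out]] <- matrix(NA_real_, nrow = k, ncol = r,
                                dimnames = list(pnames, NULL))
          ee[[out]][i, traj] <- e[[out]]
        }
      }
      x <- x_new
      y_prev <- y_new
    }
  }
  if (n_failed > 0)
    warning(n_failed, " model evaluations failed and were excluded")

  res <- lapply(ee, function(m) {
    mu_star <- apply(m, 1, function(z) mean(abs(z), na.rm = TRUE))
    sigma <- apply(m, 1, stats::sd, na.rm = TRUE)
    df <- data.frame(parameter = pnames, mu_star = mu_star, sigma = sigma)
    df$rank <- rank(-df$mu_star, ties.method = "min")
    df[order(df$rank), ]
  })
  structure(list(outputs = res, n_failed = n_failed, r = r, levels = levels),
            class = "morris_result")
}

#' Top-ranked parameters for one Morris output
#' @param result a `morris_result`
#' @param output output name (e.g. `"c_max"`)
#' @param n how many parameters
#' @return character vector of parameter names, highest mu* first
#' @export
morris_top <- function(result, output, n = 3) {
  df <- result$outputs[[output]]
  if (is.null(df)) stop_domain("unknown Morris output: ", output)
  utils::head(df$parameter, n)
}

#' @export
print.morris_result <- function(x, ...) {
  cat("<morris_result>", x$r, "trajectories,", x$levels, "levels\n")
  for (out in names(x$outputs)) {
    df <- x$outputs[[out]]
    cat("  ", out, ": ",
        paste(utils::head(df$parameter, 3), collapse = " > "),
        " (mu* ", paste(signif(utils::head(df$mu_star, 3), 3),
                        collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Default nine-parameter Morris setup for the nonpregnant escitalopram model
#'
#' The nine screened drug parameters are the absorption inputs (`f_a`, `k_a`,
#' `fu_gut`, `q_gut`), the distribution scalar (`kp_scalar`), and the
#' elimination inputs (three per-isoform CLints and renal clearance), each
#' over a +/-50% range around its default. The model output is single-dose
#' Cmax and AUC(0-inf) for a 20 mg oral dose at gestational week 0.
#'
#' @param compound a [compound_record()]; defaults to escitalopram
#' @param dose single dose, mg
#' @param settings a [sim_settings()]; the default uses a coarser solver
#'   tolerance suited to screening
#' @return list with elements `model` and `ranges` for [morris_screening()]
#' @export
morris_setup_nonpregnant <- function(compound = load_compound(), dose = 20,
                                     settings = fast_settings()) {
  phys <- build_physiology(0)
  defaults <- c(f_absorbed = compound$f_absorbed,
                k_absorption = compound$k_absorption,
                fu_gut = compound$fu_gut,
                q_gut = compound$q_gut,
                kp_scalar = compound$kp_scalar,
                cl_renal_adult = compound$cl_renal_adult,
                clint_cyp2c19 = compound$clint_by_isoform[["CYP2C19"]],
                clint_cyp2d6 = compound$clint_by_isoform[["CYP2D6"]],
                clint_cyp3a4 = compound$clint_by_isoform[["CYP3A4"]])
  ranges <- lapply(defaults, function(v) c(0.5 * v, 1.5 * v))
  # fractions cannot exceed 1
  ranges$f_absorbed[2] <- min(ranges$f_absorbed[2], 1)
  ranges$fu_gut[2] <- min(ranges$fu_gut[2], 1)
  regimen <- dose_regimen(dose, n_doses = 1)
  # simulate well past absorption; extrapolate the terminal tail for AUCinf
  settings$horizon_extra <- 216

  model <- function(x) {
    cmp <- compound
    cmp$f_absorbed <- min(x[["f_absorbed"]], 1)
    cmp$k_absorption <- x[["k_absorption"]]
    cmp$fu_gut <- min(x[["fu_gut"]], 1)
    cmp$q_gut <- x[["q_gut"]]
    cmp$kp_scalar <- x[["kp_scalar"]]
    cmp$cl_renal_adult <- x[["cl_renal_adult"]]
    cmp$clint_by_isoform <- c(CYP2C19 = x[["clint_cyp2c19"]],
                              CYP2D6 = x[["clint_cyp2d6"]],
                              CYP3A4 = x[["clint_cyp3a4"]])
    prof <- simulate_individual(cmp, phys, regimen, settings)
    auc_last <- trapz(prof$time, prof$maternal_plasma)
    n <- nrow(prof)
    # log-linear terminal slope from the last 48 h
    tail_sel <- prof$time >= max(prof$time) - 48
    lam <- -stats::coef(stats::lm(log(prof$maternal_plasma[tail_sel]) ~
                                    prof$time[tail_sel]))[[2]]
    auc_inf <- auc_last + prof$maternal_plasma[n] / lam
    c(c_max = max(prof$maternal_plasma), auc = auc_inf)
  }
  list(model = model, ranges = ranges)
}
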