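# Parameter estimation: noise-level grid search, stop/ignore slopes,
# truncated-normal safety level, logistic cue-choice rule.

fit_result <- function(parameter, estimate, std_error = NA_real_,
                       objective = NA_real_, details = NULL, flags = character(0)) {
  structure(list(parameter = parameter, estimate = estimate,
                 std_error = std_error, objective = objective,
                 details = details, flags = flags),
            class = "ttb_fit")
}

#' @export
print.ttb_fit <- function(x, ...) {
  cat(sprintf("<fit> %s\n", x$parameter))
  est <- x$estimate
  se <- x$std_error
  for (i in seq_along(est)) {
    nm <- names(est)[i] %||% x$parameter
    if (!is.null(se) && !all(is.na(se)) && length(se) >= i && !is.na(se[i]))
      cat(sprintf("  %s = %.4g (s.e. %.3g)\n", nm, est[i], se[i]))
    else cat(sprintf("  %s = %.4g\n", nm, est[i]))
  }
  if (!is.na(x$objective)) cat(sprintf("  objective = %.4g\n", x$objective))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the noise level by grid search on pay-off curves
#'
#' For every candidate `epsilon`, simulates exploration-phase trajectories
#' (split equally across poor and rich landscapes), computes the best-so-far
#' pay-off curves per landscape kind and measures the squared-difference
#' distance to the observed curves; returns the grid value minimizing the
#' summed distance. The same landscape set is reused across grid points
#' (common random numbers), which sharpens the comparison between
#' neighbouring grid values.
#'
#' @param observed_curves named list with elements `poor` and `rich`, each a
#'   length-`rounds` mean normalized best-so-far curve.
#' @param grid candidate `epsilon` values in `[0, 1]`.
#' @param n_sim total number of simulated trajectories per grid point.
#' @param n_landscapes_per_kind how many landscapes per kind to spread them
#'   over.
#' @param params agent parameters for the simulated searcher (its `epsilon`
#'   is overridden per grid point).
#' @param phase the phase to simulate (default exploration).
#' @param seed master seed.
#' @return A `ttb_fit` with the selected `epsilon`, the objective at the
#'   optimum and the full grid in `details`.
#' @export
fit_epsilon <- function(observed_curves, grid = seq(0, 1, by = 0.01),
                        n_sim = 8000L, n_landscapes_per_kind = 50L,
                        params = agent_params("ttb", "none"),
                        phase = phase_config("exploration"), seed = NULL) {
  if (length(grid) == 0L) stop("empty epsilon grid", call. = FALSE)
  if (any(grid < 0 | grid > 1)) stop("grid values outside [0, 1]", call. = FALSE)
  kinds <- names(observed_curves)
  if (is.null(kinds)) stop("'observed_curves' must be a named list", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  trials <- max(1L, as.integer(round(n_sim / length(kinds) / n_landscapes_per_kind)))
  land_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  length(kinds) * n_landscapes_per_kind),
                       nrow = length(kinds))
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(grid) * length(kinds)),
                      nrow = length(grid))
  landscapes <- lapply(seq_along(kinds), function(ki) {
    lapply(land_seeds[ki, ], function(s)
      generate_landscape(dims = phase$dims, kind = kinds[ki], seed = s))
  })
  objective <- vapply(seq_along(grid), function(gi) {
    p <- params
    p$epsilon <- grid[gi]
    sum(vapply(seq_along(kinds), function(ki) {
      set.seed(run_seeds[gi, ki])
      trs <- unlist(lapply(landscapes[[ki]], function(land) {
        lapply(seq_len(trials), function(j) run_trial(phase, p, land))
      }), recursive = FALSE)
      dist_payoff(observed_curves[[ki]], payoff_curve(trs, "best_so_far"))
    }, numeric(1L)))
  }, numeric(1L))
  best <- which.min(objective)
  fit_result("epsilon", c(epsilon = grid[best]), objective = objective[best],
             details = data.frame(epsilon = grid, objective = objective))
}

records_for_fit <- function(records) {
  if (is.data.frame(records))
    records[!(records$censored %in% c("short_horizon", "superseded")), , drop = FALSE]
  else records
}

#' Fit the stopping slope k
#'
#' Linear-probability model of the immediate-stop indicator `S == 0` on the
#' discovered pay-off `x_best`, through the origin (the stopping probability
#' `k * x_best` has no intercept by construction). Short-horizon and
#' superseded episodes are excluded.
#'
#' @param records a `safety_records` data frame (episodes, possibly pooled
#'   over trajectories).
#' @return A `ttb_fit` with estimate `k`.
#' @export
fit_stop_slope <- function(records) {
  rec <- records_for_fit(records)
  if (length(unique(rec$x_best)) < 2L)
    stop("need at least two distinct x_best values", call. = FALSE)
  y <- as.numeric(rec$censored == "none" & rec$S == 0)
  if (all(y == 0)) return(fit_result("k", c(k = 0), flags = "no stop episodes"))
  fit <- stats::lm(y ~ 0 + x_best, data = rec)
  # binary outcome: heteroskedasticity-robust standard error
  fit_result("k", c(k = unname(stats::coef(fit)[1L])),
             std_error = sqrt(sandwich::vcovHC(fit, type = "HC1")[1L, 1L]))
}

#' Fit the ignore slope l
#'
#' Linear-probability model of the no-return indicator (`S > 1`: the episode
#' never re-occupied its best position) on `x_best`, with intercept; the
#' slope is reported as `l`. Under the generating rule
#' `P(ignore) = clip(1 + l * x_best, 0, 1)` the slope recovers `l` while the
#' intercept sits near 1.
#'
#' @inheritParams fit_stop_slope
#' @return A `ttb_fit` with estimate `l`.
#' @export
fit_ignore_slope <- function(records) {
  rec <- records_for_fit(records)
  if (length(unique(rec$x_best)) < 2L)
    stop("need at least two distinct x_best values", call. = FALSE)
  y <- as.numeric(rec$censored == "no_return" | (!is.na(rec$S) & rec$S > 1))
  if (all(y == 0)) return(fit_result("l", c(l = 0), flags = "no ignore episodes"))
  fit <- stats::lm(y ~ x_best, data = rec)
  fit_result("l", c(l = unname(stats::coef(fit)[2L])),
             std_error = sqrt(sandwich::vcovHC(fit, type = "HC1")[2L, 2L]))
}

#' Maximum-likelihood fit of the truncated-normal safety level
#'
#' Fits a normal distribution truncated to `(0, 1]` to the observed safety
#' levels with `0 < S <= 1`, by direct optimization of the log-likelihood
#' (BFGS on `(mu, log sd)`, standard errors from the numerical Hessian via
#' the delta method).
#'
#' @param records a `safety_records` data frame or a bare numeric vector of
#'   safety levels.
#' @param min_n minimum number of usable observations.
#' @return A `ttb_fit` with estimates `mu` and `sigma2`.
#' @export
fit_s0 <- function(records, min_n = 10L) {
  s <- if (is.data.frame(records)) {
    rec <- records_for_fit(records)
    rec$S[!is.na(rec$S) & rec$S > 0 & rec$S <= 1]
  } else records[records > 0 & records <= 1]
  n <- length(s)
  if (n < min_n) stop("too few observations with 0 < S <= 1", call. = FALSE)
  if (stats::sd(s) < 1e-8) {
    return(fit_result("s0", c(mu = mean(s), sigma2 = 0),
                      flags = "degenerate: zero-variance sample"))
  }
  # mean negative log-likelihood: scaling by n keeps the surface and its
  # gradients O(1), which stabilizes the optimizer
  nll <- function(par) {
    mu <- par[1L]; sd <- exp(par[2L])
    z <- stats::pnorm(1, mu, sd) - stats::pnorm(0, mu, sd)
    if (z <= 0 || !is.finite(z)) return(1e10)
    -(mean(stats::dnorm(s, mu, sd, log = TRUE)) - log(z))
  }
  # the truncated-sample sd underestimates the latent sd, so probe a few
  # inflation factors and keep the best Nelder-Mead optimum
  starts <- lapply(c(1, 2, 4), function(f) c(mean(s), log(stats::sd(s) * f)))
  opts <- lapply(starts, function(st)
    stats::optim(st, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12)))
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  mu <- opt$par[1L]; sd <- exp(opt$par[2L]); sigma2 <- sd^2
  se <- c(NA_real_, NA_real_)
  hess <- try(stats::optimHess(opt$par, nll), silent = TRUE)
  if (!inherits(hess, "try-error")) {
    cv <- try(solve(hess * n), silent = TRUE) # back to the full-likelihood scale
    if (!inherits(cv, "try-error") && all(diag(cv) > 0))
      se <- c(sqrt(cv[1L, 1L]), 2 * sigma2 * sqrt(cv[2L, 2L]))
  }
  fit_result("s0", c(mu = mu, sigma2 = sigma2), std_error = se,
             objective = n * opt$value)
}

#' Logistic fit of the probabilistic cue-choice rule
#'
#' Binary logistic regression of the pay-off-cue-consistent choice indicator
#' on the most-rewarding neighbouring pay-off `pn_max`. Complete or
#' quasi-complete separation is flagged.
#'
#' @param decisions data frame with logical `used_payoff` and numeric
#'   `pn_max`.
#' @return A `ttb_fit` with estimates `beta0`, `beta1`.
#' @export
fit_probabilistic_logistic <- function(decisions) {
  if (length(unique(decisions$used_payoff)) < 2L)
    stop("both choice classes must be present", call. = FALSE)
  flags <- character(0)
  fit <- withCallingHandlers(
    stats::glm(used_payoff ~ pn_max, family = stats::binomial(), data = decisions),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        flags <<- c(flags, "separation")
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (any(abs(stats::coef(fit)) > 50)) flags <- c(flags, "separation")
  fit_result("logistic", c(beta0 = unname(co[1L, 1L]), beta1 = unname(co[2L, 1L])),
             std_error = c(co[1L, 2L], co[2L, 2L]),
             objective = stats::deviance(fit), flags = unique(flags))
}

#' Probability of relying on the pay-off cue
#'
#' The probabilistic exploration variant relies on the pay-off cue (rather
#' than the novelty cue) with probability
#' `1 - 1 / (1 + exp(beta0 + beta1 * pn_max))`, an increasing logistic
#' function of the most-rewarding neighbouring pay-off.
#'
#' @param pn_max pay-off of the most-rewarding neighbouring solution.
#' @param beta0,beta1 logistic coefficients.
#' @return Probability in `(0, 1)`.
#' @export
prob_payoff_cue <- function(pn_max, beta0 = -1.509, beta1 = 0.301) {
  stats::plogis(beta0 + beta1 * pn_max)
}
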