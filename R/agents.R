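# Agent models.
#
# The full search model couples a take-the-best exploration cascade
# (not-visited, pay-off, novelty) with an exploitation mechanism expressed as
# a single extra cue at the top of the cascade: the exploration-radius cue.
# Each time the agent discovers a strictly better pay-off X_best it draws an
# excursion budget around the new best position P_best:
#   R = 1            with probability clip(k * X_best, 0, 1)      (stop)
#   R = Inf          with probability clip(1 + l * X_best, 0, 1)  (ignore)
#   R = S0 * D_opt   otherwise, S0 ~ N(mu, sigma2) truncated to (0, 1]
# where D_opt = floor(T_left / 2) is the farthest excursion that still allows
# a return to P_best by the final round. While a stop or return budget is
# active, the options considered in a round are those within
# min(R, T_left - 1) of P_best: the second term is the feasibility horizon
# that shrinks as time runs out and produces the emergent return to P_best
# exactly at the last round. An ignored peak imposes no constraint at all.

#' Agent parameters
#'
#' Bundles the model-variant selectors and all numeric parameters of the
#' search models. The numeric defaults are the package's reference values:
#' `epsilon = 0.17` for the take-the-best exploration noise, and per-phase
#' stopping/returning parameters (`preset = "exploitation"`: `k = 0.0051`,
#' `l = -0.027`, `mu = 0.806`, `sigma2 = 0.364`; `preset = "combined"`:
#' `k = 0.011`, `l = -0.022`, `mu = 0.386`, `sigma2 = 0.275`). The logistic
#' coefficients of the probabilistic exploration variant default to
#' `beta0 = -1.509`, `beta1 = 0.301`.
#'
#' @param exploration_model one of `"ttb"`, `"probabilistic"`,
#'   `"hill_climbing"`, `"blind"`, `"random"`.
#' @param exploitation_model one of `"none"` (pure exploration, no radius
#'   cue), `"returning"` (the full stop/ignore/return draw),
#'   `"simple_returning"` (no ignore branch), `"early_stop"` (radius 1 as
#'   soon as the first visited pay-off > 0 weakly dominating its visible
#'   neighbours is found), `"normative"` (deterministic `S0 = 1`, no stop, no
#'   ignore).
#' @param preset which per-phase defaults to use for `k`, `l`, `mu`,
#'   `sigma2`.
#' @param epsilon per-decision probability of a uniformly random choice among
#'   all legal options. Defaults to 0.17 for the take-the-best model and 0
#'   for the alternative exploration models.
#' @param k per-point slope of the stopping probability.
#' @param l per-point slope of the peak-ignoring probability (negative).
#' @param mu,sigma2 mean and variance of the truncated-normal safety level
#'   `S0`.
#' @param beta0,beta1 logistic coefficients of the probabilistic variant.
#' @return An object of class `agent_params`.
#' @examples
#' agent_params()                             # full model, exploitation preset
#' agent_params("random", "none")             # random-walk baseline
#' @export
agent_params <- function(exploration_model = c("ttb", "probabilistic",
                                               "hill_climbing", "blind", "random"),
                         exploitation_model = c("returning", "simple_returning",
                                                "early_stop", "normative", "none"),
                         preset = c("exploitation", "combined"),
                         epsilon = NULL, k = NULL, l = NULL,
                         mu = NULL, sigma2 = NULL,
                         beta0 = -1.509, beta1 = 0.301) {
  exploration_model <- match.arg(exploration_model)
  exploitation_model <- match.arg(exploitation_model)
  preset <- match.arg(preset)
  def <- if (preset == "exploitation") {
    list(k = 0.0051, l = -0.027, mu = 0.806, sigma2 = 0.364)
  } else {
    list(k = 0.011, l = -0.022, mu = 0.386, sigma2 = 0.275)
  }
  if (is.null(epsilon)) epsilon <- if (exploration_model == "ttb") 0.17 else 0
  p <- list(exploration_model = exploration_model,
            exploitation_model = exploitation_model,
            preset = preset,
            epsilon = epsilon,
            k = k %||% def$k, l = l %||% def$l,
            mu = mu %||% def$mu, sigma2 = sigma2 %||% def$sigma2,
            beta0 = beta0, beta1 = beta1,
            ignore_zero = FALSE, s0_fixed = NA_real_)
  if (p$epsilon < 0 || p$epsilon > 1) stop("'epsilon' must be in [0, 1]", call. = FALSE)
  if (p$sigma2 <= 0) stop("'sigma2' must be positive", call. = FALSE)
  class(p) <- "agent_params"
  configure_exploitation(exploitation_model, p)
}

#' Derive the effective parameters of an exploitation variant
#'
#' Maps an exploitation model name onto the effective stopping/returning
#' machinery: `"normative"` forces `k = 0`, removes the ignore branch and
#' pins `S0` at 1 (a deterministic full-horizon return);
#' `"simple_returning"` removes the ignore branch only; `"early_stop"` and
#' `"none"` use no stochastic draw at all.
#'
#' @param which exploitation model name.
#' @param params an `agent_params` object.
#' @return The modified `agent_params`.
#' @export
configure_exploitation <- function(which, params) {
  params$exploitation_model <- which
  params$ignore_zero <- which %in% c("simple_returning", "normative")
  params$s0_fixed <- if (which == "normative") 1 else NA_real_
  if (which == "normative") params$k <- 0
  params
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("<agent_params> exploration = %s, exploitation = %s (preset %s)\n",
              x$exploration_model, x$exploitation_model, x$preset))
  cat(sprintf("  epsilon = %g; k = %g, l = %g, mu = %g, sigma2 = %g\n",
              x$epsilon, x$k, x$l, x$mu, x$sigma2))
  if (x$exploration_model == "probabilistic")
    cat(sprintf("  beta0 = %g, beta1 = %g\n", x$beta0, x$beta1))
  cat(sprintf("  free parameters: %d, exploration cues: %d\n",
              n_free_params(x), n_cues(x)))
  invisible(x)
}

# Free-parameter and cue counts of the model variants (used in comparison
# tables). The component argument isolates the count of one mechanism, the
# way the comparison tables list only the varying component.
n_free_params <- function(params, component = c("total", "exploration", "exploitation")) {
  component <- match.arg(component)
  explo <- switch(params$exploration_model,
                  ttb = 1L, probabilistic = 2L, 0L)
  exploit <- switch(params$exploitation_model,
                    returning = 4L, simple_returning = 3L, 0L)
  switch(component, total = explo + exploit, exploration = explo,
         exploitation = exploit)
}

n_cues <- function(params) {
  switch(params$exploration_model,
         ttb = 3L, probabilistic = 3L, hill_climbing = 2L, blind = 2L, random = 0L)
}

#' Optimal exploration range
#'
#' The farthest distance an agent can move away from its best position and
#' still return to it by the final round: `floor(t_left / 2)`, where `t_left`
#' is the number of rounds remaining.
#'
#' @param t_left non-negative integer number of remaining rounds.
#' @return `floor(t_left / 2)` as an integer.
#' @export
d_optimal <- function(t_left) {
  if (any(t_left < 0)) stop("'t_left' must be non-negative", call. = FALSE)
  as.integer(t_left %/% 2)
}

# Truncated-normal sampler on (0, 1] by inverse CDF.
rtruncnorm01 <- function(n, mu, sd) {
  lo <- stats::pnorm(0, mu, sd)
  hi <- stats::pnorm(1, mu, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mu, sd)
}

#' Draw an exploration-range budget after a pay-off improvement
#'
#' Sequential draw over the three branches: stop (`R = 1`) with probability
#' `clip(k * x_best, 0, 1)`; otherwise ignore (`R = Inf`) with probability
#' `clip(1 + l * x_best, 0, 1)`; otherwise return with
#' `R = S0 * d_optimal(t_left)` and `S0` drawn from a normal distribution
#' with mean `mu` and variance `sigma2` truncated to `(0, 1]`. The ignore
#' probability is 1 at `x_best = 0` and falls to 0 near `x_best = -1/l`
#' (about 37 under the default `l`), so only low peaks tend to be ignored.
#'
#' @param x_best the newly discovered best pay-off (positive).
#' @param t_left rounds remaining after the discovery.
#' @param params an `agent_params`.
#' @return A list with `R`, `s0` (`NA` unless the return branch fired) and
#'   `branch` (`"stop"`, `"ignore"` or `"return"`).
#' @export
draw_exploration_range <- function(x_best, t_left, params) {
  p_stop <- clip01(params$k * x_best)
  if (stats::runif(1L) < p_stop)
    return(list(R = 1, s0 = NA_real_, branch = "stop"))
  p_ignore <- if (params$ignore_zero) 0 else clip01(1 + params$l * x_best)
  if (stats::runif(1L) < p_ignore)
    return(list(R = Inf, s0 = NA_real_, branch = "ignore"))
  s0 <- if (!is.na(params$s0_fixed)) params$s0_fixed
        else rtruncnorm01(1L, params$mu, sqrt(params$sigma2))
  list(R = s0 * d_optimal(t_left), s0 = s0, branch = "return")
}

clip01 <- function(p) min(max(p, 0), 1)

# ---------------------------------------------------------------------------
# Search state and the one-round step engine
# ---------------------------------------------------------------------------

#' Initialize a search state
#'
#' @param phase a [phase_config()].
#' @param landscape a `landscape` with dimensions matching the phase.
#' @param params an `agent_params`.
#' @return A `search_state` list: position, visited/seen masks (linear cell
#'   indices), `x_best`, `p_best`, the active branch and excursion budget,
#'   and the round counter (number of decisions already made).
#' @export
init_search_state <- function(phase, landscape, params) {
  dims <- phase$dims
  n <- prod(dims)
  visited <- logical(n)
  seen <- logical(n)
  pos <- phase$start
  idx <- (pos[2L] - 1L) * dims[1L] + pos[1L]
  visited[idx] <- TRUE
  seen[neighbourhood_idx(pos[1L], pos[2L], dims)] <- TRUE
  payoff <- as.integer(landscape$payoffs[idx])
  state <- list(position = pos, visited = visited, seen = seen,
                x_best = 0L, p_best = NULL,
                branch = "none", R0 = Inf, s0 = NA_real_,
                round = 0L, rounds = phase$rounds)
  class(state) <- "search_state"
  register_arrival(state, payoff, phase, params, landscape)
}

neighbourhood_idx <- function(row, col, dims) {
  offs <- moore_offsets(dims)
  r2 <- row + offs[, 1L]
  c2 <- col + offs[, 2L]
  ok <- r2 >= 1L & r2 <= dims[1L] & c2 >= 1L & c2 <= dims[2L]
  (c2[ok] - 1L) * dims[1L] + r2[ok]
}

# Book-keeping shared by initialization and every step: x_best/p_best update,
# the range redraw on strict improvement, and the early-stop trigger.
register_arrival <- function(state, payoff, phase, params, landscape = NULL) {
  exploit <- params$exploitation_model
  if (payoff > state$x_best) {
    state$x_best <- payoff
    state$p_best <- state$position
    if (exploit %in% c("returning", "simple_returning", "normative")) {
      d <- draw_exploration_range(payoff, phase$rounds - state$round, params)
      state$branch <- d$branch
      state$R0 <- d$R
      state$s0 <- d$s0
    }
  }
  if (exploit == "early_stop" && state$branch == "none" && payoff > 0 &&
      !is.null(landscape)) {
    nb <- neighbourhood_idx(state$position[1L], state$position[2L], phase$dims)
    if (payoff >= max(landscape$payoffs[nb])) {
      state$branch <- "stop"
      state$R0 <- 1
      state$p_best <- state$position
      state$x_best <- max(state$x_best, payoff)
    }
  }
  state
}

# One decision: returns list(option index fields, deciding_cue, noise flag).
choose_option <- function(state, landscape, phase, params) {
  r <- state$round + 1L
  t_left <- phase$rounds - r + 1L
  first_1d <- phase$phase == "exploitation" && r == 1L
  opts <- legal_options(state$position, phase$dims,
                        forbid_stay = first_1d, forbid_left = first_1d)
  m <- length(opts$idx)
  if (params$epsilon > 0 && stats::runif(1L) < params$epsilon) {
    j <- sample_one(seq_len(m))
    return(c(pick(opts, j), list(deciding_cue = "noise", noise = TRUE)))
  }
  keep <- seq_len(m)
  if (state$branch %in% c("stop", "return") && !is.null(state$p_best)) {
    eff_R <- min(state$R0, t_left - 1L)
    dist <- chebyshev_dist(opts$row, opts$col, state$p_best[1L], state$p_best[2L])
    keep <- which(dist <= eff_R)
    if (length(keep) == 0L) {
      # stranded outside the radius (after noise): head back towards p_best
      j <- sample_one(which(dist == min(dist)))
      return(c(pick(opts, j), list(deciding_cue = "radius", noise = FALSE)))
    }
    if (length(keep) == 1L && m > 1L) {
      return(c(pick(opts, keep), list(deciding_cue = "radius", noise = FALSE)))
    }
  }
  sub <- pick(opts, keep)
  dec <- switch(params$exploration_model,
    ttb = ttb_decide(rbind(
      not_visited = cue_not_visited(sub, state$visited),
      payoff      = cue_payoff(sub, landscape),
      novelty     = cue_novelty(sub, state$seen, phase$dims))),
    probabilistic = {
      pn_max <- max(landscape$payoffs[opts$idx[!opts$is_stay]])
      use_payoff <- stats::runif(1L) < stats::plogis(params$beta0 + params$beta1 * pn_max)
      second <- if (use_payoff) rbind(payoff = cue_payoff(sub, landscape))
                else rbind(novelty = cue_novelty(sub, state$seen, phase$dims))
      ttb_decide(rbind(not_visited = cue_not_visited(sub, state$visited), second))
    },
    hill_climbing = ttb_decide(rbind(payoff = cue_payoff(sub, landscape))),
    blind = ttb_decide(rbind(
      not_visited = cue_not_visited(sub, state$visited),
      novelty     = cue_novelty(sub, state$seen, phase$dims))),
    random = list(choice = sample_one(seq_along(keep)),
                  deciding_cue = "random_tiebreak"))
  c(pick(sub, dec$choice), list(deciding_cue = dec$deciding_cue, noise = FALSE))
}

pick <- function(opts, j) {
  list(row = opts$row[j], col = opts$col[j], idx = opts$idx[j],
       is_stay = opts$is_stay[j])
}

# Apply a chosen option to the state.
apply_option <- function(state, dec, landscape, phase, params) {
  state$round <- state$round + 1L
  state$position <- c(dec$row, dec$col)
  state$visited[dec$idx] <- TRUE
  state$seen[neighbourhood_idx(dec$row, dec$col, phase$dims)] <- TRUE
  payoff <- as.integer(landscape$payoffs[dec$idx])
  register_arrival(state, payoff, phase, params, landscape)
}

#' Advance the full take-the-best model by one round
#'
#' Runs one decision of the four-cue cascade (exploration-radius,
#' not-visited, pay-off, novelty, in this order) with epsilon-noise at the
#' top level, applies the move and updates the state (visited/seen masks,
#' `x_best`/`p_best`, and the excursion budget redraw on strict
#' improvement).
#'
#' @inheritParams init_search_state
#' @param state a `search_state`.
#' @return A list with the updated `state` and the `decision` (target row,
#'   col, deciding cue, noise flag).
#' @export
step_full_model <- function(state, landscape, phase, params) {
  if (state$round >= phase$rounds) stop("no rounds left", call. = FALSE)
  dec <- choose_option(state, landscape, phase, params)
  list(state = apply_option(state, dec, landscape, phase, params), decision = dec)
}

#' @rdname step_full_model
#' @param which exploration model to use for this step (overrides
#'   `params$exploration_model`).
#' @export
step_alternative <- function(state, landscape, phase, params, which) {
  params$exploration_model <- match.arg(which, c("ttb", "probabilistic",
                                                 "hill_climbing", "blind", "random"))
  step_full_model(state, landscape, phase, params)
}
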