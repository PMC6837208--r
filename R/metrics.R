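# Descriptive statistics and model-comparison distances over trajectory sets.

traj_list <- function(x) {
  if (inherits(x, "trajectory_set")) x$trajectories
  else if (inherits(x, "trajectory")) list(x)
  else x
}

#' Mean normalized pay-off per round
#'
#' Averages the normalized pay-off over trajectories, round by round.
#' `mode = "best_so_far"` uses the running best pay-off (the exploration-phase
#' reward quantity, non-decreasing by construction); `mode = "current"` uses
#' the pay-off of the occupied field (the exploitation/combined reward
#' quantity). Pay-offs are normalized per landscape by its maximum.
#'
#' @param x a `trajectory_set`, a list of trajectories or one `trajectory`.
#' @param mode `"best_so_far"` or `"current"`.
#' @return Numeric vector of length `rounds` (rounds 1..30; the round-0 start
#'   state is excluded).
#' @export
payoff_curve <- function(x, mode = c("best_so_far", "current")) {
  mode <- match.arg(mode)
  trs <- traj_list(x)
  if (length(trs) == 0L) stop("empty trajectory set", call. = FALSE)
  mat <- vapply(trs, function(tr) {
    m <- attr(tr, "landscape_max")
    if (is.null(m) || is.na(m) || m <= 0)
      stop("trajectory lacks a positive landscape maximum", call. = FALSE)
    v <- if (mode == "best_so_far") tr$x_best else tr$payoff
    v[-1L] / m
  }, numeric(nrow(trs[[1L]]) - 1L))
  rowMeans(mat)
}

#' Aggregate visit-density map
#'
#' Per-cell counts of occupancy over all rounds (including the start state)
#' of all trajectories. The log transform used for display and for
#' [dist_density()] is applied separately.
#'
#' @param x a `trajectory_set` or list of trajectories.
#' @param dims grid dimensions.
#' @return An integer `rows x cols` matrix whose entries sum to
#'   `(rounds + 1) * n_trajectories`.
#' @export
density_map <- function(x, dims) {
  trs <- traj_list(x)
  counts <- matrix(0L, dims[1L], dims[2L])
  for (tr in trs) {
    idx <- (tr$col - 1L) * dims[1L] + tr$row
    t <- tabulate(idx, nbins = prod(dims))
    counts <- counts + t
  }
  counts
}

#' Fraction of revisited fields
#'
#' The number of distinct fields occupied in two or more rounds divided by
#' the number of distinct fields occupied at all (the start state counts as
#' an occupancy).
#'
#' @param trajectory a `trajectory`.
#' @return A value in `[0, 1]`.
#' @export
revisit_fraction <- function(trajectory) {
  key <- paste(trajectory$row, trajectory$col)
  occ <- table(key)
  sum(occ >= 2L) / length(occ)
}

#' Replay a trajectory and classify its decisions against the cue definitions
#'
#' Reconstructs the visited/seen masks along a trajectory and classifies
#' every decision by the three observable cue criteria: (a) did the movement
#' target a non-visited field; (b) did it target a non-visited field with the
#' highest pay-off among the non-visited options; (c) at decision points
#' where neither the not-visited nor the pay-off cue uniquely discriminates
#' (the two-cue subset cascade leaves more than one option), did the chosen
#' option attain maximal novelty among the remaining options. The
#' classification looks only at positions and the landscape, never at the
#' recorded model internals, so it applies equally to simulated and external
#' trajectories.
#'
#' For criterion (c) the number of newly revealed solutions is counted
#' against what is on screen at the moment of the decision
#' (`novelty_seen = "screen"`): the display only ever shows the current
#' field and its adjacent ones, so an interior diagonal move reveals exactly
#' five new solutions and an orthogonal move three, and a movement is
#' novelty-consistent when no other option would have revealed more.
#' `novelty_seen = "history"` instead counts fields never shown at any
#' earlier round (the bookkeeping the model's novelty cue uses) and requires
#' the chosen option to attain the maximum among the options surviving the
#' two-cue cascade; this is a stricter classification with a much lower
#' chance level.
#'
#' @param trajectory a `trajectory`.
#' @param landscape the `landscape` it was played on.
#' @param phase the [phase_config()] (for grid dims and first-round rules).
#' @param novelty_seen reference set for the (c) classification, see above.
#' @return A data frame with one row per decision: `round`,
#'   `toward_not_visited`, `payoff_consistent`, `cues_silent` (the (c)
#'   conditioning event) and `novelty_consistent` (`NA` when not
#'   conditioned).
#' @export
classify_decisions <- function(trajectory, landscape, phase,
                               novelty_seen = c("screen", "history")) {
  novelty_seen <- match.arg(novelty_seen)
  dims <- phase$dims
  n <- prod(dims)
  visited <- logical(n); seen <- logical(n)
  pos <- c(trajectory$row[1L], trajectory$col[1L])
  visited[(pos[2L] - 1L) * dims[1L] + pos[1L]] <- TRUE
  seen[neighbourhood_idx(pos[1L], pos[2L], dims)] <- TRUE
  rounds <- nrow(trajectory) - 1L
  out <- data.frame(round = seq_len(rounds), toward_not_visited = NA,
                    payoff_consistent = NA, cues_silent = NA,
                    novelty_consistent = NA)
  for (r in seq_len(rounds)) {
    first_1d <- phase$phase == "exploitation" && r == 1L
    opts <- legal_options(pos, dims, forbid_stay = first_1d, forbid_left = first_1d)
    target <- c(trajectory$row[r + 1L], trajectory$col[r + 1L])
    tidx <- (target[2L] - 1L) * dims[1L] + target[1L]
    j <- which(opts$idx == tidx)
    if (length(j) != 1L) stop("illegal move in trajectory at round ", r, call. = FALSE)

    nv <- cue_not_visited(opts, visited)
    pay <- cue_payoff(opts, landscape)
    out$toward_not_visited[r] <- nv[j] == 1L
    if (any(nv == 1L)) {
      nv_idx <- which(nv == 1L)
      out$payoff_consistent[r] <- (j %in% nv_idx) && pay[j] == max(pay[nv_idx])
    } else {
      out$payoff_consistent[r] <- FALSE
    }
    surv <- seq_along(opts$idx)
    for (v in list(nv, pay)) {
      vv <- v[surv]
      surv <- surv[vv == max(vv)]
      if (length(surv) == 1L) break
    }
    out$cues_silent[r] <- length(surv) > 1L
    if (out$cues_silent[r]) {
      if (novelty_seen == "screen") {
        screen <- logical(length(seen))
        screen[neighbourhood_idx(pos[1L], pos[2L], dims)] <- TRUE
        nov <- novelty_counts(opts$row, opts$col, screen, dims)
        out$novelty_consistent[r] <- nov[j] == max(nov)
      } else {
        nov <- cue_novelty(opts, seen, dims)
        out$novelty_consistent[r] <- (j %in% surv) && nov[j] == max(nov[surv])
      }
    }
    pos <- target
    visited[tidx] <- TRUE
    seen[neighbourhood_idx(pos[1L], pos[2L], dims)] <- TRUE
  }
  out
}

#' Cue-usage frequencies over a trajectory set
#'
#' Per-trajectory proportions of the three observable decision
#' classifications of [classify_decisions()], averaged over trajectories:
#' (a) movements towards a non-visited solution, (b) movements towards a
#' non-visited solution with the highest pay-off, and (c) movements
#' maximizing the number of newly revealed solutions among decision points
#' where neither earlier cue discriminates. The attribute `"provenance"`
#' additionally tabulates the simulator's own per-decision deciding cues
#' when available.
#'
#' @param set a `trajectory_set` carrying its landscapes.
#' @param novelty_seen passed to [classify_decisions()].
#' @return Named numeric vector `c(not_visited, payoff, novelty)` of mean
#'   proportions in `[0, 1]`.
#' @export
cue_usage <- function(set, novelty_seen = c("screen", "history")) {
  novelty_seen <- match.arg(novelty_seen)
  if (is.null(set$landscapes)) stop("trajectory set lacks landscapes", call. = FALSE)
  props <- vapply(seq_along(set$trajectories), function(i) {
    cls <- classify_decisions(set$trajectories[[i]],
                              set$landscapes[[set$landscape_id[i]]], set$phase,
                              novelty_seen)
    c(mean(cls$toward_not_visited),
      mean(cls$payoff_consistent),
      if (any(cls$cues_silent)) mean(cls$novelty_consistent[cls$cues_silent])
      else NA_real_)
  }, numeric(3L))
  out <- rowMeans(props, na.rm = TRUE)
  names(out) <- c("not_visited", "payoff", "novelty")
  cues <- unlist(lapply(set$trajectories, function(tr) tr$deciding_cue[-1L]))
  attr(out, "provenance") <- table(cues) / length(cues)
  out
}

#' Safety-level episodes of a trajectory
#'
#' One episode per strict improvement of the best discovered pay-off. For an
#' improvement after round `r` the optimal exploration range is
#' `d_optimal(rounds - r)`; the realized excursion `R` is the maximum
#' distance from the new best position attained before its first
#' re-occupation (Chebyshev in 2-D, `|dx|` in 1-D), and the safety level is
#' `S = R / D_optimal`. Episodes are censored when the horizon is too short
#' to show return behaviour (`D_optimal <= 2`, `"short_horizon"`), when the
#' trajectory ends without re-occupation (`"no_return"`, the `S > 1` case),
#' or when a better pay-off supersedes the episode before any return
#' (`"superseded"`). Only uncensored episodes enter heat-map style
#' aggregations.
#'
#' @param trajectory a `trajectory`.
#' @param rounds total number of decisions (defaults to the trajectory
#'   length).
#' @return A data frame of class `safety_records` with columns `x_best`,
#'   `discovery_round`, `d_optimal`, `realized_R`, `S`, `censored`.
#' @export
safety_levels <- function(trajectory, rounds = nrow(trajectory) - 1L) {
  xb <- trajectory$x_best
  imp <- which(diff(c(0L, xb)) > 0L) # rows (1-based) where x_best strictly rose
  recs <- lapply(imp, function(i) {
    disc_round <- trajectory$round[i]
    p <- c(trajectory$row[i], trajectory$col[i])
    d_opt <- d_optimal(rounds - disc_round)
    j <- if (i < nrow(trajectory)) (i + 1L):nrow(trajectory) else integer(0)
    nxt <- imp[imp > i]
    end <- if (length(nxt)) nxt[1L] else nrow(trajectory) + 1L
    j <- j[j < end]
    dist <- if (length(j))
      chebyshev_dist(trajectory$row[j], trajectory$col[j], p[1L], p[2L])
    else integer(0)
    ret <- which(dist == 0L)
    if (length(ret)) {
      realized <- if (ret[1L] > 1L) max(dist[seq_len(ret[1L] - 1L)]) else 0L
      censored <- "none"
    } else {
      realized <- if (length(dist)) max(dist) else 0L
      censored <- if (length(nxt)) "superseded" else "no_return"
    }
    if (d_opt <= 2L) censored <- "short_horizon"
    data.frame(x_best = xb[i], discovery_round = disc_round, d_optimal = d_opt,
               realized_R = realized,
               S = if (d_opt > 0L) realized / d_opt else NA_real_,
               censored = censored, stringsAsFactors = FALSE)
  })
  out <- if (length(recs)) do.call(rbind, recs)
  else data.frame(x_best = integer(0), discovery_round = integer(0),
                  d_optimal = integer(0), realized_R = integer(0),
                  S = numeric(0), censored = character(0))
  class(out) <- c("safety_records", "data.frame")
  out
}

#' Distance between pay-off curves
#'
#' The sum over rounds of squared differences between the mean normalized
#' pay-off curves; when both arguments are lists (e.g. one curve per
#' landscape kind) the distances are summed over elements.
#'
#' @param observed,predicted numeric vectors of equal length, or lists of
#'   such vectors.
#' @return A non-negative number.
#' @export
dist_payoff <- function(observed, predicted) {
  if (is.list(observed) || is.list(predicted)) {
    stopifnot(length(observed) == length(predicted))
    return(sum(mapply(dist_payoff, observed, predicted)))
  }
  if (length(observed) != length(predicted))
    stop("pay-off curves of different length", call. = FALSE)
  sum((observed - predicted)^2)
}

#' Distance between density maps
#'
#' The mean over cells of the absolute difference between the two maps on a
#' log scale: each count map is converted to relative frequencies with one
#' pseudo-count per cell and transformed by `log10`. `log_scale = FALSE`
#' compares raw relative frequencies instead.
#'
#' @param observed,predicted count matrices of equal dimensions.
#' @param log_scale compare on the log scale (default).
#' @return A non-negative number, symmetric in its arguments, zero for
#'   identical maps.
#' @export
dist_density <- function(observed, predicted, log_scale = TRUE) {
  if (!all(dim(observed) == dim(predicted)))
    stop("density maps of different dimensions", call. = FALSE)
  f <- function(m) {
    rel <- (m + 1) / sum(m + 1)
    if (log_scale) log10(rel) else rel
  }
  mean(abs(f(observed) - f(predicted)))
}

#' k-fold cross-validated model comparison
#'
#' Splits the landscapes of an observed trajectory set into `k` folds. For
#' each fold, the model's free parameters are fitted on the remaining folds
#' (when a fitting function is supplied; parameter-free models skip this
#' step), the model is simulated on the held-out landscapes with the same
#' number of trajectories per landscape as observed, and the out-of-sample
#' [dist_payoff()] and [dist_density()] are computed against the held-out
#' trajectories. Fold results are averaged.
#'
#' @param observed a `trajectory_set` carrying its landscapes.
#' @param params an [agent_params()] describing the candidate model.
#' @param k number of folds (default 5).
#' @param fit_fun optional `function(train_set, params)` returning updated
#'   parameters.
#' @param seed integer seed for the fold simulations.
#' @param name model label for the result row.
#' @return A one-row data frame of class `comparison_result`: `name`,
#'   `dist_payoff`, `dist_density`, `n_params`, `n_cues`, `folds`.
#' @export
kfold_cv <- function(observed, params, k = 5L, fit_fun = NULL, seed = NULL,
                     name = params$exploration_model) {
  k <- as.integer(k)
  n_land <- length(observed$landscapes)
  if (k < 2L) stop("'k' must be >= 2", call. = FALSE)
  if (n_land < k) stop("need at least k landscapes for k folds", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fold_of <- rep_len(seq_len(k), n_land)[sample.int(n_land)]
  mode <- if (observed$phase$reward_rule == "highest_payoff") "best_so_far" else "current"
  fold_seeds <- sample.int(.Machine$integer.max - 1L, k)
  res <- vapply(seq_len(k), function(f) {
    test_land <- which(fold_of == f)
    test_idx <- which(observed$landscape_id %in% test_land)
    pars <- params
    if (!is.null(fit_fun)) {
      train <- subset_trajectory_set(observed, which(!(observed$landscape_id %in% test_land)))
      pars <- fit_fun(train, params)
    }
    sim <- simulate_on_landscapes(observed, test_land, pars, fold_seeds[f])
    obs_sub <- subset_trajectory_set(observed, test_idx)
    c(dist_payoff(payoff_curve(obs_sub, mode), payoff_curve(sim, mode)),
      dist_density(density_map(obs_sub, observed$phase$dims),
                   density_map(sim, observed$phase$dims)))
  }, numeric(2L))
  out <- data.frame(name = name, dist_payoff = mean(res[1L, ]),
                    dist_density = mean(res[2L, ]),
                    n_params = n_free_params(params), n_cues = n_cues(params),
                    folds = k, stringsAsFactors = FALSE)
  attr(out, "fold_of") <- fold_of
  attr(out, "per_fold") <- t(res)
  class(out) <- c("comparison_result", "data.frame")
  out
}

# Replay the observed per-landscape trial counts with a candidate model.
simulate_on_landscapes <- function(observed, land_ids, params, seed) {
  set.seed(seed)
  trajectories <- list()
  landscape_id <- integer(0)
  landscapes <- observed$landscapes[land_ids]
  for (ii in seq_along(land_ids)) {
    i <- land_ids[ii]
    n_tr <- sum(observed$landscape_id == i)
    for (j in seq_len(n_tr)) {
      trajectories[[length(trajectories) + 1L]] <-
        run_trial(observed$phase, params, observed$landscapes[[i]])
      landscape_id <- c(landscape_id, ii)
    }
  }
  structure(list(trajectories = trajectories, landscapes = landscapes,
                 landscape_id = landscape_id, phase = observed$phase,
                 params = params, seed = seed),
            class = "trajectory_set")
}

subset_trajectory_set <- function(set, idx) {
  keep_land <- sort(unique(set$landscape_id[idx]))
  structure(list(trajectories = set$trajectories[idx],
                 landscapes = set$landscapes[keep_land],
                 landscape_id = match(set$landscape_id[idx], keep_land),
                 phase = set$phase, params = set$params, seed = set$seed),
            class = "trajectory_set")
}

#' Compare a menu of models against one observed trajectory set
#'
#' Runs [kfold_cv()] for each candidate and stacks the rows, sorted by
#' `dist_payoff`.
#'
#' @param observed a `trajectory_set`.
#' @param models named list of [agent_params()] objects.
#' @param k folds.
#' @param seed integer seed.
#' @param fit_funs optional named list of fitting functions per model.
#' @return A `comparison_result` data frame, one row per model.
#' @export
compare_models <- function(observed, models, k = 5L, seed = NULL,
                           fit_funs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(models))
  rows <- lapply(seq_along(models), function(i) {
    kfold_cv(observed, models[[i]], k = k,
             fit_fun = fit_funs[[names(models)[i]]],
             seed = seeds[i], name = names(models)[i])
  })
  out <- do.call(rbind, rows)
  out[order(out$dist_payoff), ]
}
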