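# Trial and batch simulation of the three experimental phases.

#' Phase configuration
#'
#' The three phases of the search task, 30 rounds each: `exploration`
#' (63 x 63 grid, start in the centre at (32, 32), reward = highest pay-off
#' encountered), `exploitation` (1 x 63 line, start at the left end, reward =
#' pay-off of the final position, first round restricted to a move to the
#' right) and `combined` (63 x 63 from (32, 32), reward = pay-off of the
#' final position).
#'
#' @param phase phase name.
#' @param landscape_kind which landscape preset the phase is played on.
#' @param rounds number of decisions (default 30).
#' @return An object of class `phase_config`.
#' @export
phase_config <- function(phase = c("exploration", "exploitation", "combined"),
                         landscape_kind = c("poor", "rich"), rounds = 30L) {
  phase <- match.arg(phase)
  landscape_kind <- match.arg(landscape_kind)
  cfg <- switch(phase,
    exploration  = list(dims = c(63L, 63L), start = c(32L, 32L),
                        reward_rule = "highest_payoff"),
    exploitation = list(dims = c(1L, 63L), start = c(1L, 1L),
                        reward_rule = "last_round_payoff"),
    combined     = list(dims = c(63L, 63L), start = c(32L, 32L),
                        reward_rule = "last_round_payoff"))
  structure(c(list(phase = phase, rounds = as.integer(rounds),
                   landscape_kind = landscape_kind), cfg),
            class = "phase_config")
}

#' @export
print.phase_config <- function(x, ...) {
  cat(sprintf("<phase_config> %s: %d x %d grid, start (%d, %d), %d rounds, reward = %s\n",
              x$phase, x$dims[1], x$dims[2], x$start[1], x$start[2], x$rounds,
              x$reward_rule))
  invisible(x)
}

#' Run one 30-round trial
#'
#' Places the agent at the phase's start field (which counts as visited, with
#' its visible neighbourhood seen, before the first decision), applies 30
#' decisions of the configured model and records the full per-round
#' trajectory. The decision at round r is taken with `t_left = rounds - r + 1`
#' rounds remaining; an excursion budget drawn after the round-r move uses
#' `t_left = rounds - r`.
#'
#' @param phase a [phase_config()].
#' @param params an [agent_params()].
#' @param landscape a `landscape` whose dimensions match the phase.
#' @param seed optional integer seed for this trial.
#' @return An object of class `trajectory`: a data frame with one row per
#'   round (round 0 is the start state) and columns `round`, `row`, `col`,
#'   `payoff`, `x_best`, `p_best_row`, `p_best_col`, `R` (current excursion
#'   budget, `NA` while none or infinite), `deciding_cue`, `noise_flag`;
#'   attributes carry the reward, the normalized reward, the landscape
#'   maximum and kind, the parameters and the seed.
#' @examples
#' land <- generate_landscape(kind = "poor", seed = 7)
#' tr <- run_trial(phase_config("exploration"), agent_params(), land, seed = 1)
#' attr(tr, "reward")
#' @export
run_trial <- function(phase, params, landscape, seed = NULL) {
  if (!identical(as.integer(landscape$dims), as.integer(phase$dims)))
    stop("landscape dimensions do not match the phase", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rounds <- phase$rounds
  state <- init_search_state(phase, landscape, params)

  n <- rounds + 1L
  rec_row <- integer(n); rec_col <- integer(n); rec_pay <- integer(n)
  rec_xb <- integer(n); rec_pbr <- integer(n); rec_pbc <- integer(n)
  rec_R <- numeric(n); rec_cue <- character(n); rec_noise <- logical(n)

  snap <- function(i, cue, noise) {
    rec_row[i] <<- state$position[1L]; rec_col[i] <<- state$position[2L]
    rec_pay[i] <<- landscape$payoffs[(state$position[2L] - 1L) * phase$dims[1L] +
                                       state$position[1L]]
    rec_xb[i] <<- state$x_best
    rec_pbr[i] <<- if (is.null(state$p_best)) NA_integer_ else state$p_best[1L]
    rec_pbc[i] <<- if (is.null(state$p_best)) NA_integer_ else state$p_best[2L]
    rec_R[i] <<- if (is.finite(state$R0)) state$R0 else NA_real_
    rec_cue[i] <<- cue; rec_noise[i] <<- noise
  }
  snap(1L, NA_character_, FALSE)
  for (r in seq_len(rounds)) {
    dec <- choose_option(state, landscape, phase, params)
    state <- apply_option(state, dec, landscape, phase, params)
    snap(r + 1L, dec$deciding_cue, dec$noise)
  }

  reward <- switch(phase$reward_rule,
                   highest_payoff = state$x_best,
                   last_round_payoff = rec_pay[n])
  land_max <- max(landscape$payoffs)
  out <- data.frame(round = 0:rounds, row = rec_row, col = rec_col,
                    payoff = rec_pay, x_best = rec_xb,
                    p_best_row = rec_pbr, p_best_col = rec_pbc,
                    R = rec_R, deciding_cue = rec_cue,
                    noise_flag = rec_noise, stringsAsFactors = FALSE)
  structure(out,
            class = c("trajectory", "data.frame"),
            reward = as.integer(reward),
            normalized_reward = if (land_max > 0) reward / land_max else NA_real_,
            landscape_max = land_max,
            landscape_kind = landscape$kind,
            phase = phase$phase,
            params = params,
            seed = seed)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s phase, %d rounds, reward = %d (normalized %.3f)\n",
              attr(x, "phase"), nrow(x) - 1L, attr(x, "reward"),
              attr(x, "normalized_reward")))
  cat(sprintf("  final position (%d, %d); x_best = %d; %d distinct fields visited\n",
              x$row[nrow(x)], x$col[nrow(x)], x$x_best[nrow(x)],
              nrow(unique(x[, c("row", "col")]))))
  invisible(x)
}

#' Run a batch of independent trials
#'
#' Generates `n_landscapes` landscapes of the requested kind and runs
#' `trials_per_landscape` trials on each. All randomness derives from the
#' master `seed`: per-landscape and per-trial seeds are pre-drawn from the
#' seeded master stream and stored with each trajectory, so any single trial
#' is reproducible in isolation via [run_trial()].
#'
#' @inheritParams run_trial
#' @param n_landscapes number of landscapes.
#' @param trials_per_landscape trials per landscape.
#' @param seed master seed.
#' @param kind landscape kind, defaulting to the phase's.
#' @return An object of class `trajectory_set`: a list with `trajectories`,
#'   `landscapes`, `landscape_id` (per trajectory), `phase`, `params`,
#'   `seed`.
#' @export
run_batch <- function(phase, params, n_landscapes, trials_per_landscape = 1L,
                      seed = NULL, kind = phase$landscape_kind) {
  if (n_landscapes < 1L) stop("'n_landscapes' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  land_seeds <- sample.int(.Machine$integer.max - 1L, n_landscapes)
  trial_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   n_landscapes * trials_per_landscape),
                        nrow = n_landscapes)
  one_d <- phase$dims[1L] == 1L
  landscapes <- lapply(land_seeds, function(s) {
    if (one_d) generate_1d_landscape(kind = kind, seed = s)
    else generate_landscape(dims = phase$dims, kind = kind, seed = s)
  })
  trajectories <- vector("list", n_landscapes * trials_per_landscape)
  landscape_id <- integer(length(trajectories))
  t <- 0L
  for (i in seq_len(n_landscapes)) {
    for (j in seq_len(trials_per_landscape)) {
      t <- t + 1L
      trajectories[[t]] <- run_trial(phase, params, landscapes[[i]],
                                     seed = trial_seeds[i, j])
      landscape_id[t] <- i
    }
  }
  structure(list(trajectories = trajectories, landscapes = landscapes,
                 landscape_id = landscape_id, phase = phase, params = params,
                 seed = seed),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  rw <- vapply(x$trajectories, attr, numeric(1), "normalized_reward")
  cat(sprintf("<trajectory_set> %d trajectories on %d %s landscape(s), %s phase\n",
              length(x$trajectories), length(x$landscapes),
              x$landscapes[[1]]$kind, x$phase$phase))
  cat(sprintf("  mean normalized reward = %.3f\n", mean(rw, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  dfs <- lapply(seq_along(x$trajectories), function(i) {
    tr <- x$trajectories[[i]]
    cbind(data.frame(trial_id = i, phase = attr(tr, "phase"),
                     landscape_id = x$landscape_id[i]),
          as.data.frame(unclass(tr), stringsAsFactors = FALSE))
  })
  do.call(rbind, dfs)
}

#' Write / read a trajectory set as CSV plus JSON manifest
#'
#' Columns: `trial_id, phase, landscape_id, round, row, col, payoff, x_best,
#' p_best_row, p_best_col, R, deciding_cue, noise_flag`; `R` is empty while
#' no finite excursion budget is active. The manifest (`<path>.manifest.json`)
#' records the phase, parameters, master seed and per-trajectory metadata;
#' the landscapes are written alongside as `<path>.landscape<i>.csv`.
#'
#' @param set a `trajectory_set`.
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(set, path) {
  df <- as.data.frame(set)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  for (i in seq_along(set$landscapes))
    write_landscape(set$landscapes[[i]], paste0(path, sprintf(".landscape%d.csv", i)))
  manifest <- list(
    phase = unclass(set$phase),
    params = unclass(set$params)[!vapply(unclass(set$params), is.function, logical(1))],
    master_seed = set$seed,
    n_trajectories = length(set$trajectories),
    landscape_id = set$landscape_id,
    trial_seeds = vapply(set$trajectories,
                         function(tr) attr(tr, "seed") %||% NA_integer_, numeric(1)),
    rewards = vapply(set$trajectories, attr, numeric(1), "reward"),
    package_version = as.character(utils::packageVersion("ttbsearch")))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  manifest_path <- paste0(path, ".manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  phase <- if (!is.null(manifest)) {
    pc <- phase_config(manifest$phase$phase, manifest$phase$landscape_kind,
                       manifest$phase$rounds)
    pc
  } else phase_config(df$phase[1])
  ids <- unique(df$trial_id)
  landscape_files <- paste0(path, sprintf(".landscape%d.csv",
                                          seq_len(max(df$landscape_id))))
  landscapes <- if (all(file.exists(landscape_files)))
    lapply(landscape_files, read_landscape) else NULL
  trajectories <- lapply(ids, function(id) {
    tr <- df[df$trial_id == id,
             c("round", "row", "col", "payoff", "x_best", "p_best_row",
               "p_best_col", "R", "deciding_cue", "noise_flag")]
    rownames(tr) <- NULL
    land_id <- df$landscape_id[df$trial_id == id][1]
    land_max <- if (!is.null(landscapes)) max(landscapes[[land_id]]$payoffs) else NA
    reward <- if (phase$reward_rule == "highest_payoff") max(tr$x_best)
              else tr$payoff[nrow(tr)]
    structure(tr, class = c("trajectory", "data.frame"),
              reward = reward,
              normalized_reward = if (!is.na(land_max) && land_max > 0)
                reward / land_max else NA_real_,
              landscape_max = land_max,
              landscape_kind = if (!is.null(landscapes))
                landscapes[[land_id]]$kind else NA_character_,
              phase = df$phase[df$trial_id == id][1])
  })
  structure(list(trajectories = trajectories, landscapes = landscapes,
                 landscape_id = df$landscape_id[!duplicated(df$trial_id)],
                 phase = phase, params = NULL,
                 seed = manifest$master_seed),
            class = "trajectory_set")
}
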