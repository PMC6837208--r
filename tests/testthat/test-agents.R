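test_that("parameter presets carry the per-phase reference values", {
  p <- agent_params()
  expect_equal(p$epsilon, 0.17)
  expect_equal(c(p$k, p$l, p$mu, p$sigma2), c(0.0051, -0.027, 0.806, 0.364))
  pc <- agent_params(preset = "combined")
  expect_equal(c(pc$k, pc$l, pc$mu, pc$sigma2), c(0.011, -0.022, 0.386, 0.275))
  expect_equal(c(p$beta0, p$beta1), c(-1.509, 0.301))
  expect_equal(agent_params("random")$epsilon, 0)
  expect_error(agent_params(epsilon = 1.5), "epsilon")
  expect_error(agent_params(sigma2 = 0), "sigma2")
})

test_that("the optimal exploration range is floor(t_left / 2)", {
  expect_identical(d_optimal(30L), 15L)
  expect_identical(d_optimal(5L), 2L)
  expect_identical(d_optimal(0L), 0L)
  expect_error(d_optimal(-1L), "non-negative")
})

test_that("range draws follow the sequential stop/ignore/return rule", {
  p <- agent_params("ttb", "returning")
  # deterministic return branch with a pinned safety level
  pf <- p; pf$k <- 0; pf$ignore_zero <- TRUE; pf$s0_fixed <- 0.8
  d <- draw_exploration_range(50L, 20L, pf)
  expect_identical(d$branch, "return")
  expect_equal(d$R, 0.8 * 10)
  # x_best = 0: the ignore probability clips to 1 under the defaults
  p0 <- p; p0$k <- 0
  set.seed(1)
  expect_true(all(replicate(50, draw_exploration_range(0L, 20L, p0)$branch) == "ignore"))
  # branch frequencies at x_best = 50: (0.255, 0, 0.745), and the safety
  # draws match the closed-form truncated-normal moments
  set.seed(2)
  n <- 100000L
  draws <- replicate(n, {
    d <- draw_exploration_range(50L, 20L, p)
    c(stop = d$branch == "stop", ignore = d$branch == "ignore", s0 = d$s0)
  })
  p_stop <- mean(draws[1, ]); p_ign <- mean(draws[2, ])
  expect_lt(abs(p_stop - 0.255), 3 * sqrt(0.255 * 0.745 / n))
  expect_identical(p_ign, 0) # clip(1 - 1.35) = 0
  s0 <- draws[3, !is.na(draws[3, ])]
  mom <- truncnorm_moments(0.806, sqrt(0.364))
  expect_lt(abs(mean(s0) - mom["mean"]), 3 * sqrt(mom["var"] / length(s0)))
  expect_lt(abs(var(s0) - mom["var"]), 0.02)
})

test_that("exploitation variants configure the effective machinery", {
  pn <- agent_params("ttb", "normative")
  expect_identical(pn$k, 0)
  expect_true(pn$ignore_zero)
  expect_identical(pn$s0_fixed, 1)
  set.seed(3)
  expect_true(all(replicate(200, draw_exploration_range(5L, 20L, pn)$R) == 10))
  # simple returning never ignores, even at x_best where ignoring dominates
  ps <- agent_params("ttb", "simple_returning")
  set.seed(4)
  expect_false(any(replicate(1000, draw_exploration_range(5L, 20L, ps)$branch) == "ignore"))
  # free-parameter counts of the exploitation component
  counts <- vapply(c("returning", "simple_returning", "early_stop", "normative"),
                   function(w) ttbsearch:::n_free_params(
                     agent_params("ttb", w), "exploitation"), integer(1))
  expect_identical(unname(counts), c(4L, 3L, 0L, 0L))
  explo <- vapply(c("ttb", "probabilistic", "hill_climbing", "blind", "random"),
                  function(w) ttbsearch:::n_free_params(
                    agent_params(w, "none"), "exploration"), integer(1))
  expect_identical(unname(explo), c(1L, 2L, 0L, 0L, 0L))
})

test_that("a fresh noiseless searcher opens with a diagonal move", {
  ph <- phase_config("exploration")
  p <- agent_params("ttb", "none", epsilon = 0)
  land <- zero_landscape()
  set.seed(5)
  for (i in 1:10) {
    tr <- run_trial(ph, p, land)
    expect_identical(abs(tr$row[2] - 32L), 1L)
    expect_identical(abs(tr$col[2] - 32L), 1L)
    # all four diagonals tie at novelty 5, so the tie-break decides among them
    expect_identical(tr$deciding_cue[2], "random_tiebreak")
  }
})

test_that("noiseless search never revisits while unvisited options remain", {
  ph <- phase_config("exploration")
  p <- agent_params("ttb", "none", epsilon = 0)
  land <- generate_landscape(kind = "poor", seed = 6)
  for (s in 1:10) {
    tr <- run_trial(ph, p, land, seed = s)
    # in the 63x63 interior an unvisited neighbour always exists
    expect_identical(nrow(unique(tr[, c("row", "col")])), 31L)
    expect_true(all(diff(tr$x_best) >= 0L))
  }
})

test_that("with a stop budget and an exhausted neighbourhood the agent settles", {
  ph <- phase_config("exploration")
  land <- generate_landscape(kind = "poor", seed = 7)
  p <- agent_params("ttb", "returning", epsilon = 0)
  state <- init_search_state(ph, land, p)
  pb <- c(40L, 40L)
  state$position <- pb
  state$visited[as.vector(outer((38:42 - 1L) * 63L, 38:42, "+"))] <- TRUE # whole 5x5 block
  state$visited[(pb[2] - 1L) * 63L + pb[1]] <- TRUE
  state$seen[state$visited] <- TRUE
  state$x_best <- land$payoffs[pb[1], pb[2]]
  state$p_best <- pb
  state$branch <- "stop"; state$R0 <- 1
  res <- step_full_model(state, land, ph, p)
  expect_true(res$decision$is_stay ||
                max(abs(c(res$decision$row, res$decision$col) - pb)) <= 1)
  # when p_best strictly dominates its ball, the pay-off cue keeps it there
  land2 <- zero_landscape()
  land2$payoffs[pb[1], pb[2]] <- 10L
  land2$scale_max <- 10L
  state$x_best <- 10L
  res2 <- step_full_model(state, land2, ph, p)
  expect_true(res2$decision$is_stay)
  expect_identical(res2$decision$deciding_cue, "payoff")
})

test_that("hill climbing is absorbed at a visible local maximum", {
  ph <- phase_config("exploration")
  land <- zero_landscape()
  land$payoffs[32, 33] <- 10L
  land$scale_max <- 10L
  p <- agent_params("hill_climbing", "none")
  for (s in 1:5) {
    tr <- run_trial(ph, p, land, seed = s)
    expect_identical(tr$row[2:31], rep(32L, 30))
    expect_identical(tr$col[2:31], rep(33L, 30))
    expect_true(all(diff(tr$payoff) >= 0L))
  }
})

test_that("the random model chooses uniformly among the legal options", {
  ph <- phase_config("exploration")
  p <- agent_params("random", "none")
  land <- zero_landscape()
  set.seed(10)
  moves <- do.call(rbind, lapply(1:300, function(i) {
    tr <- run_trial(ph, p, land)
    cbind(diff(tr$row), diff(tr$col))
  }))
  freq <- table(paste(moves[, 1], moves[, 2])) / nrow(moves)
  expect_identical(length(freq), 9L)
  se <- sqrt((1 / 9) * (8 / 9) / nrow(moves))
  expect_true(all(abs(freq - 1 / 9) < 3.5 * se))
})

test_that("the probabilistic variant pivots at the logistic midpoint", {
  expect_equal(prob_payoff_cue(1.509 / 0.301), 0.5, tolerance = 1e-12)
  expect_true(prob_payoff_cue(40) > prob_payoff_cue(5))
  # high neighbouring pay-off makes the pay-off cue the near-certain pick
  ph <- phase_config("exploration")
  land <- zero_landscape()
  land$payoffs[32, 33] <- 60L # p(payoff cue) ~ 1
  land$scale_max <- 60L
  p <- agent_params("probabilistic", "none")
  set.seed(11)
  first <- vapply(1:50, function(i) {
    tr <- run_trial(ph, p, land)
    tr$col[2] == 33L && tr$row[2] == 32L
  }, logical(1))
  expect_gt(mean(first), 0.9)
})

test_that("an epsilon-noise excursion outside the radius falls back towards the best", {
  ph <- phase_config("exploration")
  land <- zero_landscape()
  land$payoffs[32, 32] <- 10L
  land$scale_max <- 10L
  p <- agent_params("ttb", "returning", epsilon = 0)
  state <- init_search_state(ph, land, p)
  state$branch <- "return"; state$R0 <- 2; state$s0 <- 0.5
  state$position <- c(32L, 37L) # distance 5, outside the budget
  state$visited[(37L - 1L) * 63L + 32L] <- TRUE
  res <- step_full_model(state, land, ph, p)
  expect_identical(res$decision$deciding_cue, "radius")
  expect_identical(abs(res$decision$col - 32L), 4L) # one step closer
})
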