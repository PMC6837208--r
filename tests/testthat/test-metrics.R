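test_that("pay-off curves average normalized pay-offs per round", {
  # sitting on the global peak: both modes give a constant 1
  tr <- make_traj(rep(5L, 31), rep(5L, 31), rep(40L, 31), land_max = 40)
  expect_equal(payoff_curve(list(tr), "best_so_far"), rep(1, 30))
  expect_equal(payoff_curve(list(tr), "current"), rep(1, 30))
  # three-trajectory fixture against a hand-rolled mean
  tr1 <- make_traj(rep(1L, 31), 1:31, c(0:29, 29L), land_max = 50)
  tr2 <- make_traj(rep(1L, 31), rep(3L, 31), rep(10L, 31), land_max = 50)
  tr3 <- make_traj(rep(1L, 31), rep(4L, 31), rep(25L, 31), land_max = 50)
  by_hand <- (c(1:29, 29) / 50 + 10 / 50 + 25 / 50) / 3
  expect_equal(payoff_curve(list(tr1, tr2, tr3), "current"), by_hand)
  expect_error(payoff_curve(list()), "empty")
})

test_that("best-so-far curves are non-decreasing for every input", {
  set <- run_batch(phase_config("exploration"), agent_params("ttb", "none"),
                   5, 2, seed = 14, kind = "rich")
  for (tr in set$trajectories)
    expect_true(all(diff(payoff_curve(list(tr), "best_so_far")) >= 0))
})

test_that("density maps count occupancies exactly", {
  tr <- make_traj(rep(7L, 31), rep(9L, 31), rep(0L, 31), land_max = 1)
  dm <- density_map(list(tr), c(63L, 63L))
  expect_identical(dm[7, 9], 31L)
  expect_identical(sum(dm), 31L)
  set <- run_batch(phase_config("exploration"), agent_params("random", "none"),
                   2, 3, seed = 15)
  dm2 <- density_map(set, c(63L, 63L))
  expect_identical(sum(dm2), 31L * 6L)
  # per-cell tally oracle
  all_pos <- do.call(rbind, lapply(set$trajectories, function(t) t[, c("row", "col")]))
  tally <- table(paste(all_pos$row, all_pos$col))
  for (key in sample(names(tally), 20))
    expect_identical(dm2[as.integer(strsplit(key, " ")[[1]])[1],
                         as.integer(strsplit(key, " ")[[1]])[2]],
                     as.integer(tally[[key]]))
})

test_that("revisit fractions cover the self-avoiding and stationary extremes", {
  self_avoiding <- make_traj(rep(1L, 31), 1:31, rep(0L, 31), land_max = 1)
  expect_identical(revisit_fraction(self_avoiding), 0)
  stationary <- make_traj(rep(5L, 31), rep(5L, 31), rep(0L, 31), land_max = 1)
  expect_identical(revisit_fraction(stationary), 1)
})

test_that("decision classification matches hand-computed cases", {
  ph <- phase_config("exploration")
  land <- zero_landscape()
  # diagonal then stay on an all-zero landscape
  tr <- make_traj(c(32L, 33L, 33L), c(32L, 33L, 33L), rep(0L, 3), land_max = 1)
  cls <- classify_decisions(tr, land, ph)
  expect_identical(cls$toward_not_visited, c(TRUE, FALSE))
  expect_identical(cls$payoff_consistent, c(TRUE, FALSE))
  expect_identical(cls$cues_silent, c(TRUE, TRUE))
  # the diagonal reveals 5 new fields, the maximum; staying reveals none
  expect_identical(cls$novelty_consistent, c(TRUE, FALSE))
  # history mode additionally requires surviving the two-cue cascade
  cls_h <- classify_decisions(tr, land, ph, novelty_seen = "history")
  expect_identical(cls_h$novelty_consistent, c(TRUE, FALSE))
  # pay-off pulls the choice: moving onto a visible paying field is (b)-consistent
  land2 <- zero_landscape(); land2$payoffs[31, 31] <- 9L; land2$scale_max <- 9L
  tr2 <- make_traj(c(32L, 31L), c(32L, 31L), c(0L, 9L), land_max = 9)
  cls2 <- classify_decisions(tr2, land2, ph)
  expect_true(cls2$payoff_consistent[1])
  expect_false(cls2$cues_silent[1]) # the pay-off cue discriminates uniquely
})

test_that("noiseless take-the-best always moves to non-visited fields first", {
  set <- run_batch(phase_config("exploration"),
                   agent_params("ttb", "none", epsilon = 0), 4, 2, seed = 16)
  u <- cue_usage(set)
  expect_equal(unname(u["not_visited"]), 1)
  expect_true(all(u >= 0 & u <= 1))
  expect_lte(u["payoff"], u["not_visited"])
})

test_that("safety levels reproduce the narrated excursion example", {
  # best found at round 15 (position 15), explored 3 fields further, then
  # returned and settled: D_opt = 7, realized R = 3, S = 3/7
  cols <- c(1L, 1L, 2:15, 16L, 17L, 18L, 17L, 16L, 15L, rep(15L, 9))
  pay <- integer(31)
  pay[16] <- 10L # arrival at col 15 in round 15 (one early stay)
  tr <- make_traj(rep(1L, 31), cols, pay, land_max = 10,
                  phase = "exploitation", x_best = cummax(pay))
  recs <- safety_levels(tr)
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$discovery_round, 15L)
  expect_identical(recs$d_optimal, 7L)
  expect_identical(recs$realized_R, 3L)
  expect_equal(recs$S, 3 / 7)
  expect_identical(recs$censored, "none")
  # immediate settling gives S = 0
  cols2 <- c(1:10, rep(10L, 21))
  pay2 <- integer(31); pay2[10] <- 8L
  tr2 <- make_traj(rep(1L, 31), cols2, pay2, land_max = 8,
                   phase = "exploitation", x_best = cummax(pay2))
  recs2 <- safety_levels(tr2)
  expect_identical(recs2$realized_R, 0L)
  expect_equal(recs2$S, 0)
  # never returning is censored as no_return
  cols3 <- c(1:10, 11:31)
  pay3 <- integer(31); pay3[10] <- 8L
  tr3 <- make_traj(rep(1L, 31), cols3, pay3, land_max = 8,
                   phase = "exploitation", x_best = cummax(pay3))
  expect_identical(safety_levels(tr3)$censored, "no_return")
})

test_that("a noiseless normative searcher realizes S = 1 on every counted episode", {
  p <- agent_params("ttb", "normative", epsilon = 0)
  set <- run_batch(phase_config("exploitation"), p, 25, 2, seed = 17, kind = "rich")
  recs <- do.call(rbind, lapply(set$trajectories, safety_levels))
  unc <- recs[recs$censored == "none", ]
  expect_gt(nrow(unc), 20)
  expect_true(all(unc$S == 1))
  expect_false(any(recs$censored == "no_return"))
})

test_that("pay-off curve distances are squared differences summed over rounds", {
  a <- runif(30)
  expect_identical(dist_payoff(a, a), 0)
  expect_equal(dist_payoff(a, a + 0.1), 30 * 0.1^2)
  expect_equal(dist_payoff(list(poor = a, rich = a), list(a + 0.1, a)), 30 * 0.01)
  expect_error(dist_payoff(a, a[-1]), "length")
})

test_that("density distances are symmetric, zero at identity", {
  set.seed(18)
  a <- matrix(rpois(63 * 63, 1), 63, 63)
  b <- matrix(rpois(63 * 63, 1), 63, 63)
  expect_identical(dist_density(a, a), 0)
  expect_equal(dist_density(a, b), dist_density(b, a))
  expect_gt(dist_density(a, b), 0)
  expect_error(dist_density(a, b[-1, ]), "dimensions")
})

test_that("cross-validation folds partition the landscapes", {
  set <- run_batch(phase_config("exploration"), agent_params("ttb", "none"),
                   6, 2, seed = 19)
  res <- kfold_cv(set, agent_params("ttb", "none"), k = 3, seed = 20)
  fold_of <- attr(res, "fold_of")
  expect_identical(sort(unique(fold_of)), 1:3)
  expect_lte(diff(range(table(fold_of))), 1)
  expect_identical(length(fold_of), 6L)
  expect_identical(res$folds, 3L)
  expect_true(res$dist_payoff >= 0 && res$dist_density >= 0)
  expect_error(kfold_cv(set, agent_params(), k = 7), "at least")
})

test_that("cross-validation ranks the generating model above random search", {
  obs <- run_batch(phase_config("exploration"), agent_params("ttb", "none"),
                   10, 2, seed = 21, kind = "poor")
  res <- compare_models(obs, list(ttb = agent_params("ttb", "none"),
                                  random = agent_params("random", "none")),
                        k = 5, seed = 22)
  expect_lt(res$dist_payoff[res$name == "ttb"],
            res$dist_payoff[res$name == "random"])
})
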