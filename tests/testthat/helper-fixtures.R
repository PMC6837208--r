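# Shared fixtures and independent oracles, all built in code.

zero_landscape <- function(nr = 63L, nc = 63L) {
  ttbsearch:::as_landscape(matrix(0L, nr, nc))
}

flat_landscape <- function(values) ttbsearch:::as_landscape(values)

# Independent brute-force lexicographic argmax-filter oracle for the cue
# cascade: plain loops, no shared code with ttb_decide.
oracle_ttb <- function(cues) {
  surv <- seq_len(ncol(cues))
  for (i in seq_len(nrow(cues))) {
    best <- -Inf
    for (j in surv) if (cues[i, j] > best) best <- cues[i, j]
    keep <- integer(0)
    for (j in surv) if (cues[i, j] == best) keep <- c(keep, j)
    surv <- keep
    if (length(surv) == 1L) return(list(survivors = surv, cue = i))
  }
  list(survivors = surv, cue = NA_integer_)
}

# Direct dense 2-D convolution oracle (zero padding), quadratic loops.
oracle_conv2 <- function(m, k2) {
  r <- (nrow(k2) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m))
        acc <- acc + m[ii, jj] * k2[di + r + 1L, dj + r + 1L]
    }
    out[i, j] <- acc
  }
  out
}

# Hand-built trajectory object for metric unit tests.
make_traj <- function(rows, cols, payoffs, land_max, phase = "exploration",
                      x_best = cummax(payoffs), reward = NULL) {
  n <- length(rows)
  df <- data.frame(round = 0:(n - 1L), row = rows, col = cols,
                   payoff = payoffs, x_best = x_best,
                   p_best_row = NA_integer_, p_best_col = NA_integer_,
                   R = NA_real_, deciding_cue = NA_character_,
                   noise_flag = FALSE, stringsAsFactors = FALSE)
  structure(df, class = c("trajectory", "data.frame"),
            reward = reward %||% max(x_best),
            normalized_reward = (reward %||% max(x_best)) / land_max,
            landscape_max = land_max, landscape_kind = "custom",
            phase = phase, params = NULL, seed = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form moments of a normal(mu, sd) truncated to (0, 1).
truncnorm_moments <- function(mu, sd) {
  a <- (0 - mu) / sd; b <- (1 - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mu + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z - ((dnorm(a) - dnorm(b)) / Z)^2)
  c(mean = m, var = v)
}

# Trajectory-wide legality check: consecutive positions differ by a legal
# step and stay in bounds.
expect_legal_moves <- function(tr, dims) {
  dr <- diff(tr$row); dc <- diff(tr$col)
  expect_true(all(pmax(abs(dr), abs(dc)) <= 1L))
  expect_true(all(tr$row >= 1L & tr$row <= dims[1L]))
  expect_true(all(tr$col >= 1L & tr$col <= dims[2L]))
}
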