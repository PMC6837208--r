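# Option sets and the four decision cues.
#
# Positions are 1-based (row, col); a grid cell's linear index is
# (col - 1) * nrows + row (column-major, matching R matrices). An option is a
# candidate target field: staying put or moving to one in-bounds Moore
# neighbour (8 in the 2-D interior, 2 in the 1-D interior).

moore_offsets <- function(dims) {
  if (dims[1L] > 1L) {
    cbind(dr = rep(-1:1, times = 3), dc = rep(-1:1, each = 3))
  } else {
    cbind(dr = c(0L, 0L, 0L), dc = -1:1)
  }
}

#' Enumerate the legal options at a position
#'
#' The legal options are the current field (stay) plus every in-bounds Moore
#' neighbour. In a 1-D landscape the neighbourhood is the two adjacent fields.
#'
#' @param position 1-based `c(row, col)`.
#' @param dims grid dimensions `c(rows, cols)`.
#' @param forbid_stay drop the stay option (used for the first round of the
#'   exploitation phase, where only a move to the right is allowed together
#'   with `forbid_left`).
#' @param forbid_left drop options moving to a lower column index.
#' @return A list with parallel vectors `row`, `col`, `idx` (linear index),
#'   `is_stay`.
#' @export
legal_options <- function(position, dims, forbid_stay = FALSE, forbid_left = FALSE) {
  position <- as.integer(position)
  nr <- as.integer(dims[1L]); nc <- as.integer(dims[2L])
  if (position[1L] < 1L || position[1L] > nr || position[2L] < 1L || position[2L] > nc)
    stop("position out of bounds", call. = FALSE)
  offs <- moore_offsets(dims)
  rows <- position[1L] + offs[, 1L]
  cols <- position[2L] + offs[, 2L]
  keep <- rows >= 1L & rows <= nr & cols >= 1L & cols <= nc
  if (forbid_stay) keep <- keep & !(offs[, 1L] == 0L & offs[, 2L] == 0L)
  if (forbid_left) keep <- keep & offs[, 2L] >= 0L
  rows <- rows[keep]; cols <- cols[keep]
  list(row = rows, col = cols, idx = (cols - 1L) * nr + rows,
       is_stay = offs[keep, 1L] == 0L & offs[keep, 2L] == 0L)
}

#' Decision cues
#'
#' The four cues of the cascade, each evaluated for a set of options:
#' `cue_not_visited` is 1 for options whose target has never been occupied;
#' `cue_payoff` is the pay-off at the target; `cue_novelty` counts how many
#' fields of the target's visible neighbourhood (3 x 3 in 2-D, 3 cells in
#' 1-D) have never been on screen (not in the seen set); `cue_in_radius` is 1
#' for targets within distance `R` of the best position found so far
#' (Chebyshev distance in 2-D, `|dx|` in 1-D). With no best position yet
#' (`p_best = NULL`) or `R = Inf` the radius cue is inert and returns 1 for
#' every option.
#'
#' @param options as returned by [legal_options()].
#' @param visited,seen logical vectors over linear cell indices.
#' @param landscape a `landscape`.
#' @param dims grid dimensions.
#' @param p_best 1-based `c(row, col)` of the best discovered pay-off, or
#'   `NULL`.
#' @param R exploration radius (`Inf` allowed).
#' @return An integer vector, one value per option.
#' @export
cue_not_visited <- function(options, visited) {
  as.integer(!visited[options$idx])
}

#' @rdname cue_not_visited
#' @export
cue_payoff <- function(options, landscape) {
  as.integer(landscape$payoffs[options$idx])
}

#' @rdname cue_not_visited
#' @export
cue_novelty <- function(options, seen, dims) {
  novelty_counts(options$row, options$col, seen, dims)
}

novelty_counts <- function(rows, cols, seen, dims) {
  nr <- dims[1L]; nc <- dims[2L]
  offs <- moore_offsets(dims)
  n <- integer(length(rows))
  for (k in seq_len(nrow(offs))) {
    r2 <- rows + offs[k, 1L]
    c2 <- cols + offs[k, 2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    n[ok] <- n[ok] + !seen[(c2[ok] - 1L) * nr + r2[ok]]
  }
  n
}

#' @rdname cue_not_visited
#' @export
cue_in_radius <- function(options, p_best, R, dims) {
  if (is.null(R) || length(R) == 0L) R <- Inf
  if (R < 0) stop("negative exploration radius", call. = FALSE)
  if (is.null(p_best) || is.infinite(R))
    return(rep(1L, length(options$idx)))
  as.integer(chebyshev_dist(options$row, options$col, p_best[1L], p_best[2L]) <= R)
}

chebyshev_dist <- function(r1, c1, r2, c2) pmax(abs(r1 - r2), abs(c1 - c2))

#' Take-the-best decision over a cue table
#'
#' Lexicographic subset-filtering cascade. With probability `epsilon` the
#' decision is uniform noise over all options. Otherwise the cues are examined
#' one at a time in row order: at each cue only the options attaining the
#' maximal cue value among the current survivors are retained; as soon as a
#' single option survives, that cue decides. If several options survive the
#' whole cascade, one is drawn uniformly (random tie-break). Binary cues
#' discriminate only when both values are present: if every survivor scores 0
#' the cue retains all of them.
#'
#' @param cues numeric matrix, one row per cue in cascade order (rownames name
#'   the cues), one column per option.
#' @param epsilon probability in `[0, 1]` of a uniformly random choice.
#' @return A list with `choice` (column index of the chosen option),
#'   `deciding_cue` (a cue name, `"random_tiebreak"` or `"noise"`) and
#'   `survivors` (column indices alive when the decision fell).
#' @examples
#' cues <- rbind(not_visited = c(1, 1, 0), payoff = c(3, 7, 9))
#' ttb_decide(cues)$choice  # option 2: option 3 is eliminated first
#' @export
ttb_decide <- function(cues, epsilon = 0) {
  m <- ncol(cues)
  if (is.null(m) || m == 0L) stop("empty option set", call. = FALSE)
  if (epsilon < 0 || epsilon > 1) stop("'epsilon' must be in [0, 1]", call. = FALSE)
  if (epsilon > 0 && stats::runif(1L) < epsilon) {
    return(list(choice = sample_one(seq_len(m)), deciding_cue = "noise",
                survivors = seq_len(m)))
  }
  cue_names <- rownames(cues)
  if (is.null(cue_names)) cue_names <- paste0("cue", seq_len(nrow(cues)))
  surv <- seq_len(m)
  for (i in seq_len(nrow(cues))) {
    v <- cues[i, surv]
    surv <- surv[v == max(v)]
    if (length(surv) == 1L)
      return(list(choice = surv, deciding_cue = cue_names[i], survivors = surv))
  }
  list(choice = sample_one(surv), deciding_cue = "random_tiebreak",
       survivors = surv)
}

# sample() with length-1 x would sample from 1:x; this never does.
sample_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
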