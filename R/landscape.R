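# Discrete Gaussian kernel sampled at integer offsets, truncated at radius
# ceiling(4*sigma) and normalized to sum 1 (zero loss of mass by renormalization).
gaussian_kernel <- function(sigma = 1) {
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# Separable 2-D convolution with a symmetric 1-D kernel, constant-zero padding.
# Used both by the sub-landscape generator and as the reference path the
# impulse fast path is tested against.
conv2_sep <- function(m, kernel) {
  r <- (length(kernel) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  # along rows (vertical direction)
  tmp <- matrix(0, nr, nc)
  for (d in -r:r) {
    w <- kernel[d + r + 1L]
    src_rows <- max(1L, 1L + d):min(nr, nr + d)
    dst_rows <- src_rows - d
    tmp[dst_rows, ] <- tmp[dst_rows, ] + w * m[src_rows, ]
  }
  # along columns (horizontal direction)
  out <- matrix(0, nr, nc)
  for (d in -r:r) {
    w <- kernel[d + r + 1L]
    src_cols <- max(1L, 1L + d):min(nc, nc + d)
    dst_cols <- src_cols - d
    out[, dst_cols] <- out[, dst_cols] + w * tmp[, src_cols]
  }
  out
}

#' Generate one single-peak sub-landscape
#'
#' A sub-landscape is an all-zero matrix except for one uniformly chosen field
#' holding `z^2` with `z ~ N(0, 1)` (squared to avoid negative pay-offs), then
#' smoothed with an isotropic discrete Gaussian filter of standard deviation
#' `sigma` (zero padding at the borders). The smoothed bump is the local
#' gradient an agent can climb towards the peak.
#'
#' @param dims integer vector `c(rows, cols)`, both at least 3.
#' @param sigma standard deviation of the Gaussian filter (default 1).
#' @return A numeric `rows x cols` matrix, non-negative everywhere, with
#'   attributes `peak` (1-based `c(row, col)` of the impulse) and `peak_value`
#'   (the pre-filter value `z^2`).
#' @export
generate_sublandscape <- function(dims, sigma = 1) {
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims < 3L))
    stop("'dims' must be two integers >= 3", call. = FALSE)
  nr <- dims[1L]; nc <- dims[2L]
  cell <- sample.int(nr * nc, 1L)
  z <- stats::rnorm(1L)
  m <- matrix(0, nr, nc)
  m[cell] <- z^2
  out <- conv2_sep(m, gaussian_kernel(sigma))
  attr(out, "peak") <- c(row = ((cell - 1L) %% nr) + 1L,
                         col = ((cell - 1L) %/% nr) + 1L)
  attr(out, "peak_value") <- z^2
  out
}

# Fast path: a filtered impulse equals value * outer(kernel, kernel) centred on
# the impulse, clipped at the borders (zero padding). Draws the RNG in exactly
# the same order as generate_sublandscape so the two paths are interchangeable.
merge_sublandscapes_fast <- function(dims, n_peaks, sigma = 1) {
  nr <- dims[1L]; nc <- dims[2L]
  kernel <- gaussian_kernel(sigma)
  r <- (length(kernel) - 1L) / 2L
  merged <- matrix(0, nr, nc)
  for (i in seq_len(n_peaks)) {
    cell <- sample.int(nr * nc, 1L)
    z <- stats::rnorm(1L)
    pr <- ((cell - 1L) %% nr) + 1L
    pc <- ((cell - 1L) %/% nr) + 1L
    rows <- max(1L, pr - r):min(nr, pr + r)
    cols <- max(1L, pc - r):min(nc, pc + r)
    patch <- outer(z^2 * kernel[rows - pr + r + 1L], kernel[cols - pc + r + 1L])
    merged[rows, cols] <- pmax(merged[rows, cols], patch)
  }
  merged
}

#' Generate a pay-off landscape
#'
#' Generates `n_peaks` single-peak sub-landscapes, merges them by taking the
#' element-wise maximum, linearly rescales the merged surface so that its
#' minimum maps to 0 and its maximum to `scale_max` (an integer drawn
#' uniformly from 30..80 unless supplied), and rounds to the nearest integer.
#' Scaling precedes rounding so that pay-offs are integers with the maximum
#' exactly `scale_max`. The presets `n_peaks = 32` and `n_peaks = 512`
#' correspond to poor and rich landscapes.
#'
#' @param dims `c(rows, cols)` grid size (default `c(63, 63)`).
#' @param n_peaks number of sub-landscapes (peaks) to merge; at least 1.
#' @param kind optional label; `"poor"` and `"rich"` imply `n_peaks` 32 and
#'   512, `"custom"` leaves `n_peaks` as given.
#' @param scale_max optional integer in 30..80; drawn uniformly if `NULL`.
#' @param seed optional integer seed; if supplied the global RNG is seeded so
#'   the landscape is reproducible in isolation.
#' @param sigma Gaussian filter standard deviation (default 1).
#' @return An object of class `landscape`: a list with `payoffs` (integer
#'   matrix), `n_peaks`, `scale_max`, `kind`, `seed` and `dims`.
#' @examples
#' land <- generate_landscape(kind = "poor", seed = 1)
#' max(land$payoffs) == land$scale_max
#' @export
generate_landscape <- function(dims = c(63L, 63L), n_peaks = NULL,
                               kind = c("custom", "poor", "rich"),
                               scale_max = NULL, seed = NULL, sigma = 1) {
  kind <- match.arg(kind)
  if (is.null(n_peaks))
    n_peaks <- switch(kind, poor = 32L, rich = 512L,
                      stop("supply 'n_peaks' or kind = 'poor'/'rich'", call. = FALSE))
  n_peaks <- as.integer(n_peaks)
  if (n_peaks < 1L) stop("'n_peaks' must be >= 1", call. = FALSE)
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims < 3L))
    stop("'dims' must be two integers >= 3", call. = FALSE)
  if (kind == "custom" && n_peaks %in% c(32L, 512L))
    kind <- if (n_peaks == 32L) "poor" else "rich"
  if (!is.null(seed)) set.seed(seed)
  merged <- merge_sublandscapes_fast(dims, n_peaks, sigma)
  if (is.null(scale_max)) scale_max <- sample(30:80, 1L)
  scale_max <- as.integer(scale_max)
  payoffs <- scale_payoffs(merged, scale_max)
  structure(list(payoffs = payoffs, n_peaks = n_peaks, scale_max = scale_max,
                 kind = kind, seed = seed, dims = dims),
            class = "landscape")
}

# Linear rescale (min -> 0, max -> scale_max) followed by rounding. Rounding
# cannot move the extremes because 0 and scale_max are already integers.
scale_payoffs <- function(m, scale_max) {
  rng <- range(m)
  if (rng[2] > rng[1]) {
    out <- round((m - rng[1]) / (rng[2] - rng[1]) * scale_max)
  } else {
    out <- round(m - rng[1]) # degenerate flat surface -> all zero
  }
  storage.mode(out) <- "integer"
  out
}

#' Generate a 1-D pay-off landscape
#'
#' Draws one uniformly chosen horizontal line from a freshly generated
#' 2-D landscape of the same kind, giving a `1 x 63` (by default) vector
#' landscape for the exploitation phase.
#'
#' @inheritParams generate_landscape
#' @param parent_dims dimensions of the parent 2-D landscape.
#' @return A `landscape` whose `payoffs` is a `1 x cols` integer matrix;
#'   `parent_row` records which line was taken and `scale_max` is the
#'   parent's (the row maximum may be lower).
#' @export
generate_1d_landscape <- function(n_peaks = NULL, kind = c("custom", "poor", "rich"),
                                  parent_dims = c(63L, 63L), scale_max = NULL,
                                  seed = NULL, sigma = 1) {
  parent <- generate_landscape(parent_dims, n_peaks, kind, scale_max, seed, sigma)
  row <- sample.int(parent$dims[1L], 1L)
  out <- parent
  out$payoffs <- parent$payoffs[row, , drop = FALSE]
  out$dims <- c(1L, parent$dims[2L])
  out$parent_row <- row
  out
}

#' Normalize a pay-off against a landscape's maximum
#'
#' The normalized pay-off of a solution is its pay-off divided by the highest
#' pay-off of the landscape.
#'
#' @param landscape a `landscape` object.
#' @param payoff integer pay-off value(s).
#' @return Numeric value(s) in `[0, 1]`.
#' @export
normalize_payoff <- function(landscape, payoff) {
  m <- max(landscape$payoffs)
  if (m <= 0)
    stop("normalization undefined for an all-zero landscape", call. = FALSE)
  payoff / m
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d, kind = %s, n_peaks = %d, scale_max = %d\n",
              x$dims[1], x$dims[2], x$kind, x$n_peaks, x$scale_max))
  cat(sprintf("  pay-offs: integers in [%d, %d], %d non-zero fields\n",
              min(x$payoffs), max(x$payoffs), sum(x$payoffs > 0)))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' @export
plot.landscape <- function(x, ...) {
  graphics::image(t(x$payoffs)[, rev(seq_len(nrow(x$payoffs))), drop = FALSE],
                  axes = FALSE, asp = nrow(x$payoffs) / ncol(x$payoffs),
                  main = sprintf("%s landscape (max = %d)", x$kind, x$scale_max), ...)
  invisible(x)
}

#' Write / read a landscape as CSV plus JSON sidecar
#'
#' The pay-off matrix is written as a plain integer CSV (one line per grid
#' row, no header); generation metadata goes to `<path>.json`. Coordinates
#' throughout the package are 1-based `(row, col)`.
#'
#' @param landscape a `landscape`.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `write_landscape` the path, invisibly; `read_landscape` a
#'   `landscape`.
#' @export
write_landscape <- function(landscape, path) {
  utils::write.table(landscape$payoffs, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(n_peaks = landscape$n_peaks, scale_max = landscape$scale_max,
               kind = landscape$kind, seed = landscape$seed,
               dims = landscape$dims, coordinate_convention = "1-based")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  payoffs <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(payoffs) <- NULL
  storage.mode(payoffs) <- "integer"
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  structure(list(payoffs = payoffs,
                 n_peaks = meta$n_peaks %||% NA_integer_,
                 scale_max = meta$scale_max %||% max(payoffs),
                 kind = meta$kind %||% "custom",
                 seed = meta$seed,
                 dims = dim(payoffs)),
            class = "landscape")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap a bare pay-off matrix (e.g. an all-zero test surface) as a landscape.
as_landscape <- function(payoffs, kind = "custom") {
  payoffs <- as.matrix(payoffs)
  dimnames(payoffs) <- NULL
  storage.mode(payoffs) <- "integer"
  structure(list(payoffs = payoffs, n_peaks = NA_integer_,
                 scale_max = max(payoffs), kind = kind, seed = NULL,
                 dims = dim(payoffs)),
            class = "landscape")
}
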