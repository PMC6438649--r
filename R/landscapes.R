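#' Fitness-valley specification
#'
#' A valley is a piecewise-linear height profile over path positions
#' `0..l1+l2`: from the left peak at height `d1` the fitness falls linearly
#' to 0 at position `l1` (the valley bottom) and then rises linearly to `d2`
#' at position `l1 + l2`.  The ratios `d1/l1` and `d2/l2` are the slopes of
#' the two flanks.
#'
#' @param l1 Length of the descending slope (integer, at least 2).
#' @param l2 Length of the ascending slope (integer, at least 2).
#' @param d1 Height of the left peak (positive).
#' @param d2 Height of the right peak (positive); `d2 >= d1` so that the
#'   right peak is the optimum.
#' @return An object of class `"valley_spec"` with fields `l1`, `l2`, `d1`,
#'   `d2` and the total length `l = l1 + l2`.
#' @examples
#' valley(2, 2, 1, 2)
#' @export
valley <- function(l1, l2, d1, d2) {
  stopifnot(length(l1) == 1, length(l2) == 1, length(d1) == 1, length(d2) == 1)
  l1 <- as.integer(l1); l2 <- as.integer(l2)
  if (is.na(l1) || l1 < 2) stop("'l1' must be an integer >= 2")
  if (is.na(l2) || l2 < 2) stop("'l2' must be an integer >= 2")
  if (!is.finite(d1) || d1 <= 0) stop("'d1' must be positive")
  if (!is.finite(d2) || d2 <= 0) stop("'d2' must be positive")
  if (d1 > d2) stop("'d1' must not exceed 'd2' (the right peak is the optimum)")
  structure(list(l1 = l1, l2 = l2, d1 = d1, d2 = d2, l = l1 + l2),
            class = "valley_spec")
}

#' @export
print.valley_spec <- function(x, ...) {
  cat(sprintf("Valley: l1 = %d, l2 = %d, d1 = %g, d2 = %g (length %d, effective length %d)\n",
              x$l1, x$l2, x$d1, x$d2, x$l, effective_length(x)))
  invisible(x)
}

#' Valley height at a path position
#'
#' @param spec A [valley()] specification.
#' @param i Position(s) in `0..l1+l2` (vectorised).
#' @return `d1 - i*d1/l1` on the descending flank (`i <= l1`), and
#'   `(i - l1)*d2/l2` on the ascending flank.
#' @examples
#' valley_height(valley(2, 2, 1, 2), 0:4)
#' @export
valley_height <- function(spec, i) {
  stopifnot(inherits(spec, "valley_spec"), is.numeric(i))
  if (any(i < 0 | i > spec$l)) {
    stop(sprintf("position out of range [0, %d]", spec$l))
  }
  ifelse(i <= spec$l1,
         spec$d1 - i * spec$d1 / spec$l1,
         (i - spec$l1) * spec$d2 / spec$l2)
}

#' Effective length of a valley
#'
#' The distance from the starting peak to the first valley position of at
#' least equal fitness: `l* = l1 + ceiling(d1 * l2 / d2)`.  An elitist
#' searcher has to jump at least this far in one mutation, so its expected
#' crossing time scales as `n^(l*)`.
#'
#' @param spec A [valley()] specification.
#' @return The effective length, an integer in `[l1 + 1, l1 + l2]`.
#' @examples
#' effective_length(valley(2, 2, 1, 2))  # 3
#' @export
effective_length <- function(spec) {
  stopifnot(inherits(spec, "valley_spec"))
  as.integer(spec$l1 + ceiling(spec$d1 * spec$l2 / spec$d2))
}

#' Chain-of-valleys specification
#'
#' `m` copies of the same valley glued end to end, each shifted upwards by
#' `d2 - d1` relative to its predecessor so that consecutive peaks have
#' strictly increasing heights and the global optimum sits at global
#' position `m * (l1 + l2)`.  Requires `d1 < d2` strictly.
#'
#' @param m Number of valleys (positive integer).
#' @param spec A [valley()] specification with `d1 < d2`.
#' @return An object of class `"valleypath_spec"`.
#' @examples
#' valleypath(3, valley(2, 2, 2, 4))
#' @export
valleypath <- function(m, spec) {
  stopifnot(length(m) == 1, inherits(spec, "valley_spec"))
  m <- as.integer(m)
  if (is.na(m) || m < 1) stop("'m' must be a positive integer")
  if (spec$d1 >= spec$d2) {
    stop("a chain of valleys requires 'd1' < 'd2' (increasing peaks)")
  }
  structure(list(m = m, valley = spec), class = "valleypath_spec")
}

#' @export
print.valleypath_spec <- function(x, ...) {
  cat(sprintf("ValleyPath: %d valleys of ", x$m))
  print(x$valley)
  invisible(x)
}

#' Height within a given valley of a chain of valleys
#'
#' Valley `j` (1-based) contributes an offset `j * (d2 - d1)` on top of the
#' single-valley profile.  The profile is continuous at valley boundaries:
#' position `l` of valley `j` has the same height as position 0 of valley
#' `j + 1`.
#'
#' @param spec A [valleypath()] specification.
#' @param j Valley index in `1..m`.
#' @param i Within-valley position in `0..l1+l2` (vectorised).
#' @return Numeric height(s).
#' @export
valleypath_height <- function(spec, j, i) {
  stopifnot(inherits(spec, "valleypath_spec"))
  if (any(j < 1 | j > spec$m)) stop(sprintf("valley index out of range [1, %d]", spec$m))
  v <- spec$valley
  j * (v$d2 - v$d1) + valley_height(v, i)
}

#' Flattened height profile of a chain of valleys
#'
#' Maps global positions `0..m*l` to heights.  A boundary position belongs
#' to both adjoining valleys; the flattening assigns it to the earlier
#' valley (`j = ceiling(g/l)` clamped to `[1, m]`), which is value-neutral
#' because the profile is continuous there.
#'
#' @param spec A [valleypath()] specification.
#' @return Numeric vector of length `m*l + 1`; element `g + 1` is the height
#'   at global position `g`.
#' @export
global_heights <- function(spec) {
  stopifnot(inherits(spec, "valleypath_spec"))
  v <- spec$valley
  g <- 0:(spec$m * v$l)
  j <- pmin(pmax(ceiling(g / v$l), 1), spec$m)
  i <- g - (j - 1) * v$l
  valleypath_height(spec, j, i)
}

#' Peaks and minima of a chain of valleys
#'
#' @param spec A [valleypath()] specification.
#' @return A list with `peaks` (global indices `j*l`, `j = 0..m`, the `m+1`
#'   local maxima) and `minima` (global indices `(j-1)*l + l1`,
#'   `j = 1..m`, the `m` local minima).
#' @export
enumerate_extrema <- function(spec) {
  stopifnot(inherits(spec, "valleypath_spec"))
  v <- spec$valley
  list(peaks = (0:spec$m) * v$l,
       minima = (seq_len(spec$m) - 1) * v$l + v$l1)
}
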