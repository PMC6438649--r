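#' Long k-path specification
#'
#' A long k-path is a recursively defined sequence of bit strings of length
#' `n` forming a Hamming path: consecutive points differ in exactly one bit,
#' while any "shortcut" between points that are `k` or more positions apart
#' on the path requires flipping at least `k` bits simultaneously.  The path
#' of dimension `n` is built from the path of dimension `n - k` by prepending
#' `0^k` to it (front section), appending a bridge of `k - 1` points that
#' turn the leading block from `0^k` into `1^k` one bit at a time, and then
#' prepending `1^k` to the reversed sub-path (back section).  Its length is
#' `k * 2^(n/k) - k + 1`, exponential in `n` for `k = Theta(sqrt(n))`.
#'
#' @param n Dimension of the bit strings.  Must be a non-negative multiple
#'   of `k`; `n = 0` gives the degenerate path holding only the empty string.
#' @param k Fold parameter, a positive integer.
#' @return An object of class `"long_k_path"` with elements `n` and `k`.
#' @seealso [path_length()], [build_path()], [index_of()],
#'   [verify_hamming_property()], [embed_fitness()]
#' @examples
#' spec <- long_k_path(9, 3)
#' path_length(spec)  # 22
#' @export
long_k_path <- function(n, k) {
  stopifnot(length(n) == 1, length(k) == 1, is.numeric(n), is.numeric(k))
  n <- as.integer(n)
  k <- as.integer(k)
  if (is.na(n) || n < 0) stop("'n' must be a non-negative integer")
  if (is.na(k) || k < 1) stop("'k' must be a positive integer")
  if (n > 0 && n %% k != 0) {
    stop(sprintf("'n' (%d) must be a multiple of 'k' (%d)", n, k))
  }
  structure(list(n = n, k = k), class = "long_k_path")
}

#' @export
print.long_k_path <- function(x, ...) {
  cat(sprintf("Long %d-path of dimension %d (%s points)\n",
              x$k, x$n, format(path_length(x), big.mark = ",")))
  invisible(x)
}

#' Number of points on a long k-path
#'
#' Evaluates the closed form `k * 2^(n/k) - k + 1`.  The value is returned
#' as a double so that specifications whose length exceeds the integer range
#' are still representable exactly up to 2^53.
#'
#' @param spec A [long_k_path()] specification.
#' @return The number of points on the path (1 for `n = 0`).
#' @export
path_length <- function(spec) {
  stopifnot(inherits(spec, "long_k_path"))
  if (spec$n == 0) return(1)
  spec$k * 2^(spec$n / spec$k) - spec$k + 1
}

## Recursive point lookup; i is 0-based, n a multiple of k (or 0).
path_point_chr <- function(n, k, i) {
  if (n == 0) return("")
  ell <- k * 2^((n - k) / k) - k + 1 # length of the (n-k)-dimensional path
  if (i < ell) {
    paste0(strrep("0", k), path_point_chr(n - k, k, i))
  } else if (i < ell + k - 1) {
    j <- i - ell + 1 # bridge position: prefix 0^(k-j) 1^j
    paste0(strrep("0", k - j), strrep("1", j), path_point_chr(n - k, k, ell - 1))
  } else {
    paste0(strrep("1", k), path_point_chr(n - k, k, 2 * ell + k - 2 - i))
  }
}

#' Materialise points of a long k-path
#'
#' Points are generated lazily by recursion, so only the first `limit`
#' points are ever constructed; full materialisation is refused above
#' `max_points` because path lengths grow exponentially in `n`.
#'
#' @param spec A [long_k_path()] specification.
#' @param limit Optional number of leading points to return; defaults to the
#'   whole path.
#' @param max_points Safety cap on full materialisation (default `2^20`).
#' @return A data frame with columns `index` (0-based position) and `bits`
#'   (bit string of length `n`).
#' @examples
#' build_path(long_k_path(3, 3))  # 000, 001, 011, 111
#' @export
build_path <- function(spec, limit = NULL, max_points = 2^20) {
  stopifnot(inherits(spec, "long_k_path"))
  len <- path_length(spec)
  if (is.null(limit)) {
    limit <- len
  } else {
    stopifnot(length(limit) == 1, is.numeric(limit), limit >= 1)
    if (limit > len) {
      stop(sprintf("'limit' (%s) exceeds the path length (%s)",
                   format(limit), format(len)))
    }
  }
  if (limit > max_points) {
    stop(sprintf("refusing to materialise %s points (cap %s); pass a smaller 'limit'",
                 format(limit), format(max_points)))
  }
  idx <- seq_len(limit) - 1
  bits <- vapply(idx, function(i) path_point_chr(spec$n, spec$k, i), character(1))
  data.frame(index = idx, bits = bits, stringsAsFactors = FALSE)
}

#' Decode a bit string to its path index
#'
#' Recursively inverts the construction: a leading block `0^k` places the
#' string in the front section, `1^k` in the (reversed) back section, and a
#' block `0^(k-j) 1^j` is a bridge point provided the remaining bits equal
#' the last point of the sub-path.  Any other string is off the path.
#'
#' @param spec A [long_k_path()] specification.
#' @param bits A bit string (`"0"`/`"1"` characters) of length `n`.
#' @return The 0-based index of `bits` on the path, or `NA_real_` if the
#'   string is not a path point.
#' @examples
#' index_of(long_k_path(9, 3), "000111000")  # 9
#' @export
index_of <- function(spec, bits) {
  stopifnot(inherits(spec, "long_k_path"), is.character(bits), length(bits) == 1)
  if (nchar(bits) != spec$n) {
    stop(sprintf("'bits' has length %d; expected %d", nchar(bits), spec$n))
  }
  if (grepl("[^01]", bits)) stop("'bits' may contain only '0' and '1'")
  decode_index(spec$n, spec$k, bits)
}

decode_index <- function(n, k, bits) {
  if (n == 0) return(0)
  ell <- k * 2^((n - k) / k) - k + 1
  prefix <- substr(bits, 1L, k)
  tail <- substr(bits, k + 1L, n)
  ones <- nchar(gsub("0", "", prefix))
  if (ones == 0) {
    decode_index(n - k, k, tail)
  } else if (ones == k) {
    sub <- decode_index(n - k, k, tail)
    if (is.na(sub)) NA_real_ else 2 * ell + k - 2 - sub
  } else if (prefix == paste0(strrep("0", k - ones), strrep("1", ones))) {
    # bridge point: the tail must be the final point of the sub-path
    if (tail == path_point_chr(n - k, k, ell - 1)) ell + ones - 1 else NA_real_
  } else {
    NA_real_
  }
}

## Bit-string helpers shared across modules.
bits_to_int <- function(bits) {
  as.integer(strsplit(bits, "", fixed = TRUE)[[1]])
}

int_to_bits <- function(v) {
  paste(v, collapse = "")
}

hamming <- function(a, b) sum(a != b)

#' Check the shortcut-free property of a long k-path
#'
#' For every ordered pair of points `i` positions apart the Hamming distance
#' must equal `i` when `i < k` and be at least `k` when `i >= k`.  The whole
#' path is materialised, so the check is only feasible for small dimensions.
#'
#' @param spec A [long_k_path()] specification.
#' @param max_points Materialisation cap passed to [build_path()].
#' @return A list of class `"hamming_report"` with elements `ok` (logical),
#'   `violations` (data frame of offending pairs: `s`, `i`, `distance`),
#'   `n`, `k` and `n_points`.
#' @export
verify_hamming_property <- function(spec, max_points = 2^14) {
  stopifnot(inherits(spec, "long_k_path"))
  pts <- build_path(spec, max_points = max_points)
  mat <- do.call(rbind, lapply(pts$bits, bits_to_int))
  L <- nrow(mat)
  viol <- list()
  for (s in seq_len(L)) {
    for (t in seq_len(L)) {
      if (t <= s) next
      i <- t - s
      d <- sum(mat[s, ] != mat[t, ])
      bad <- if (i < spec$k) d != i else d < spec$k
      if (bad) {
        viol[[length(viol) + 1]] <- data.frame(s = s - 1, i = i, distance = d)
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(s = numeric(0), i = numeric(0), distance = numeric(0))
  structure(list(ok = nrow(violations) == 0, violations = violations,
                 n = spec$n, k = spec$k, n_points = L),
            class = "hamming_report")
}

#' @export
print.hamming_report <- function(x, ...) {
  cat(sprintf("Hamming-path report for the long %d-path of dimension %d (%d points)\n",
              x$k, x$n, x$n_points))
  if (x$ok) {
    cat("All pairwise distances satisfy H(P_s, P_{s+i}) = i (i < k), >= k otherwise.\n")
  } else {
    cat(sprintf("%d violating pairs, e.g.:\n", nrow(x$violations)))
    print(utils::head(x$violations))
  }
  invisible(x)
}

#' Embed a height profile on the leading points of a long k-path
#'
#' Assigns `heights[i + 1]` to path point `P_i` for `i < length(heights)`
#' and the off-path sentinel `-Inf` to every other bit string (including
#' path points beyond the supplied heights).  All acceptance rules map a
#' fitness difference involving the sentinel to probability 0, so search
#' never leaves the embedded landscape.
#'
#' @param spec A [long_k_path()] specification.
#' @param heights Numeric vector of finite heights, one per leading path
#'   point; must not be empty nor longer than the path.
#' @return A function `f(bits) -> numeric` evaluating the fitness.
#' @examples
#' f <- embed_fitness(long_k_path(3, 3), c(2, 1, 0, 3))
#' f("000")  # 2
#' f("010")  # -Inf (off the path)
#' @export
embed_fitness <- function(spec, heights) {
  stopifnot(inherits(spec, "long_k_path"), is.numeric(heights))
  if (length(heights) == 0) stop("'heights' must not be empty")
  if (any(!is.finite(heights))) stop("'heights' must be finite")
  if (length(heights) > path_length(spec)) {
    stop("'heights' is longer than the path")
  }
  m <- length(heights)
  force(spec)
  function(bits) {
    i <- index_of(spec, bits)
    if (!is.na(i) && i < m) heights[i + 1] else -Inf
  }
}

## Fast lookup table bits -> height for the first m path points; used by the
## bitstring simulator so each evaluation is a hash probe, not a recursive
## decode.
path_fitness_table <- function(spec, heights) {
  pts <- build_path(spec, limit = length(heights))
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(pts))) {
    assign(pts$bits[i], c(index = pts$index[i], height = heights[i]), envir = env)
  }
  env
}

#' Largest divisor-compatible fold parameter
#'
#' The shortcut probability argument wants `k` of order `sqrt(n)`, but
#' `sqrt(n)` rarely divides `n`.  This helper returns the largest
#' `k <= ceiling(sqrt(n))` that divides `n`.
#'
#' @param n Positive integer dimension.
#' @return The chosen fold parameter `k`.
#' @examples
#' choose_fold(12) # 4
#' @export
choose_fold <- function(n) {
  stopifnot(length(n) == 1, is.numeric(n), n >= 1)
  n <- as.integer(n)
  for (k in seq(ceiling(sqrt(n)), 1)) {
    if (n %% k == 0) return(as.integer(k))
  }
  1L
}
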