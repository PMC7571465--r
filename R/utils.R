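# Small internal helpers shared across modules.

# Shoelace area of a polygon given as an n x 2 matrix (absolute value).
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# All permutations of 1..n as an (n!) x n integer matrix, in a fixed
# (lexicographic) order so downstream tie-breaks are reproducible.
perms_n <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_n(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    idx <- row:(row + nrow(sub) - 1L)
    out[idx, 1L] <- first
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("'%s' must be in [%s, %s]", name, format(min), format(max)),
         call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
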