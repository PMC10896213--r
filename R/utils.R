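# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All generators route randomness through this so
# that identical spec + seed => bit-identical output, with no global RNG
# side effects.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

# FWHM of a Gaussian with standard deviation sigma.
fwhm_factor <- 2 * sqrt(2 * log(2))

# Bilinear interpolation of matrix `m` at fractional 1-based (row, col)
# positions. Callers must ensure 1 <= row <= nrow(m), 1 <= col <= ncol(m).
bilinear_sample <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- row - r0; fc <- col - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

# 3x3 mean filter with edge replication; used before peak detection so a
# single hot pixel cannot masquerade as a pole.
smooth3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    out <- out + pad[dr + seq_len(nr), dc + seq_len(nc)]
  }
  out / 9
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x)

is_num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
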