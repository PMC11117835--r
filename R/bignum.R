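# Arbitrary-precision non-negative integers for the exact codec path.
#
# A "bn" is a numeric vector of limbs in base 1e7, little-endian (limb 1 is
# the least significant), with no high zero limbs (canonical zero is the
# length-1 vector 0). Every limb is an integer-valued double in [0, 1e7),
# so all intermediate products and carries stay below 2^53 and double
# arithmetic on limbs is exact. Base 1e7 also makes decimal serialization a
# straight concatenation of limbs.
#
# Only the operations the dyadic codec needs are provided: addition,
# subtraction (a >= b), comparison, multiplication by a small integer,
# shifts by powers of two, splitting at a bit position, multiplication by
# powers of five (for decimal output), and 2-/5-adic valuations (for
# reduction to lowest terms). Nothing here ever touches binary floating
# point with a non-integer value.

.BN_BASE <- 1e7
# largest small multiplier m such that m * (BASE - 1) + m stays < 2^53
.BN_CHUNK_BITS <- 29L # shifts are applied in chunks of 2^29
.BN_POW5_CHUNK <- 12L # ... and 5^12 for decimal scaling

bn_trim <- function(x) {
  n <- length(x)
  while (n > 1L && x[n] == 0) n <- n - 1L
  x[seq_len(n)]
}

# from a non-negative integer-valued double (exact only below 2^53)
bn <- function(x) {
  stopifnot(length(x) == 1L, !is.na(x), x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0)
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% .BN_BASE)
    x <- floor(x / .BN_BASE)
  }
  limbs
}

bn_is_zero <- function(a) length(a) == 1L && a[1L] == 0

# carry-propagate a limb vector whose entries may exceed the base
bn_carry <- function(x) {
  i <- 1L
  while (i <= length(x)) {
    if (x[i] >= .BN_BASE) {
      carry <- floor(x[i] / .BN_BASE)
      x[i] <- x[i] - carry * .BN_BASE
      if (i == length(x)) x <- c(x, carry) else x[i + 1L] <- x[i + 1L] + carry
    }
    i <- i + 1L
  }
  bn_trim(x)
}

bn_add <- function(a, b) {
  n <- max(length(a), length(b))
  x <- c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
  bn_carry(c(x, 0))
}

# a - b, requiring a >= b
bn_sub <- function(a, b) {
  if (bn_cmp(a, b) < 0L) stop("bignum underflow: a < b in bn_sub()")
  n <- length(a)
  x <- a - c(b, numeric(n - length(b)))
  for (i in seq_len(n)) {
    if (x[i] < 0) {
      x[i] <- x[i] + .BN_BASE
      x[i + 1L] <- x[i + 1L] - 1
    }
  }
  bn_trim(x)
}

# -1, 0, 1 as a < b, a == b, a > b
bn_cmp <- function(a, b) {
  if (length(a) != length(b)) return(if (length(a) < length(b)) -1L else 1L)
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

# multiply by a small non-negative integer m (m <= 2^29 keeps limbs exact)
bn_mul_small <- function(a, m) {
  stopifnot(m >= 0, m == floor(m), m <= 2^29)
  if (m == 0 || bn_is_zero(a)) return(0)
  bn_carry(c(a * m, 0, 0))
}

# a * 2^k
bn_shl <- function(a, k) {
  stopifnot(k >= 0, k == floor(k))
  while (k >= .BN_CHUNK_BITS) {
    a <- bn_mul_small(a, 2^.BN_CHUNK_BITS)
    k <- k - .BN_CHUNK_BITS
  }
  if (k > 0) a <- bn_mul_small(a, 2^k)
  a
}

# divide by a small positive integer: list(q = quotient, r = remainder double)
bn_divmod_small <- function(a, m) {
  stopifnot(m > 0, m == floor(m), m <= 2^29)
  q <- numeric(length(a))
  r <- 0
  for (i in rev(seq_along(a))) {
    cur <- r * .BN_BASE + a[i]
    qi <- floor(cur / m)
    ri <- cur - qi * m
    # guard against a double division landing on the wrong side of an integer
    if (ri < 0) { qi <- qi - 1; ri <- ri + m }
    if (ri >= m) { qi <- qi + 1; ri <- ri - m }
    q[i] <- qi
    r <- ri
  }
  list(q = bn_trim(q), r = r)
}

# split a at bit k: list(hi, lo) with a == hi * 2^k + lo, 0 <= lo < 2^k
bn_split2 <- function(a, k) {
  stopifnot(k >= 0, k == floor(k))
  lo <- 0 # bignum accumulator for the low bits
  shift <- 0
  while (k > 0) {
    step <- min(k, .BN_CHUNK_BITS)
    dm <- bn_divmod_small(a, 2^step)
    lo <- bn_add(lo, bn_shl(bn(dm$r), shift))
    a <- dm$q
    shift <- shift + step
    k <- k - step
  }
  list(hi = a, lo = lo)
}

# a * 5^k
bn_mul_pow5 <- function(a, k) {
  stopifnot(k >= 0, k == floor(k))
  while (k >= .BN_POW5_CHUNK) {
    a <- bn_mul_small(a, 5^.BN_POW5_CHUNK)
    k <- k - .BN_POW5_CHUNK
  }
  if (k > 0) a <- bn_mul_small(a, 5^k)
  a
}

# exponent of the largest power of p (2 or 5) dividing a; capped at `max`
bn_valuation <- function(a, p, max = Inf) {
  if (bn_is_zero(a)) return(0L)
  v <- 0L
  while (v < max) {
    dm <- bn_divmod_small(a, p)
    if (dm$r != 0) break
    a <- dm$q
    v <- v + 1L
  }
  v
}

# remove p^v from a (caller guarantees divisibility)
bn_drop_pow <- function(a, p, v) {
  for (i in seq_len(v)) {
    dm <- bn_divmod_small(a, p)
    stopifnot(dm$r == 0)
    a <- dm$q
  }
  a
}

# back to double; errors if the value does not fit exactly
bn_to_double <- function(a) {
  x <- 0
  for (i in rev(seq_along(a))) {
    if (x > 2^53 / .BN_BASE) stop("bignum too large for exact double conversion")
    x <- x * .BN_BASE + a[i]
  }
  if (x >= 2^53) stop("bignum too large for exact double conversion")
  x
}

# number of binary digits (0 for zero)
bn_bitlength <- function(a) {
  if (bn_is_zero(a)) return(0L)
  bits <- 0L
  while (!bn_is_zero(a)) {
    dm <- bn_divmod_small(a, 2^.BN_CHUNK_BITS)
    if (bn_is_zero(dm$q)) {
      r <- dm$r
      while (r > 0) {
        bits <- bits + 1L
        r <- floor(r / 2)
      }
      return(bits)
    }
    bits <- bits + .BN_CHUNK_BITS
    a <- dm$q
  }
  bits
}

# decimal digit string; limbs are already base-1e7 digit groups
bn_to_decstr <- function(a) {
  n <- length(a)
  if (n == 1L) return(sprintf("%.0f", a[1L]))
  paste0(sprintf("%.0f", a[n]),
         paste(sprintf("%07.0f", rev(a[-n])), collapse = ""))
}

bn_from_decstr <- function(s) {
  if (!grepl("^[0-9]+$", s)) stop("not a decimal digit string: ", s)
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  n <- nchar(s)
  ends <- seq(n, 1L, by = -7L) # chunk end positions, right to left
  limbs <- vapply(ends, function(e) {
    as.numeric(substr(s, max(1L, e - 6L), e))
  }, numeric(1))
  bn_trim(limbs)
}
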