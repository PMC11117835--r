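# ---- the encoded-number class -------------------------------------------

# Field width (in bits) allotted to node i's column code inside the packed
# fraction of the modified scheme. Column i has i - 1 strict-upper bits; the
# node immediately after the skipped principal node carries one spare
# (always-zero) bit, which is what the published worked value fixes the
# layout to. See the methods vignette for the full derivation.
field_width <- function(i, mn) (i - 1L) + as.integer(i == mn + 1L)

# internal constructor; reduces the value to lowest terms
new_ubnin_value <- function(num, exp2, exp5, n_nodes, mn, scheme) {
  if (bn_is_zero(num)) {
    exp2 <- 0L
    exp5 <- 0L
  } else {
    v2 <- bn_valuation(num, 2, max = exp2)
    if (v2 > 0L) {
      num <- bn_drop_pow(num, 2, v2)
      exp2 <- exp2 - v2
    }
    if (exp5 > 0L) {
      v5 <- bn_valuation(num, 5, max = exp5)
      if (v5 > 0L) {
        num <- bn_drop_pow(num, 5, v5)
        exp5 <- exp5 - v5
      }
    }
  }
  structure(
    list(num = num, exp2 = as.integer(exp2), exp5 = as.integer(exp5),
         n_nodes = as.integer(n_nodes), mn = mn, scheme = scheme),
    class = "ubnin_value"
  )
}

#' @export
print.ubnin_value <- function(x, digits = NULL, ...) {
  mn <- if (identical(x$mn, "classic")) "classic" else sprintf("MN=%d", x$mn)
  cat(sprintf("<UBNIN value: T=%d, %s, scheme=%s>\n", x$n_nodes, mn, x$scheme))
  s <- to_decimal_string(x)
  if (!is.null(digits)) {
    dot <- regexpr(".", s, fixed = TRUE)
    if (dot > 0L && nchar(s) - dot > digits) {
      s <- paste0(substr(s, 1L, dot + digits), "... (display truncated, lossy)")
    }
  }
  cat(" ", s, "\n", sep = "")
  invisible(x)
}

#' @export
as.character.ubnin_value <- function(x, ...) to_decimal_string(x)

#' Integer part of an encoded value
#'
#' For the modified scheme this equals the column code `DEC(MN)` of the
#' principal node; for the classic scheme it equals `DEC(T)`.
#'
#' @param v a `ubnin_value`.
#' @return a non-negative integer (as double).
#' @examples
#' v <- encode_modified(c(0, 1, 3, 6, 13, 20, 60, 67, 1, 321, 503, 996), mn = 3)
#' ubnin_integer_part(v) # 3
#' @export
ubnin_integer_part <- function(v) {
  stopifnot(inherits(v, "ubnin_value"))
  num <- v$num
  if (v$exp5 > 0L) {
    for (i in seq_len(v$exp5)) num <- bn_divmod_small(num, 5)$q
  }
  bn_to_double(bn_split2(num, v$exp2)$hi)
}

# ---- encoding -------------------------------------------------------------

# raw recurrence, shared by the public encoder and the batch experiment;
# returns the unreduced dyadic pair (num, exp2)
encode_modified_raw <- function(dec, mn) {
  n <- length(dec)
  s <- seq_len(n)[-mn]
  num <- bn(dec[s[1L]])
  e <- 0L
  for (k in seq_along(s)[-1L]) {
    e <- e + field_width(s[k - 1L], mn)
    num <- bn_add(num, bn_shl(bn(dec[s[k]]), e))
  }
  e <- e + n
  num <- bn_add(num, bn_shl(bn(dec[mn]), e))
  list(num = num, exp2 = e)
}

encode_classic_raw <- function(dec) {
  n <- length(dec)
  num <- bn(dec[1L])
  e <- 0L
  for (k in seq_len(n)[-1L]) {
    e <- e + (k - 1L)
    num <- bn_add(num, bn_shl(bn(dec[k]), e))
  }
  list(num = num, exp2 = e)
}

#' Encode a column code as a modified UBNIN number
#'
#' Packs the per-column decimal codes `DEC(1..T)` into one exact dyadic
#' rational. The code of the chosen principal node `mn` becomes the integer
#' part; the remaining codes, in ascending node order, are nested into the
#' fraction by the positional recurrence
#' `V := V * 2^-w(prev) + DEC(next)` followed by a final wrap `V * 2^-T`,
#' where `w(i)` is the bit width allotted to node `i`'s column
#' (its strict-upper width `i - 1`, plus one spare bit for the node directly
#' after the skipped `mn`). Every column therefore occupies its own disjoint
#' bit field of the fraction, which makes the map injective and exactly
#' invertible (see [decode_modified()]).
#'
#' All arithmetic is exact; binary floating point never enters the codec
#' path. The fractional part of the result is always below one half.
#'
#' @param dec numeric vector of column codes `DEC(1..T)`, `T >= 2`.
#' @param mn 1-based index of the (maximally occurring) principal node.
#' @param scheme codec identifier; only `"worked-example"`, the layout fixed
#'   by the published 12-node worked value, is defined.
#' @return a `ubnin_value`.
#' @examples
#' v <- encode_modified(c(0, 1, 3, 6, 13, 20, 60, 67, 1, 321, 503, 996), mn = 3)
#' to_decimal_string(v)
#' @export
encode_modified <- function(dec, mn, scheme = "worked-example") {
  dec <- validate_column_code(dec)
  n <- length(dec)
  if (n < 2L) stop("the modified scheme needs at least 2 nodes")
  if (length(mn) != 1L || is.na(mn) || mn != floor(mn) || mn < 1 || mn > n) {
    stop(sprintf("mn must be a single node index in 1..%d", n))
  }
  scheme <- match.arg(scheme)
  raw <- encode_modified_raw(dec, as.integer(mn))
  new_ubnin_value(raw$num, raw$exp2, 0L, n, as.integer(mn), scheme)
}

#' Encode a column code with the classic (unskipped) recurrence
#'
#' The original flavour of the codec: all columns in ascending node order,
#' no principal node skipped, recurrence `V := V * 2^-(k-1) + DEC(k)`. The
#' integer part equals `DEC(T)`. Provided as a best-effort alignment with
#' the earlier algorithm, which the worked material does not restate; it is
#' the default encoder of [uniqueness_experiment()].
#'
#' @param dec numeric vector of column codes `DEC(1..T)`.
#' @return a `ubnin_value` with `mn` marker `"classic"`.
#' @examples
#' to_decimal_string(encode_classic(c(0, 1, 3, 6))) # "6.40625"
#' @export
encode_classic <- function(dec) {
  dec <- validate_column_code(dec)
  raw <- encode_classic_raw(dec)
  new_ubnin_value(raw$num, raw$exp2, 0L, length(dec), "classic", "worked-example")
}

# ---- decoding -------------------------------------------------------------

#' Decode a modified UBNIN number back to its column code
#'
#' Exact inverse of [encode_modified()]: peels the integer part off as
#' `DEC(MN)`, then unwinds the positional recurrence field by field. The
#' decode is strict: a value that is not exactly representable as a valid
#' column code for its `(T, MN)` -- a non-dyadic denominator, a column code
#' exceeding its `2^(i-1) - 1` bound, or a non-zero residual -- is rejected,
#' never rounded to the nearest valid code.
#'
#' @param v a `ubnin_value` carrying `n_nodes` and a numeric `mn` (from
#'   [encode_modified()] or [parse_decimal_string()]).
#' @return numeric vector of column codes `DEC(1..T)`.
#' @examples
#' dec <- c(0, 1, 3, 6, 13, 20, 60, 67, 1, 321, 503, 996)
#' identical(decode_modified(encode_modified(dec, mn = 3)), dec)
#' @export
decode_modified <- function(v) {
  stopifnot(inherits(v, "ubnin_value"))
  if (identical(v$mn, "classic")) {
    stop("value carries the 'classic' marker; decoding is defined for the modified scheme")
  }
  n <- v$n_nodes
  mn <- v$mn
  invalid <- function(why) {
    stop(sprintf("not a valid UBNIN-M value for (T=%d, MN=%d): %s", n, mn, why))
  }
  if (v$exp5 > 0L) invalid("denominator is not a power of 2")
  s <- seq_len(n)[-mn]
  dec <- numeric(n)

  sp <- bn_split2(v$num, v$exp2)
  if (bn_bitlength(sp$hi) > mn - 1L) {
    invalid(sprintf("integer part exceeds 2^%d - 1", mn - 1L))
  }
  dec[mn] <- bn_to_double(sp$hi)

  # W = F / 2^ef walks the recurrence backwards
  f <- sp$lo
  ef <- v$exp2
  mul2 <- function(m) {
    ef <<- ef - m
    if (ef < 0L) {
      f <<- bn_shl(f, -ef)
      ef <<- 0L
    }
  }
  mul2(n)
  for (k in rev(seq_along(s))[-length(s)]) {
    sp <- bn_split2(f, ef)
    if (bn_bitlength(sp$hi) > s[k] - 1L) {
      invalid(sprintf("recovered DEC(%d) exceeds 2^%d - 1", s[k], s[k] - 1L))
    }
    dec[s[k]] <- bn_to_double(sp$hi)
    f <- sp$lo
    mul2(field_width(s[k - 1L], mn))
  }
  sp <- bn_split2(f, ef)
  if (!bn_is_zero(sp$lo)) invalid("non-integer residual after the last column")
  if (bn_bitlength(sp$hi) > s[1L] - 1L) {
    invalid(sprintf("recovered DEC(%d) exceeds 2^%d - 1", s[1L], s[1L] - 1L))
  }
  dec[s[1L]] <- bn_to_double(sp$hi)
  dec
}

# ---- exact decimal serialization ------------------------------------------

#' Serialize an encoded value as its exact terminating decimal
#'
#' An encoded value is a dyadic rational, so its decimal expansion
#' terminates; the string carries every digit, with the number of fractional
#' digits equal to the exponent of 2 in the reduced denominator. No rounding,
#' no exponent notation. [parse_decimal_string()] inverts it exactly.
#'
#' @param v a `ubnin_value`.
#' @return a decimal string such as `"3.2431640625"`.
#' @examples
#' to_decimal_string(encode_classic(c(0, 1))) # "1"
#' @export
to_decimal_string <- function(v) {
  stopifnot(inherits(v, "ubnin_value"))
  d <- max(v$exp2, v$exp5)
  num <- bn_mul_pow5(bn_shl(v$num, d - v$exp2), d - v$exp5)
  s <- bn_to_decstr(num)
  if (d == 0L) return(s)
  if (nchar(s) <= d) s <- paste0(strrep("0", d - nchar(s) + 1L), s)
  paste0(substr(s, 1L, nchar(s) - d), ".", substr(s, nchar(s) - d + 1L, nchar(s)))
}

#' Parse an exact decimal string into an encoded value
#'
#' Accepts a plain finite decimal numeral (digits, optionally one decimal
#' point). Scientific notation, signs and anything already rounded through a
#' binary float are refused -- values must cross program boundaries as exact
#' decimal strings. The result is reduced to lowest terms; whether the
#' denominator is a power of two (as every genuinely encoded value is) is
#' enforced on decode, not here.
#'
#' @param s the decimal string, e.g. `"3.25"`.
#' @param n_nodes node count `T` the value belongs to.
#' @param mn principal-node index, or `"classic"`.
#' @param scheme codec identifier, see [encode_modified()].
#' @return a `ubnin_value`.
#' @examples
#' v <- parse_decimal_string("3.25", n_nodes = 12, mn = 3)
#' ubnin_integer_part(v) # 3
#' @export
parse_decimal_string <- function(s, n_nodes, mn, scheme = "worked-example") {
  stopifnot(length(s) == 1L, is.character(s))
  s <- trimws(s)
  m <- regmatches(s, regexec("^([0-9]+)(?:\\.([0-9]+))?$", s))[[1L]]
  if (length(m) == 0L) {
    stop(sprintf("malformed decimal numeral: '%s' %s", s,
                 "(expected plain digits with at most one '.'; floats are refused)"))
  }
  intpart <- m[2L]
  frac <- if (is.na(m[3L]) || m[3L] == "") "" else m[3L]
  d <- nchar(frac)
  num <- bn_from_decstr(paste0(intpart, frac))
  if (!identical(mn, "classic")) {
    if (length(mn) != 1L || is.na(mn) || mn != floor(mn) || mn < 1 || mn > n_nodes) {
      stop(sprintf("mn must be 'classic' or a node index in 1..%d", n_nodes))
    }
    mn <- as.integer(mn)
  }
  new_ubnin_value(num, d, d, as.integer(n_nodes), mn, scheme)
}
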