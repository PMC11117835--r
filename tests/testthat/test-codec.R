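test_that("the worked example encodes to its full 66-digit value", {
  v <- encode_modified(worked_dec, mn = 3)
  expect_identical(to_decimal_string(v), worked_value)
  expect_identical(ubnin_integer_part(v), 3)
  expect_identical(v$exp2, 66L) # reduced denominator is 2^66
  expect_identical(v$exp5, 0L)
})

test_that("small encodings match independent closed-form weight sums", {
  # T = 4, mn = 2: fields at 2^-4 (node 4), 2^-7 (node 3), integer DEC(2)
  # => 1 + 6/16 + 3/128 = 179/128
  expect_identical(to_decimal_string(encode_modified(c(0, 1, 3, 6), mn = 2)),
                   "1.3984375")
  # classic, T = 4: 6 + 3/2^3 + 1/2^5 = 205/32
  expect_identical(to_decimal_string(encode_classic(c(0, 1, 3, 6))), "6.40625")
  expect_identical(to_decimal_string(encode_classic(c(0, 1))), "1")
  # all-zero codes encode to 0 under both schemes
  expect_identical(to_decimal_string(encode_modified(rep(0, 7), mn = 4)), "0")
  expect_identical(to_decimal_string(encode_classic(rep(0, 7))), "0")
})

test_that("decoding inverts encoding, including the printed worked value", {
  v <- parse_decimal_string(worked_value, n_nodes = 12, mn = 3)
  dec <- decode_modified(v)
  expect_identical(dec, worked_dec)
  expect_identical(dec[12], 996)
  expect_identical(decode_modified(parse_decimal_string("0", 9, 5)), rep(0, 9))
  set.seed(23)
  for (rep in 1:1000) {
    code <- random_code(10)
    mn <- sample(10, 1)
    expect_identical(decode_modified(encode_modified(code, mn)), code)
  }
})

test_that("integer part, fraction bound and dyadic denominator hold everywhere", {
  set.seed(37)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    code <- random_code(n)
    mn <- sample(n, 1)
    v <- encode_modified(code, mn)
    expect_identical(ubnin_integer_part(v), code[mn])
    expect_identical(v$exp5, 0L) # denominator a pure power of 2
    # fractional part < 1/2: frac * 2 < 1, i.e. num mod 2^exp2, doubled,
    # still fits below 2^exp2
    frac <- ubnin:::bn_split2(v$num, v$exp2)$lo
    expect_lt(ubnin:::bn_bitlength(frac), v$exp2 + 1L)
    if (!ubnin:::bn_is_zero(frac)) {
      expect_identical(ubnin:::bn_bitlength(ubnin:::bn_shl(frac, 1)) <= v$exp2,
                       TRUE)
    }
  }
})

test_that("encoding is injective over all five-node networks for every mn", {
  codes <- all_codes(5)
  for (mn in 1:5) {
    values <- vapply(seq_len(nrow(codes)), function(r) {
      to_decimal_string(encode_modified(codes[r, ], mn))
    }, character(1))
    expect_identical(anyDuplicated(values), 0L)
  }
  # and for the classic scheme
  classic <- vapply(seq_len(nrow(codes)), function(r) {
    to_decimal_string(encode_classic(codes[r, ]))
  }, character(1))
  expect_identical(anyDuplicated(classic), 0L)
})

test_that("decoding is strict: near-miss values are rejected, not rounded", {
  # fraction >= 1/2 cannot come out of the encoder
  expect_error(decode_modified(parse_decimal_string("0.75", 3, 1)),
               "not a valid UBNIN-M")
  # integer part exceeding DEC(mn)'s bound
  expect_error(decode_modified(parse_decimal_string("9.0", 12, 3)),
               "not a valid UBNIN-M")
  # a denominator with a factor of 5 is not dyadic
  expect_error(decode_modified(parse_decimal_string("0.2", 12, 3)),
               "not a power of 2")
  # one ulp of decimal dust below the last field
  v <- encode_modified(worked_dec, mn = 3)
  dust <- parse_decimal_string(paste0(to_decimal_string(v), "1"), 12, 3)
  expect_error(decode_modified(dust), "not a valid UBNIN-M")
  # classic-marked values have no defined decode
  expect_error(decode_modified(encode_classic(c(0, 1, 3))), "classic")
})

test_that("decimal serialization is exact and parse inverts it", {
  half <- parse_decimal_string("0.5", 2, 1)
  expect_identical(to_decimal_string(half), "0.5")
  expect_identical(half$exp2, 1L)
  # 3 + 996/4096 by long division
  v <- parse_decimal_string("3.2431640625", 12, 3)
  expect_identical(to_decimal_string(v), "3.2431640625")
  expect_identical(v$exp2, 10L) # 3 + 996/4096 reduces to 3321/2^10
  expect_identical(to_decimal_string(parse_decimal_string("3.25", 12, 3)), "3.25")
  expect_identical(to_decimal_string(parse_decimal_string("0", 12, 3)), "0")
  expect_error(parse_decimal_string("1e-3", 12, 3), "malformed")
  expect_error(parse_decimal_string("-1.5", 12, 3), "malformed")
  expect_error(parse_decimal_string("3.", 12, 3), "malformed")
})

test_that("64-bit floating point cannot reproduce the exact value", {
  # the same recurrence evaluated in doubles drifts from the exact result:
  # the worked value needs 67 significant bits, a double carries 53
  s <- seq_len(12)[-3]
  w <- function(i) (i - 1) + (i == 4)
  V <- worked_dec[s[1]]
  for (k in 2:11) V <- V / 2^w(s[k - 1]) + worked_dec[s[k]]
  dbl <- V / 2^12 + worked_dec[3]
  expect_false(identical(sprintf("%.66f", dbl), worked_value))
  # and no double round-trips the printed string
  expect_false(identical(sprintf("%.66f", as.numeric(worked_value)), worked_value))
  expect_gt(ubnin:::bn_bitlength(encode_modified(worked_dec, 3)$num), 53L)
})
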