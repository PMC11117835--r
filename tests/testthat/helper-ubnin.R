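# the canonical 12-node worked example: column codes and the full exact
# encoded value (66 fractional digits) it must reproduce with MN = 3
worked_dec <- c(0, 1, 3, 6, 13, 20, 60, 67, 1, 321, 503, 996)
worked_value <-
  "3.243284136525345895659473878513967548542495933361351490020751953125"

# random valid column code for a T-node network (uses the session RNG)
random_code <- function(n) {
  vapply(seq_len(n), function(i) {
    sum((stats::runif(i - 1) < 0.5) * 2^(seq_len(i - 1) - 1))
  }, numeric(1))
}

# all 2^(n(n-1)/2) column codes of an n-node network, one per row
all_codes <- function(n) {
  m <- n * (n - 1) / 2
  grid <- as.matrix(expand.grid(rep(list(0:1), m)))
  widths <- seq_len(n) - 1L
  out <- matrix(0, nrow(grid), n)
  pos <- 0L
  for (i in seq_len(n)) {
    w <- widths[i]
    if (w > 0L) {
      out[, i] <- grid[, pos + seq_len(w), drop = FALSE] %*% 2^(seq_len(w) - 1)
      pos <- pos + w
    }
  }
  out
}

tmpfile <- function(ext = "") tempfile(fileext = ext)
tmpdir <- function() {
  d <- tempfile()
  dir.create(d)
  d
}
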