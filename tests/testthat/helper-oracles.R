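# Independent oracle for the derivatization shift model: explicit
# element-wise convolution, written without reference to the package's
# applyM1Artifact().
oracle_forward_shift <- function(true, r) {
  out <- numeric(length(true))
  for (x in seq_along(true)) {
    out[x] <- (1 - r) * true[x]
    if (x > 1) out[x] <- out[x] + r * true[x - 1]
  }
  out
}

# Random fractional MID of given length
random_mid <- function(len) {
  v <- stats::runif(len)
  v / sum(v)
}

# Closed-form OLS slope, the textbook formula, as an independent check
# on lm()-based fits.
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
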