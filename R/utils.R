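# Row-wise mean/variance with NA removal, vectorized (no matrixStats dep).
row_means_na <- function(m) {
  n <- rowSums(!is.na(m))
  s <- rowSums(m, na.rm = TRUE)
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

# Unbiased (n-1) sample variance per row; NA when fewer than 2 observed.
row_vars_na <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- row_means_na(m)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  out <- ss / (n - 1)
  out[n < 2] <- NA_real_
  out
}
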