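# Brute-force oracle: exact two-sided Mann-Whitney p by enumerating every
# group labeling with utils::combn (only viable for small pooled samples).
# Independent of the package's dynamic-programming implementation.
mw_enum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  n <- length(r)
  ew <- nx * mean(r)
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  w <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(w - ew) >= abs(obs - ew) - 1e-9)
}
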