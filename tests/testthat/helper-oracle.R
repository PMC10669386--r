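# Independent brute-force oracles used by the fuzzy and CEG tests.
# Deliberately written from first principles (own triangle evaluation,
# trapezoidal integration) so they share no code path with the package.

# triangle membership by direct case analysis
oracle_tri <- function(mf, x) {
  a <- mf[1]; b <- mf[2]; c <- mf[3]
  vapply(x, function(xi) {
    if (xi < a || xi > c) return(0)
    if (xi == b) return(1)
    if (xi < b) {
      if (a == b) 0 else (xi - a) / (b - a)
    } else {
      if (b == c) 0 else (c - xi) / (c - b)
    }
  }, numeric(1))
}

# dense-grid Mamdani centroid via trapezoidal integration
oracle_centroid <- function(sys, voltage, severity, factor = 100) {
  cl <- function(x, d) min(max(x, d[1]), d[2])
  voltage <- cl(voltage, sys$voltage$domain)
  severity <- cl(severity, sys$ceg$domain)
  dv <- vapply(sys$voltage$mfs, oracle_tri, numeric(1), x = voltage)
  dc <- vapply(sys$ceg$mfs, oracle_tri, numeric(1), x = severity)
  x <- seq(sys$error$domain[1], sys$error$domain[2],
           length.out = sys$resolution * factor)
  mu <- numeric(length(x))
  for (i in seq_len(nrow(sys$rules))) {
    act <- min(dv[[sys$rules$voltage[i]]], dc[[sys$rules$ceg[i]]])
    mu <- pmax(mu, pmin(oracle_tri(sys$error$mfs[[sys$rules$error[i]]], x), act))
  }
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  trapz(x, x * mu) / trapz(x, mu)
}
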