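# Independent oracles used across tests.

# Stationary law of the n-site birth-death chain with forward rates
# theta * P[i+1] and unit backward rates, obtained from the null space of
# the explicit rate matrix (QR-based), independently of the closed-form
# product solution in the package.
bd_stationary_oracle <- function(theta, P) {
  n <- length(P)
  Q <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) {
    fwd <- theta * P[i]
    Q[i, i + 1] <- fwd       # i-1 -> i methylation
    Q[i + 1, i] <- 1         # i -> i-1 demethylation
  }
  diag(Q) <- -rowSums(Q)
  # pi Q = 0  <=>  pi is orthogonal to every column of Q: the last column of
  # the complete orthogonal factor of qr(Q) spans that complement
  v <- qr.Q(qr(Q), complete = TRUE)[, n + 1]
  v <- abs(v)
  v / sum(v)
}

# Fixed-step explicit Euler integration of the adaptation ODE, the
# reference for simulate_adaptation.
euler_adaptation_oracle <- function(protocol, mwc, kin, m_init, t_end,
                                    dt = 1e-3, modifier = function(m) 1) {
  t <- protocol$t_s[1]
  m <- m_init
  bounds <- c(protocol$t_s[-1], t_end)
  out_t <- seq(protocol$t_s[1], t_end, by = 1)
  out_m <- numeric(length(out_t))
  j <- 1
  for (i in seq_len(nrow(protocol))) {
    L <- protocol$L_mM[i]
    while (t < bounds[i] - dt / 2) {
      if (j <= length(out_t) && t >= out_t[j] - dt / 2) {
        out_m[j] <- m
        j <- j + 1
      }
      a <- receptor_activity(m, L, mwc)
      dm <- methylation_rate(a, m, kin, kR_modifier = modifier(m))
      m <- min(max(m + dt * dm, 0), 4)
      t <- t + dt
    }
  }
  while (j <= length(out_t)) {
    out_m[j] <- m
    j <- j + 1
  }
  tibble::tibble(t_s = out_t, m = out_m)
}

# Construct a noise-free fret_trace directly from a known activity path
# (bypassing the ODE), for exactness tests of the calibration chain.
trace_from_activity <- function(t_s, a, events, offset = 0.8, gain = 0.2,
                                strain = "tar-only") {
  fret_trace(tibble::tibble(t_s = t_s, ratio = offset + gain * a),
             events, strain)
}
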