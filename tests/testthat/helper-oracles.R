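# Independent oracle for the selective scan: a scalar triple loop over
# positions, channels and states, written directly from the recurrence
# definition and sharing no code with the implementation.
naive_scan <- function(delta, A, B, C, D_skip, x, h0 = NULL) {
  L <- nrow(x); E <- ncol(x); N <- ncol(A)
  if (is.null(h0)) h0 <- matrix(0, E, N)
  h <- h0
  y <- matrix(0, L, E)
  for (t in seq_len(L)) {
    hn <- matrix(0, E, N)
    for (e in seq_len(E)) {
      for (n in seq_len(N)) {
        ab <- exp(delta[t, e] * A[e, n])
        hn[e, n] <- ab * h[e, n] + delta[t, e] * B[t, n] * x[t, e]
      }
    }
    h <- hn
    for (e in seq_len(E))
      y[t, e] <- sum(h[e, ] * C[t, ]) + D_skip[e] * x[t, e]
  }
  y
}

rand_scan_instance <- function(L, E = 4L, N = 3L) {
  list(delta = matrix(stats::runif(L * E, 0.01, 0.5), L, E),
       A = -matrix(stats::runif(E * N, 0.1, 2), E, N),
       B = matrix(stats::rnorm(L * N), L, N),
       C = matrix(stats::rnorm(L * N), L, N),
       D_skip = stats::rnorm(E),
       x = matrix(stats::rnorm(L * E), L, E))
}
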