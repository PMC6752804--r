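# Independent brute-force oracle for degree-2 signatures: fine-grid
# accumulation of the iterated integrals of the piecewise-linear
# interpolant, S^(i,j) = integral of (X_i(t) - X_i(a)) dX_j(t).
# Deliberately shares no code with the tensor-algebra implementation.
riemann_signature2 <- function(path, refine = 200L) {
  tt <- path$times
  v <- path$values
  d <- ncol(v)
  n <- length(tt)
  s1 <- unname(v[n, ] - v[1, ])
  s2 <- matrix(0, d, d)
  if (n >= 2L) {
    for (seg in seq_len(n - 1L)) {
      grid <- seq(tt[seg], tt[seg + 1L], length.out = refine + 1L)
      frac_mid <- ((grid[-1L] + grid[-length(grid)]) / 2 - tt[seg]) /
        (tt[seg + 1L] - tt[seg])
      frac_step <- diff(grid) / (tt[seg + 1L] - tt[seg])
      for (i in seq_len(d)) {
        xi_mid <- v[seg, i] + frac_mid * (v[seg + 1L, i] - v[seg, i]) - v[1L, i]
        for (j in seq_len(d)) {
          dxj <- frac_step * (v[seg + 1L, j] - v[seg, j])
          s2[i, j] <- s2[i, j] + sum(xi_mid * dxj)
        }
      }
    }
  }
  list(s1 = s1, s2 = s2)
}

# flatten a signature_tensor's level-2 block into the same matrix layout
level2_matrix <- function(sig) {
  matrix(sig$levels[[3L]], nrow = sig$dim, byrow = TRUE)
}

random_path <- function(d, n, scale = 10) {
  labeled_path(cumsum(runif(n, 0.5, 2)),
               matrix(rnorm(n * d, 0, scale), n, d))
}

# the printed worked-example path
fig_path <- function() {
  labeled_path(0:4, cbind(c(2, 4, 6, 8, 10), c(1, 2, 8, 9, 10)))
}
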