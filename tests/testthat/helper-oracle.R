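# Independent oracles.  Everything here is implemented from first principles
# (closed forms, quadrature, exhaustive search, 1-D root finding on the
# steady-state algebra) and deliberately does not call the package's solver
# or fitting paths.

# depth-averaged light factor by brute-force quadrature over depth slices
oracle_light <- function(A, I_in, h_I, k_bg, k_A, z_max, n_slices = 1e4) {
  k <- k_bg + k_A * A
  z <- (seq_len(n_slices) - 0.5) / n_slices * z_max
  I <- I_in * exp(-k * z)
  mean(I / (h_I + I))
}

# steady state of the fixed-quota chemostat by 1-D root finding: at any
# non-washout equilibrium mu = a, so N = N_in - c_N A and P = P_in - c_P A,
# leaving a single decreasing function of A to bisect.
oracle_steady <- function(p, N_in, P_in) {
  fI <- function(A) {
    k <- p$k_bg + p$k_A * A
    kz <- k * p$z_max
    log((p$h_I + p$I_in) / (p$h_I + p$I_in * exp(-kz))) / kz
  }
  g <- function(A) {
    N <- N_in - p$c_N * A
    P <- P_in - p$c_P * A
    if (N <= 0 || P <= 0) return(-p$a)
    p$mu_max * min(N / (p$m_N + N), P / (p$m_P + P), fI(A)) - p$a
  }
  if (g(1e-9) <= 0)
    return(list(A = 0, N = N_in, P = P_in, washout = TRUE))
  A_hi <- min(N_in / p$c_N, P_in / p$c_P) * (1 - 1e-12)
  A <- stats::uniroot(g, c(1e-9, A_hi), tol = 1e-12)$root
  list(A = A, N = N_in - p$c_N * A, P = P_in - p$c_P * A, washout = FALSE)
}

# exhaustive profiled-breakpoint search on an equally spaced candidate grid
oracle_hinge_exhaustive <- function(x, y, window, n_grid = 2000) {
  grid <- seq(window[1], window[2], length.out = n_grid)
  rss <- vapply(grid, function(ps) {
    sum(stats::lm.fit(cbind(1, x, pmax(0, x - ps)), y)$residuals^2)
  }, numeric(1))
  list(psi = grid[which.min(rss)], step = diff(grid)[1])
}
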