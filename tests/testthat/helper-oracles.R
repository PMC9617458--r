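# Shared fixtures and independent oracles, all built in code.

# Adaptive-quadrature oracle for the conditional partition integral,
# computed on a shifted integrand so the quadrature never overflows.
# Independent of the package's closed-form branches.
quad_log_partition <- function(a, b, u) {
  f <- function(s) a * s + 0.5 * b * s^2
  m <- max(f(0), f(u), if (b < 0 && -a / b > 0 && -a / b < u) f(-a / b) else -Inf)
  log(stats::integrate(function(s) exp(f(s) - m), 0, u,
                       rel.tol = 1e-12, abs.tol = 0)$value) + m
}

# Dirichlet draws (compositions) via gamma normalization.
rdirichlet_table <- function(D, alpha) {
  g <- matrix(stats::rgamma(D * length(alpha), shape = alpha),
              nrow = D, byrow = TRUE)
  composition_table(g / rowSums(g))
}

# A random valid refined CME model (symmetric K, zero diagonal, h_N = 0).
random_cme <- function(N, h_scale = 2, K_scale = 5) {
  h <- c(stats::runif(N - 1, -h_scale, h_scale), 0)
  K <- matrix(0, N, N)
  K[upper.tri(K)] <- stats::runif(N * (N - 1) / 2, -K_scale, K_scale)
  K <- K + t(K)
  cme_parameters(h, K)
}

# A random (possibly asymmetric) tilde parameterization.
random_tilde <- function(N, scale = 3) {
  tilde_parameters(stats::runif(N - 1, -scale, scale),
                   matrix(stats::runif((N - 1)^2, -scale, scale), N - 1))
}
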