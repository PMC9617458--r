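# Stable evaluation of the one-dimensional conditional partition integrals
#
#   Z(a, b, u) = int_0^u exp(a s + b s^2 / 2) ds
#
# and the first two moments E[s], E[s^2] of the corresponding density on
# [0, u].  These are the workhorses of the simplex pseudolikelihood: for
# each sample and node, a collects the linear field acting on the node and
# b is the node's tilde self-coupling.  Everything is computed in the log
# domain via three branches chosen per element:
#
#   * a truncated-exponential expansion in b when the quadratic term is a
#     small perturbation (|b| u^2 tiny, or |b| << a^2 so the quadratic never
#     competes with the linear decay on the effective support);
#   * for b < 0, the truncated-Gaussian closed form via log-domain normal
#     CDF differences (stable in both tails);
#   * for b > 0, the imaginary-error-function branch written with the
#     Dawson function so that only bounded factors are ever exponentiated.

# Dawson function D(x) = exp(-x^2) int_0^x exp(t^2) dt, accurate to ~1e-12.
# Small |x|: Maclaurin series.  Otherwise Rybicki's sampling-theorem
# expansion D(x) = pi^{-1/2} sum_{k odd} exp(-(x - k h)^2) / k, whose error
# is O(exp(-pi^2 / (4 h^2))); h = 0.25 puts that near 1e-17.
.dawson <- function(x) {
  sgn <- sign(x)
  x <- abs(x)
  out <- numeric(length(x))
  small <- x < 0.2
  if (any(small)) {
    x2 <- x[small]^2
    out[small] <- x[small] *
      (1 - 2 * x2 / 3 + 4 * x2^2 / 15 - 8 * x2^3 / 105 + 16 * x2^4 / 945 -
         32 * x2^5 / 10395 + 64 * x2^6 / 135135)
  }
  if (any(!small)) {
    h <- 0.25
    off <- seq(-53L, 53L, by = 2L)
    out[!small] <- vapply(x[!small], function(xx) {
      k <- 2 * floor(xx / (2 * h)) + off  # odd integers bracketing x / h
      xp <- xx - k * h
      sum(exp(-xp * xp) / k) / sqrt(pi)
    }, numeric(1))
  }
  sgn * out
}

# log(Phi(beta) - Phi(alpha)) for beta >= alpha, stable in both tails.
.log_phi_diff <- function(alpha, beta) {
  n <- length(alpha)
  out <- numeric(n)
  lo <- alpha >= 0                 # both args in the upper tail
  hi <- !lo & beta <= 0            # both args in the lower tail
  mid <- !lo & !hi
  if (any(lo)) {
    la <- stats::pnorm(alpha[lo], lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(beta[lo], lower.tail = FALSE, log.p = TRUE)
    out[lo] <- la + log1p(-exp(lb - la))
  }
  if (any(hi)) {
    la <- stats::pnorm(alpha[hi], log.p = TRUE)
    lb <- stats::pnorm(beta[hi], log.p = TRUE)
    out[hi] <- lb + log1p(-exp(la - lb))
  }
  if (any(mid)) {
    out[mid] <- log(stats::pnorm(beta[mid]) - stats::pnorm(alpha[mid]))
  }
  out
}

# Moments of the truncated exponential density ~ exp(a s) on [0, u]:
# returns log I0 with I0 = int_0^u e^{a s} ds and the moment ratios
# J_k = int_0^u s^k e^{a s} ds / I0 for k = 1..7.  Power series in a*u for
# moderate arguments, upward recurrence otherwise.
.trunc_exp_moments <- function(a, u) {
  n <- length(a)
  t <- a * u
  logI0 <- numeric(n)
  J <- matrix(0, n, 7L)
  ps <- abs(t) <= 10
  if (any(ps)) {
    tp <- t[ps]
    S <- matrix(0, length(tp), 8L)  # S_k = sum_m t^m / (m! (m + k + 1))
    term <- rep(1, length(tp))
    for (m in 0:60) {
      for (k in 0:7) S[, k + 1L] <- S[, k + 1L] + term / (m + k + 1)
      term <- term * tp / (m + 1)
    }
    logI0[ps] <- log(u[ps]) + log(S[, 1L])
    for (k in 1:7) J[ps, k] <- u[ps]^k * S[, k + 1L] / S[, 1L]
  }
  if (any(!ps)) {
    ar <- a[!ps]; ur <- u[!ps]; tr <- t[!ps]
    pos <- tr > 0
    eps <- numeric(length(ar))          # e^{a u} / I0
    eps[pos] <- ar[pos] / (-expm1(-tr[pos]))
    eps[!pos] <- ar[!pos] * exp(tr[!pos]) / expm1(tr[!pos])
    lI <- numeric(length(ar))
    lI[pos] <- tr[pos] - log(ar[pos]) + log1p(-exp(-tr[pos]))
    lI[!pos] <- log1p(-exp(tr[!pos])) - log(-ar[!pos])
    logI0[!ps] <- lI
    Jprev <- rep(1, length(ar))
    for (k in 1:7) {
      Jk <- (ur^k * eps - k * Jprev) / ar
      J[!ps, k] <- Jk
      Jprev <- Jk
    }
  }
  list(logI0 = logI0, J = J)
}

# Mills ratio Phibar(z) / phi(z), z >= 8 (deep-tail scaling).  Laplace's
# continued fraction evaluated backward; full double precision for z >= 8.
.mills <- function(z) {
  r <- 0
  for (k in 60:1) r <- k / (z + r)
  1 / (z + r)
}

# Core routine: log Z(a, b, u) and, optionally, the first two moments of
# the density exp(a s + b s^2 / 2) / Z on [0, u].  Vectorized over a, b, u.
.cond_partition <- function(a, b, upper, moments = TRUE) {
  n <- max(length(a), length(b), length(upper))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  u <- rep_len(as.numeric(upper), n)
  if (any(u < 0)) stop("integration upper limit must be nonnegative (inconsistent sample)")
  logZ <- rep(-Inf, n)
  E1 <- numeric(n)
  E2 <- numeric(n)
  pos <- u > 0
  fu <- a * u + 0.5 * b * u^2

  # perturbative branch: the quadratic term never competes with the linear
  # slope at the dominating endpoint, so expand about a truncated exponential
  series <- pos & ((abs(b) * u^2 < 1e-6) |
                     (abs(b) < 1e-3 * pmin(a^2, (a + b * u)^2)))
  if (any(series)) {
    i <- which(series)
    refl <- fu[i] > 0                  # expand about the dominant endpoint
    ae <- ifelse(refl, -(a[i] + b[i] * u[i]), a[i])
    shift <- ifelse(refl, fu[i], 0)
    tm <- .trunc_exp_moments(ae, u[i])
    bb <- b[i]
    c1 <- 0.5 * bb * tm$J[, 2L]
    c2 <- 0.125 * bb^2 * tm$J[, 4L]
    c3 <- bb^3 * tm$J[, 6L] / 48
    den <- 1 + c1 + c2 + c3
    logZ[i] <- shift + tm$logI0 + log1p(c1 + c2 + c3)
    if (moments) {
      e1 <- tm$J[, 1L] +
        (0.5 * bb * (tm$J[, 3L] - tm$J[, 2L] * tm$J[, 1L]) +
           0.125 * bb^2 * (tm$J[, 5L] - tm$J[, 4L] * tm$J[, 1L]) +
           (bb^3 / 48) * (tm$J[, 7L] - tm$J[, 6L] * tm$J[, 1L])) / den
      e2 <- (tm$J[, 2L] + 0.5 * bb * tm$J[, 4L] + 0.125 * bb^2 * tm$J[, 6L]) / den
      E1[i] <- ifelse(refl, u[i] - e1, e1)
      E2[i] <- ifelse(refl, u[i]^2 - 2 * u[i] * e1 + e2, e2)
    }
  }

  gauss <- pos & !series & b < 0
  if (any(gauss)) {
    i <- which(gauss)
    sig <- 1 / sqrt(-b[i])
    mu <- -a[i] / b[i]
    alpha <- -mu / sig
    beta <- (u[i] - mu) / sig
    lZd <- .log_phi_diff(alpha, beta)
    logZ[i] <- log(sig) + 0.5 * log(2 * pi) - a[i]^2 / (2 * b[i]) + lZd
    if (moments) {
      # hazard ratios phi(alpha)/Zd, phi(beta)/Zd; in deep same-side tails
      # use scaled Mills ratios so no large log is ever exponentiated
      ra <- numeric(length(i))
      rb <- numeric(length(i))
      lo_tail <- alpha >= 8                       # mass piled near s = 0
      hi_tail <- beta <= -8                       # mass piled near s = u
      mid <- !lo_tail & !hi_tail
      if (any(mid)) {
        ra[mid] <- exp(stats::dnorm(alpha[mid], log = TRUE) - lZd[mid])
        rb[mid] <- exp(stats::dnorm(beta[mid], log = TRUE) - lZd[mid])
      }
      if (any(lo_tail)) {
        Ra <- .mills(alpha[lo_tail]); Rb <- .mills(beta[lo_tail])
        d2 <- (alpha[lo_tail] - beta[lo_tail]) * (alpha[lo_tail] + beta[lo_tail]) / 2
        ra[lo_tail] <- 1 / (Ra - Rb * exp(d2))
        rb[lo_tail] <- 1 / (Ra * exp(-d2) - Rb)
      }
      if (any(hi_tail)) {
        Ra <- .mills(-alpha[hi_tail]); Rb <- .mills(-beta[hi_tail])
        d2 <- (alpha[hi_tail] - beta[hi_tail]) * (alpha[hi_tail] + beta[hi_tail]) / 2
        ra[hi_tail] <- 1 / (Rb * exp(d2) - Ra)
        rb[hi_tail] <- 1 / (Rb - Ra * exp(-d2))
      }
      E1[i] <- mu + sig * (ra - rb)
      E2[i] <- mu^2 + sig^2 + 2 * mu * sig * (ra - rb) +
        sig^2 * (alpha * ra - beta * rb)
    }
  }

  daws <- pos & !series & b > 0
  if (any(daws)) {
    i <- which(daws)
    w <- sqrt(b[i] / 2)
    x1 <- a[i] / (2 * w)
    x2 <- x1 + w * u[i]
    m <- pmax(0, fu[i])
    t2 <- exp(fu[i] - m) * .dawson(x2)
    t1 <- exp(-m) * .dawson(x1)
    logZ[i] <- m + log(t2 - t1) - log(w)
    if (moments) {
      Gm <- exp(logZ[i] - m)
      e1 <- (exp(fu[i] - m) - exp(-m) - a[i] * Gm) / (b[i] * Gm)
      e2 <- (u[i] * exp(fu[i] - m) - Gm - a[i] * e1 * Gm) / (b[i] * Gm)
      E1[i] <- e1
      E2[i] <- e2
    }
  }

  if (moments) {
    # guard against last-digit excursions outside the feasible range
    E1 <- pmin(pmax(E1, 0), u)
    E2 <- pmin(pmax(E2, E1^2), u * E1)
    list(logZ = logZ, E1 = E1, E2 = E2)
  } else {
    list(logZ = logZ)
  }
}

#' Log-partition of a CME conditional
#'
#' Computes \eqn{\log \tilde Z = \log \int_0^{u} \exp(a s + \frac12 b s^2)\,
#' ds}, the normalizer of the one-dimensional conditional distribution of a
#' single component given the others.  Here `a` is the linear field
#' \eqn{\tilde h_i + \sum_{j \ne i} \tilde K_{ij} s_j}, `b` the tilde
#' self-coupling \eqn{\tilde K_{ii}}, and `upper` the integration limit
#' \eqn{1 - \sum_{j \ne i, j < N} s_j} imposed by the simplex.  The value is
#' computed by numerically stable closed forms (truncated-Gaussian,
#' Dawson-function, and perturbative-in-`b` branches, all in the log
#' domain), accurate to relative error below 1e-10 against adaptive
#' quadrature; overflow cannot occur.
#'
#' @param a numeric vector of linear coefficients.
#' @param b numeric vector (or scalar) of quadratic coefficients.
#' @param upper numeric vector of nonnegative integration limits.
#' @return numeric vector of log-partition values (`-Inf` where
#'   `upper == 0`).
#' @export
conditional_log_partition <- function(a, b, upper) {
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    stop("a and b must be finite")
  }
  .cond_partition(a, b, upper, moments = FALSE)$logZ
}

#' Conditioning context for one component of one sample
#'
#' Bundles what the conditional distribution of component `i` (one of the
#' free components `1..N-1`) sees in a single sample: the other free
#' coordinates `s_rest` and the resulting integration upper limit
#' `1 - sum(s_rest)` (the share left over for component `i` and the
#' reference component `N` together).
#'
#' @param i index of the conditioned component (in `1..N-1`).
#' @param s_rest numeric vector of the remaining `N-2` free coordinates,
#'   in the order of the free components with component `i` removed.
#' @return an object of class `conditional_context` with fields `i`,
#'   `s_rest`, `upper`.
#' @export
conditional_context <- function(i, s_rest) {
  s_rest <- as.numeric(s_rest)
  if (any(s_rest < 0)) stop("free coordinates must be nonnegative")
  tot <- sum(s_rest)
  if (tot > 1 + 1e-8) stop("free coordinates exceed the simplex budget")
  structure(list(i = as.integer(i), s_rest = s_rest,
                 upper = min(max(1 - tot, 0), 1)),
            class = "conditional_context")
}

#' Conditional log-density of one component
#'
#' Log of \eqn{P(s_i \mid s_{\sim i}) = \tilde Z_i^{-1} \exp[(\tilde h_i +
#' \frac12 \tilde K_{ii} s_i + \sum_{j \ne i} \tilde K_{ij} s_j) s_i]}, the
#' exact one-dimensional conditional of the CME model used by the
#' pseudolikelihood.  It integrates to 1 over `[0, ctx$upper]`.
#'
#' @param s_i value of the conditioned coordinate, in `[0, ctx$upper]`.
#' @param ctx a [conditional_context()].
#' @param tilde a [tilde_parameters()] object.
#' @return scalar log-density.
#' @export
conditional_log_density <- function(s_i, ctx, tilde) {
  stopifnot(inherits(ctx, "conditional_context"),
            inherits(tilde, "tilde_parameters"))
  n <- tilde$N - 1L
  if (length(ctx$s_rest) != n - 1L) {
    stop("context has the wrong number of free coordinates for this model")
  }
  if (s_i < -1e-12 || s_i > ctx$upper + 1e-12) {
    stop("s_i must lie in [0, upper]")
  }
  i <- ctx$i
  rest <- setdiff(seq_len(n), i)
  a <- tilde$h_tilde[i] + sum(tilde$K_tilde[i, rest] * ctx$s_rest)
  b <- tilde$K_tilde[i, i]
  a * s_i + 0.5 * b * s_i^2 -
    conditional_log_partition(a, b, max(ctx$upper, 1e-12))
}
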