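# Monte-Carlo simulation from CME models.
#
# The chain is a Metropolis random walk on the simplex with pairwise
# exchange proposals: pick two components and transfer a uniform random
# amount between them.  The sum constraint is preserved exactly by
# construction and boundary zeros are handled naturally (proposals leaving
# the simplex are rejected, which is a valid Metropolis rule for a
# symmetric proposal).  A small fraction of proposals draw the transfer
# from the full range so that well-separated modes (strong competition)
# are still exchanged.

#' Sampler configuration
#'
#' @param n_samples number of retained draws.
#' @param burn_in number of discarded warm-up steps (default `10000 * N`,
#'   filled in by the sampler when `NULL`).
#' @param thin keep every `thin`-th step after burn-in (default `N`, filled
#'   in by the sampler when `NULL`).
#' @param step_scale initial half-width of the uniform transfer proposal,
#'   as a fraction of the simplex scale; adapted during burn-in toward a
#'   30-50% acceptance rate and frozen afterwards so the equilibrium
#'   distribution is untouched.
#' @param seed integer seed for reproducibility.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(n_samples, burn_in = NULL, thin = NULL,
                           step_scale = 0.1, seed = 1L) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (!is.null(burn_in) && burn_in < 0) stop("burn_in must be >= 0")
  if (!is.null(thin) && thin < 1L) stop("thin must be >= 1")
  if (step_scale <= 0 || step_scale > 1) stop("step_scale must be in (0, 1]")
  structure(list(n_samples = as.integer(n_samples), burn_in = burn_in,
                 thin = thin, step_scale = step_scale, seed = as.integer(seed)),
            class = "sampler_config")
}

#' Simulate compositions from a CME model
#'
#' Draws approximately from the CME distribution by a Metropolis chain with
#' pairwise-exchange proposals.  Every draw lies exactly on the simplex.
#' Deterministic given `(params, config)`.
#'
#' @param params a [cme_parameters()] object.
#' @param config a [sampler_config()] (or an integer, shorthand for
#'   `sampler_config(n_samples = config)`).
#' @return a [composition_table()] of `n_samples` draws.
#' @export
cme_sample <- function(params, config) {
  stopifnot(inherits(params, "cme_parameters"))
  if (is.numeric(config)) config <- sampler_config(config)
  stopifnot(inherits(config, "sampler_config"))
  N <- params$N
  if (N > 20L || max(abs(params$K)) > 50) {
    warning("Monte-Carlo simulation is expensive for large or strongly ",
            "interacting networks; expect slow mixing")
  }
  burn_in <- if (is.null(config$burn_in)) 10000L * N else as.integer(config$burn_in)
  thin <- if (is.null(config$thin)) N else as.integer(config$thin)
  n_keep <- config$n_samples
  n_steps <- burn_in + n_keep * thin

  set.seed(config$seed)
  h <- params$h
  K <- params$K
  s <- rep(1 / N, N)
  Ks <- drop(K %*% s)
  w <- config$step_scale
  p_global <- 0.1

  # pre-generate all randomness for speed and reproducibility
  ii <- sample.int(N, n_steps, replace = TRUE)
  jo <- sample.int(N - 1L, n_steps, replace = TRUE)
  glob <- stats::runif(n_steps) < p_global
  dl <- stats::runif(n_steps, -1, 1)
  ul <- stats::runif(n_steps)

  out <- matrix(0, n_keep, N)
  kept <- 0L
  acc_win <- 0L
  win <- 0L
  for (t in seq_len(n_steps)) {
    i <- ii[t]
    j <- jo[t]
    if (j >= i) j <- j + 1L
    delta <- if (glob[t]) dl[t] else dl[t] * w
    si <- s[i] + delta
    sj <- s[j] - delta
    if (si >= 0 && sj >= 0) {
      dE <- delta * (h[i] - h[j] + Ks[i] - Ks[j]) - delta^2 * K[i, j]
      if (dE >= 0 || ul[t] < exp(dE)) {
        s[i] <- si
        s[j] <- sj
        Ks <- Ks + delta * (K[, i] - K[, j])
        acc_win <- acc_win + 1L
      }
    }
    if (t <= burn_in) {
      win <- win + 1L
      if (win == 200L) {            # adapt only during burn-in
        rate <- acc_win / 200
        if (rate > 0.5) w <- min(w * 1.25, 1)
        if (rate < 0.3) w <- max(w / 1.25, 1e-3)
        acc_win <- 0L
        win <- 0L
      }
    } else if ((t - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- s
    }
  }
  composition_table(out, component_names = params$component_names,
                    renorm_tol = 1e-9)
}

#' Monte-Carlo moment estimates for a CME model
#'
#' Simulates from the model with [cme_sample()] and summarizes the draws
#' with [compute_moments()], attaching batch-means Monte-Carlo standard
#' errors (attributes `se_M` and `se_Sigma`) so that agreement checks can
#' be framed in standard errors rather than fixed deltas.
#'
#' @inheritParams cme_sample
#' @param batches number of batches for the batch-means standard errors.
#' @return a `moment_summary` with standard-error attributes.
#' @export
estimate_moments <- function(params, config, batches = 25L) {
  if (is.numeric(config)) config <- sampler_config(config)
  draws <- cme_sample(params, config)
  ms <- compute_moments(draws)
  s <- unclass(draws)
  n <- nrow(s)
  N <- ncol(s)
  bid <- cut(seq_len(n), breaks = batches, labels = FALSE)
  bM <- apply(s, 2L, function(col) tapply(col, bid, mean))
  se_M <- apply(bM, 2L, stats::sd) / sqrt(batches)
  se_Sigma <- matrix(0, N, N)
  bmu <- colMeans(bM)
  for (i in seq_len(N)) {
    for (j in i:N) {
      bcov <- tapply(s[, i] * s[, j], bid, mean) - bM[, i] * bM[, j]
      se_Sigma[i, j] <- se_Sigma[j, i] <- stats::sd(bcov) / sqrt(batches)
    }
  }
  attr(ms, "se_M") <- se_M
  attr(ms, "se_Sigma") <- se_Sigma
  attr(ms, "n_samples") <- n
  ms
}

# unnormalized density exponent at free coordinates x (reference absorbs
# the remainder); x is a matrix with one row per point
.cme_exponent <- function(x, params) {
  sN <- 1 - rowSums(x)
  s <- cbind(x, sN)
  # order: free components in original order with reference last
  idx <- c(setdiff(seq_len(params$N), params$reference), params$reference)
  h <- params$h[idx]
  K <- params$K[idx, idx, drop = FALSE]
  drop(s %*% h) + 0.5 * rowSums((s %*% K) * s)
}

#' Deterministic moments of a small CME model by nested quadrature
#'
#' Ground-truth first and second moments of the CME distribution for
#' `N <= 4`, computed by iterated one-dimensional adaptive quadrature over
#' the simplex.  Serves as the oracle against which the Monte-Carlo sampler
#' is validated; refuses larger `N` on cost grounds.
#'
#' @param params a [cme_parameters()] object with `params$N <= 4`.
#' @param rel_tol quadrature relative tolerance per dimension.
#' @return a `moment_summary`.
#' @export
brute_force_moments <- function(params, rel_tol = 1e-10) {
  stopifnot(inherits(params, "cme_parameters"))
  N <- params$N
  if (N > 4L) stop("brute-force quadrature is limited to N <= 4 (cost)")
  n_free <- N - 1L
  # max exponent over a coarse grid, to scale the integrand into range
  gr <- as.matrix(expand.grid(rep(list(seq(0, 1, length.out = 21L)), n_free)))
  gr <- gr[rowSums(gr) <= 1 + 1e-12, , drop = FALSE]
  m0 <- max(.cme_exponent(gr, params))

  # integrand(x) = g(x) * exp(exponent - m0), integrated by iterated
  # 1-D quadrature x1 in [0,1], x2 in [0, 1-x1], ...
  nest <- function(g) {
    f_outer <- function(x_prev) {
      # returns the integral over the remaining coordinates given x_prev
      d <- length(x_prev)
      if (d == n_free) {
        return(g(x_prev) * exp(.cme_exponent(matrix(x_prev, 1L), params) - m0))
      }
      ub <- 1 - sum(x_prev)
      if (ub <= 0) return(0)
      stats::integrate(function(v) vapply(v, function(vi) f_outer(c(x_prev, vi)),
                                          numeric(1)),
                       0, ub, rel.tol = rel_tol, abs.tol = 0)$value
    }
    f_outer(numeric(0))
  }

  idx <- c(setdiff(seq_len(N), params$reference), params$reference)
  coord <- function(x, k) {              # component k (permuted order) at x
    if (k <= n_free) x[k] else 1 - sum(x)
  }
  Z <- nest(function(x) 1)
  M_perm <- vapply(seq_len(N), function(k) nest(function(x) coord(x, k)) / Z,
                   numeric(1))
  chi_perm <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in i:N) {
      chi_perm[i, j] <- chi_perm[j, i] <-
        nest(function(x) coord(x, i) * coord(x, j)) / Z
    }
  }
  inv <- order(idx)
  M <- M_perm[inv]
  chi <- chi_perm[inv, inv, drop = FALSE]
  names(M) <- params$component_names
  dimnames(chi) <- list(params$component_names, params$component_names)
  structure(list(M = M, chi = chi, Sigma = chi - tcrossprod(M), D = NA_integer_),
            class = "moment_summary")
}
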