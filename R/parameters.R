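# CME model parameterizations and the transformations between them.
#
# The CME (compositional maximum entropy) density on the simplex is
#   P(s) = Z^{-1} exp[ sum_i (h_i + 1/2 sum_{j != i} K_ij s_j) s_i ],
# with natural parameters h (node influences) and K (pairwise interactions).
# The simplex constraint makes several parameters redundant; the gauge
# convention h_N = 0, K_ii = 0 fixes them.  The pseudolikelihood works in a
# reduced "tilde" parameterization over components 1..N-1 obtained by
# eliminating component N.

#' Construct refined CME parameters
#'
#' The refined (reportable) parameterization of a CME model: a symmetric
#' interaction matrix `K` with zero diagonal, node influences `h` with
#' `h[N] = 0` (gauge convention), and softmax influence weights `Q`.
#'
#' @param h length-N numeric vector of node influences; `h[reference]` must
#'   be 0.
#' @param K N x N symmetric numeric matrix with zero diagonal.
#' @param component_names optional component labels.
#' @param reference index of the gauge-fixed component whose influence is
#'   pinned to 0 (default: the last component).
#' @param tol tolerance for the symmetry/gauge checks.
#' @return an object of class `cme_parameters` with elements `h`, `K`, `Q`,
#'   `N`, `reference`, `component_names`.
#' @export
cme_parameters <- function(h, K, component_names = NULL, reference = NULL,
                           tol = 1e-8) {
  h <- as.numeric(h)
  K <- as.matrix(K)
  N <- length(h)
  if (N < 2L) stop("need N >= 2 components")
  if (!all(dim(K) == N)) stop("K must be N x N with N = length(h)")
  if (anyNA(h) || anyNA(K) || any(!is.finite(h)) || any(!is.finite(K))) {
    stop("parameters must be finite")
  }
  if (is.null(reference)) reference <- N
  reference <- as.integer(reference)
  if (reference < 1L || reference > N) stop("reference out of range")
  if (max(abs(K - t(K))) > tol) stop("K must be symmetric")
  if (max(abs(diag(K))) > tol) stop("K must have zero diagonal (gauge convention)")
  if (abs(h[reference]) > tol) {
    stop("h[reference] must be 0 (gauge convention)")
  }
  K <- (K + t(K)) / 2
  diag(K) <- 0
  h[reference] <- 0
  if (is.null(component_names)) component_names <- paste0("c", seq_len(N))
  structure(list(h = h, K = K, Q = influence_weights(h), N = N,
                 reference = reference,
                 component_names = component_names),
            class = "cme_parameters")
}

#' @export
print.cme_parameters <- function(x, ...) {
  cat(sprintf("CME model, %d components\n", x$N))
  cat("h:\n"); print(round(stats::setNames(x$h, x$component_names), 5))
  cat("Q (influence weights):\n")
  print(round(stats::setNames(x$Q, x$component_names), 5))
  cat("K (interactions):\n"); print(round(x$K, 5))
  invisible(x)
}

#' Construct tilde (reduced) parameters
#'
#' The per-conditional parameters actually optimized by the pseudolikelihood:
#' `h_tilde` (length N-1) and `K_tilde` ((N-1) x (N-1), diagonal included,
#' not necessarily symmetric) indexed over the free components 1..N-1 after
#' component N is eliminated by the simplex constraint.
#'
#' @param h_tilde length-(N-1) numeric vector.
#' @param K_tilde (N-1) x (N-1) numeric matrix.
#' @return an object of class `tilde_parameters` with elements `h_tilde`,
#'   `K_tilde`, `N`.
#' @export
tilde_parameters <- function(h_tilde, K_tilde) {
  h_tilde <- as.numeric(h_tilde)
  K_tilde <- as.matrix(K_tilde)
  n <- length(h_tilde)
  if (n < 1L) stop("need at least one free component")
  if (!all(dim(K_tilde) == n)) stop("K_tilde must be (N-1) x (N-1)")
  if (anyNA(h_tilde) || anyNA(K_tilde) ||
      any(!is.finite(h_tilde)) || any(!is.finite(K_tilde))) {
    stop("tilde parameters must be finite")
  }
  structure(list(h_tilde = h_tilde, K_tilde = K_tilde, N = n + 1L),
            class = "tilde_parameters")
}

#' Exponent of the CME density
#'
#' Evaluates the unnormalized log-density
#' \eqn{\sum_i (h_i + \frac12 \sum_{j \ne i} K_{ij} s_j) s_i}, i.e. the
#' exponent of the CME distribution without the (intractable) log-partition
#' term.
#'
#' @param s a composition: length-N nonnegative vector summing to 1.
#' @param params a [cme_parameters()] object.
#' @return a scalar.
#' @export
log_unnormalized_density <- function(s, params) {
  stopifnot(inherits(params, "cme_parameters"))
  s <- as.numeric(s)
  if (length(s) != params$N) stop("composition length does not match model size")
  sum(params$h * s) + 0.5 * sum(s * (params$K %*% s))
}

#' Reduce refined parameters to the tilde parameterization
#'
#' Eliminates component N using the simplex constraint:
#' \eqn{\tilde h_i = h_i + \frac12 (K_{iN} + K_{Ni})} and
#' \eqn{\tilde K_{ij} = K_{ij} - K_{iN} - K_{Nj}} for \eqn{i, j \le N-1}
#' (including the diagonal, \eqn{\tilde K_{ii} = -2 K_{iN}} in the symmetric
#' gauge).  For gauge-fixed parameters this map is inverted exactly by
#' [refine_parameters()].
#'
#' @param params a [cme_parameters()] object.
#' @return a [tilde_parameters()] object.
#' @export
tilde_from_refined <- function(params) {
  stopifnot(inherits(params, "cme_parameters"))
  N <- params$N
  # free components in original order, eliminated reference last
  idx <- setdiff(seq_len(N), params$reference)
  r <- params$reference
  K <- params$K
  KiN <- (K[idx, r] + K[r, idx]) / 2
  h_tilde <- params$h[idx] + KiN
  K_tilde <- K[idx, idx, drop = FALSE] -
    matrix(K[idx, r], N - 1L, N - 1L) -
    matrix(K[r, idx], N - 1L, N - 1L, byrow = TRUE)
  tilde_parameters(h_tilde, K_tilde)
}

#' Refine tilde parameters into the reportable gauge
#'
#' Recovers interpretable model parameters from (possibly asymmetric) tilde
#' parameters: \eqn{K_{ij} = \frac12(\tilde K_{ij} + \tilde K_{ji} -
#' \tilde K_{ii} - \tilde K_{jj})}, \eqn{K_{iN} = -\frac12 \tilde K_{ii}},
#' \eqn{h_i = \tilde h_i - K_{iN}}, with \eqn{h_N = 0} and \eqn{K_{ii} = 0}.
#' The output always satisfies the refined-gauge invariants (symmetric K,
#' zero diagonal) even for asymmetric input, which is how independently
#' fitted per-node conditionals are reconciled.
#'
#' @param tilde a [tilde_parameters()] object.
#' @param component_names optional component labels.
#' @return a [cme_parameters()] object.
#' @export
refine_parameters <- function(tilde, component_names = NULL) {
  stopifnot(inherits(tilde, "tilde_parameters"))
  Kt <- tilde$K_tilde
  n <- nrow(Kt)
  N <- n + 1L
  d <- diag(Kt)
  K <- matrix(0, N, N)
  K[seq_len(n), seq_len(n)] <- 0.5 * (Kt + t(Kt) - outer(d, rep(1, n)) -
                                        outer(rep(1, n), d))
  KiN <- -0.5 * d
  K[seq_len(n), N] <- KiN
  K[N, seq_len(n)] <- KiN
  diag(K) <- 0
  h <- c(tilde$h_tilde - KiN, 0)
  cme_parameters(h, K, component_names = component_names)
}

#' Softmax influence weights
#'
#' Normalized node influence \eqn{Q_i = e^{h_i} / \sum_j e^{h_j}}: the
#' relative probability of a configuration dominated by node i.  Invariant
#' under a constant shift of all `h` (the fit itself is only determined up to
#' such a shift), positive, and summing to 1.  Computed stably by subtracting
#' the maximum before exponentiation.
#'
#' @param h numeric vector of node influences (or a [cme_parameters()]
#'   object, whose `h` is used).
#' @return numeric vector of weights summing to 1.
#' @export
influence_weights <- function(h) {
  if (inherits(h, "cme_parameters")) h <- h$h
  h <- as.numeric(h)
  if (anyNA(h) || any(!is.finite(h))) stop("h must be finite")
  e <- exp(h - max(h))
  e / sum(e)
}
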