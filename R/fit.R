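# Simplex pseudolikelihood fitting of CME models.
#
# For each free node i = 1..N-1 the conditional of s_i given the rest is a
# one-dimensional exponential family on [0, upper_d]; the per-node
# pseudolikelihood
#
#   l_PL^i = h~_i M_i + 1/2 K~_ii chi_ii + sum_{j != i} K~_ij chi_ij
#            - D^{-1} sum_d log Z~_i(s^d_{~i})
#
# is concave in (h~_i, K~_i.), so each node is maximized independently by
# quasi-Newton iteration with exact gradients, and the per-node solutions
# are reconciled into a symmetric, zero-diagonal interaction matrix by the
# refinement transformations.

# Per-node data context: everything the node-i objective needs.
.node_data <- function(s, i) {
  n <- ncol(s) - 1L                    # free components
  rest <- setdiff(seq_len(n), i)
  si <- s[, i]
  Sr <- s[, rest, drop = FALSE]
  list(
    i = i, rest = rest,
    si = si, Sr = Sr,
    upper = pmax(1 - rowSums(Sr), 1e-12),
    Mi = mean(si),
    chi_ii = mean(si^2),
    chi_ir = colMeans(si * Sr)
  )
}

# theta = c(h_tilde_i, K_tilde_ii, K_tilde_i,rest)
.node_objective <- function(theta, nd, ridge) {
  a <- theta[1L] + drop(nd$Sr %*% theta[-(1:2)])
  lZ <- .cond_partition(a, theta[2L], nd$upper, moments = FALSE)$logZ
  theta[1L] * nd$Mi + 0.5 * theta[2L] * nd$chi_ii +
    sum(theta[-(1:2)] * nd$chi_ir) - mean(lZ) - ridge * sum(theta^2)
}

.node_gradient <- function(theta, nd, ridge) {
  a <- theta[1L] + drop(nd$Sr %*% theta[-(1:2)])
  cp <- .cond_partition(a, theta[2L], nd$upper, moments = TRUE)
  g <- c(
    nd$Mi - mean(cp$E1),
    0.5 * nd$chi_ii - 0.5 * mean(cp$E2),
    nd$chi_ir - colMeans(nd$Sr * cp$E1)
  )
  unname(g - 2 * ridge * theta)
}

#' Per-node pseudolikelihood objective
#'
#' Evaluates \eqn{\ell_{PL}^i} for one free node: the moment-matching terms
#' minus the sample average of the conditional log-partition.  This equals
#' the average over samples of the conditional log-density of the observed
#' \eqn{s_i^d}, which is the identity the fitter relies on.
#'
#' @param node_i free-node index in `1..N-1` (component N is the reference).
#' @param tilde a [tilde_parameters()] object.
#' @param table a [composition_table()].
#' @return scalar objective value.
#' @export
pseudolikelihood_objective <- function(node_i, tilde, table) {
  stopifnot(inherits(tilde, "tilde_parameters"))
  table <- as_composition_table(table)
  if (ncol(table) != tilde$N) stop("table and tilde parameters disagree on N")
  if (node_i < 1L || node_i > tilde$N - 1L) stop("node_i must be in 1..N-1")
  nd <- .node_data(unclass(table), node_i)
  theta <- c(tilde$h_tilde[node_i], tilde$K_tilde[node_i, node_i],
             tilde$K_tilde[node_i, nd$rest])
  .node_objective(theta, nd, ridge = 0)
}

#' Fit a CME model by simplex pseudolikelihood
#'
#' Maximizes the per-node pseudolikelihood objectives independently
#' (limited-memory quasi-Newton with exact analytic gradients, started from
#' the flat model), then refines the tilde parameters into the reportable
#' gauge: symmetric interaction matrix `K` with zero diagonal, influences
#' `h` with `h[reference] = 0`, and softmax influence weights `Q`.  Each
#' objective is concave, so with non-degenerate data (or `ridge > 0`) the
#' maximizer is unique and the start point only affects speed.
#'
#' The tilde parameterization depends on which component plays the
#' reference role (it is eliminated via the simplex constraint), but the
#' refined `K` and `Q` do not, up to optimizer tolerance.
#'
#' @param table a [composition_table()] (or coercible matrix/data frame).
#' @param ridge nonnegative L2 penalty on the tilde parameters of each node
#'   (default 0).  Required to be positive for degenerate data (a component
#'   constant across samples).
#' @param reference component (name or index) to use as the eliminated
#'   reference component N; defaults to the last column.  Results are
#'   reported in the original column order regardless.
#' @param seed integer recorded in the result for provenance (the fit
#'   itself is deterministic).
#' @param control list of optimizer settings: `maxit` (iteration cap per
#'   node, default 1000), `factr`, `pgtol` (see [stats::optim()]).
#' @return an object of class `cme_fit` with elements `params` (the refined
#'   [cme_parameters()]), `tilde`, `objective_per_node`, `converged`,
#'   `ridge`, `seed`, `reference`, `D`.
#' @export
cme_fit <- function(table, ridge = 0, reference = NULL, seed = NULL,
                    control = list()) {
  table <- as_composition_table(table)
  D <- nrow(table)
  N <- ncol(table)
  if (D < 2L) stop("need at least D = 2 samples to fit")
  if (ridge < 0) stop("ridge must be nonnegative")
  nm <- colnames(table)

  ref <- if (is.null(reference)) N else {
    if (is.character(reference)) match(reference, nm) else as.integer(reference)
  }
  if (is.na(ref) || ref < 1L || ref > N) stop("unknown reference component")
  perm <- c(setdiff(seq_len(N), ref), ref)   # reference goes last
  s <- unclass(table)[, perm, drop = FALSE]

  if (any(apply(s, 2L, stats::var) < 1e-14)) {
    if (ridge <= 0) {
      stop("degenerate data: a component is constant across samples; ",
           "refit with ridge > 0")
    }
    warning("degenerate data (a component is constant across samples); ",
            "proceeding with ridge regularization")
  }

  ctl <- utils::modifyList(list(maxit = 1000L, factr = 1e2, pgtol = 1e-8),
                           control)
  n <- N - 1L
  h_tilde <- numeric(n)
  K_tilde <- matrix(0, n, n)
  objective <- numeric(n)
  converged <- logical(n)
  for (i in seq_len(n)) {
    nd <- .node_data(s, i)
    opt <- stats::optim(
      par = numeric(n + 1L),          # flat model start
      fn = function(th) -.node_objective(th, nd, ridge),
      gr = function(th) -.node_gradient(th, nd, ridge),
      method = "L-BFGS-B",
      control = list(maxit = ctl$maxit, factr = ctl$factr, pgtol = ctl$pgtol)
    )
    h_tilde[i] <- opt$par[1L]
    K_tilde[i, i] <- opt$par[2L]
    K_tilde[i, nd$rest] <- opt$par[-(1:2)]
    objective[i] <- -opt$value + ridge * sum(opt$par^2)
    converged[i] <- opt$convergence == 0L
    if (!converged[i]) {
      warning(sprintf("node %d did not converge within %d iterations (%s)",
                      i, ctl$maxit, opt$message))
    }
  }

  tilde <- tilde_parameters(h_tilde, K_tilde)
  refined_perm <- refine_parameters(tilde, component_names = nm[perm])
  # report in the original column order; h[reference] stays pinned at 0
  inv <- order(perm)
  K <- refined_perm$K[inv, inv, drop = FALSE]
  dimnames(K) <- list(nm, nm)
  params <- cme_parameters(refined_perm$h[inv], K, component_names = nm,
                           reference = ref)

  structure(list(params = params, tilde = tilde,
                 objective_per_node = objective, converged = converged,
                 ridge = ridge, seed = seed, reference = nm[ref], D = D),
            class = "cme_fit")
}

#' @export
print.cme_fit <- function(x, ...) {
  cat(sprintf(
    "CME pseudolikelihood fit: %d components, D = %d samples (reference: %s)\n",
    x$params$N, x$D, x$reference))
  cat(sprintf("ridge = %g; nodes converged: %d / %d\n",
              x$ridge, sum(x$converged), length(x$converged)))
  print(x$params)
  invisible(x)
}
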