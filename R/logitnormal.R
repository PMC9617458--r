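# Logit-normal (logistic-normal) baseline.
#
# The classical alternative for compositional data places a Gaussian on the
# additive log-ratios y_j = log(s_j / s_N).  Its interaction estimate is
# the negated precision matrix of the transformed data, which is then
# symmetrized into the same reportable gauge as the CME interactions so the
# two methods can be compared head to head.  Unlike CME, the log-ratio
# transform cannot natively handle zeros, hence the pseudocount machinery.

#' Additive log-ratio transform
#'
#' Maps compositions to \eqn{y_j = \log((s_j + c) / (s_N + c))},
#' `j = 1..N-1`, with pseudocount `c`.  With zeros present a positive
#' pseudocount is required; this is the zero problem inherent to log-ratio
#' methods.
#'
#' @param table a [composition_table()] (or coercible).
#' @param pseudocount nonnegative scalar added to every part before taking
#'   ratios; `"auto"` uses half the smallest positive value in the table
#'   when zeros are present, 0 otherwise.
#' @return a `D x (N-1)` matrix of log-ratios.
#' @export
logratio_transform <- function(table, pseudocount = "auto") {
  table <- as_composition_table(table)
  s <- unclass(table)
  pc <- .resolve_pseudocount(s, pseudocount)
  if (pc == 0 && any(s == 0)) {
    stop("table contains zeros: the log-ratio transform is undefined ",
         "without a positive pseudocount")
  }
  N <- ncol(s)
  y <- log(s[, -N, drop = FALSE] + pc) - log(s[, N] + pc)
  colnames(y) <- paste0("log(", colnames(s)[-N], "/", colnames(s)[N], ")")
  y
}

.resolve_pseudocount <- function(s, pseudocount) {
  if (identical(pseudocount, "auto")) {
    if (any(s == 0)) min(s[s > 0]) / 2 else 0
  } else {
    pc <- as.numeric(pseudocount)
    if (is.na(pc) || pc < 0) stop("pseudocount must be nonnegative or 'auto'")
    pc
  }
}

#' Fit the logit-normal baseline
#'
#' Estimates the mean and covariance of the log-ratio transformed data,
#' forms the precision-based interaction matrix
#' \eqn{K^*_{LN} = -\Sigma_{LN}^{-1}} over the first `N-1` components, and
#' symmetrizes it into a full N x N zero-diagonal interaction matrix with
#' the same refinement transformation used for CME, so that interactions
#' involving the reference component are also resolved.
#'
#' @inheritParams logratio_transform
#' @param shrink if `TRUE` (or if the covariance is numerically singular
#'   and `shrink = NA`, the default, which then warns), add a small
#'   diagonal ridge `1e-8 * mean(diag(Sigma_LN))` before inversion.
#' @return an object of class `logit_normal_fit` with elements `M_LN`,
#'   `Sigma_LN`, `K_star`, `K_full`, `pseudocount`, `D`.
#' @export
fit_logit_normal <- function(table, pseudocount = "auto", shrink = NA) {
  table <- as_composition_table(table)
  s <- unclass(table)
  D <- nrow(s)
  N <- ncol(s)
  if (D <= N) {
    stop("need D > N samples for an invertible log-ratio covariance")
  }
  pc <- .resolve_pseudocount(s, pseudocount)
  y <- logratio_transform(table, pc)
  M_LN <- colMeans(y)
  Sigma_LN <- stats::cov(y)
  near_singular <- rcond(Sigma_LN) < 1e-12
  use_shrink <- isTRUE(shrink) || (is.na(shrink) && near_singular)
  if (near_singular && is.na(shrink)) {
    warning("log-ratio covariance is near-singular; applying diagonal shrinkage")
  }
  if (use_shrink) {
    Sigma_LN <- Sigma_LN + diag(1e-8 * mean(diag(Sigma_LN)), N - 1L)
  } else if (near_singular) {
    stop("log-ratio covariance is singular; enable shrinkage or provide more samples")
  }
  K_star <- -solve(Sigma_LN)
  K_full <- refine_parameters(
    tilde_parameters(numeric(N - 1L), K_star),
    component_names = colnames(s)
  )$K
  structure(list(M_LN = M_LN, Sigma_LN = Sigma_LN, K_star = K_star,
                 K_full = K_full, pseudocount = pc, D = D),
            class = "logit_normal_fit")
}

#' @export
print.logit_normal_fit <- function(x, ...) {
  cat(sprintf("Logit-normal fit of %d samples (pseudocount %g)\n",
              x$D, x$pseudocount))
  cat("Symmetrized interactions K_full:\n")
  print(round(x$K_full, 5))
  invisible(x)
}
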