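# Compositional data containers: samples on the probability simplex.

#' Construct a composition table
#'
#' A composition table holds `D` samples of relative abundances across `N`
#' named components.  Every row lies on the unit simplex: entries are
#' nonnegative and sum to 1.  Rows whose sum deviates from 1 by at most
#' `renorm_tol` are silently renormalized (relative-abundance tables usually
#' carry rounding error); larger deviations are an error.  Exact zeros are
#' accepted as-is: the CME density is defined on the closed simplex, so no
#' pseudocounts are needed.
#'
#' @param x numeric matrix or data frame, samples in rows, components in
#'   columns.
#' @param component_names optional character vector of `N` unique component
#'   names; defaults to the column names of `x` (or `c1..cN`).
#' @param renorm_tol maximum tolerated deviation of a row sum from 1 before
#'   the row is rejected (default `1e-6`).
#' @return an object of class `composition_table`: a numeric `D x N` matrix
#'   with component names as column names.
#' @export
composition_table <- function(x, component_names = NULL, renorm_tol = 1e-6) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("composition table must be numeric")
  if (nrow(x) < 1L) stop("composition table is empty: need D >= 1 samples")
  if (ncol(x) < 2L) stop("composition table needs N >= 2 components")
  if (anyNA(x)) stop("composition table contains missing values")
  if (any(x < 0)) stop("relative abundances must be nonnegative")
  if (is.null(component_names)) {
    component_names <- colnames(x)
    if (is.null(component_names)) component_names <- paste0("c", seq_len(ncol(x)))
  }
  if (length(component_names) != ncol(x)) {
    stop("need exactly one name per component")
  }
  if (anyDuplicated(component_names)) stop("component names must be unique")
  rs <- rowSums(x)
  bad <- abs(rs - 1) > renorm_tol
  if (any(bad)) {
    stop(sprintf(
      "%d row(s) do not lie on the simplex (first offending row %d has sum %.8g); rows must sum to 1 within %g",
      sum(bad), which(bad)[1L], rs[which(bad)[1L]], renorm_tol
    ))
  }
  x <- x / rs
  colnames(x) <- component_names
  structure(x, class = c("composition_table", "matrix", "array"))
}

#' Test or coerce to a composition table
#' @param x object to test or coerce.
#' @param ... passed to [composition_table()].
#' @return `is_composition_table` returns a logical; `as_composition_table`
#'   returns a validated `composition_table`.
#' @export
as_composition_table <- function(x, ...) {
  if (inherits(x, "composition_table")) x else composition_table(x, ...)
}

#' @rdname as_composition_table
#' @export
is_composition_table <- function(x) inherits(x, "composition_table")

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("Composition table: %d samples x %d components (%s)\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", ")))
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more samples\n", nrow(x) - 6L))
  invisible(x)
}

#' First and second moments of a composition table
#'
#' Computes the first moments \eqn{M_i = \langle s_i \rangle}, second moments
#' \eqn{\chi_{ij} = \langle s_i s_j \rangle} and covariances
#' \eqn{\Sigma_{ij} = \chi_{ij} - M_i M_j} of compositional samples.  The
#' simplex constraint \eqn{\sum_i s_i = 1} induces closure identities that
#' hold exactly for any valid table: \eqn{\sum_i M_i = 1},
#' \eqn{\sum_j \chi_{ij} = M_i}, and every row of \eqn{\Sigma} sums to 0.
#'
#' @param table a [composition_table()] (or coercible matrix).
#' @return an object of class `moment_summary`: a list with elements `M`
#'   (length-N means), `chi` (N x N second moments), `Sigma` (N x N
#'   covariances) and `D` (sample count).
#' @export
compute_moments <- function(table) {
  table <- as_composition_table(table)
  s <- unclass(table)
  D <- nrow(s)
  M <- colMeans(s)
  chi <- crossprod(s) / D
  Sigma <- chi - tcrossprod(M)
  structure(list(M = M, chi = chi, Sigma = Sigma, D = D),
            class = "moment_summary")
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("Moment summary of %d samples, %d components\n", x$D, length(x$M)))
  cat("Means:\n"); print(round(x$M, 6))
  cat("Covariances:\n"); print(round(x$Sigma, 6))
  invisible(x)
}
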