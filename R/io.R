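# Delimited-table and model-document input/output.

#' Read a composition table from CSV/TSV
#'
#' Expects samples as rows and components as columns with a header of
#' component names; an optional first column of (non-numeric) sample IDs is
#' used as row names.  The delimiter is inferred from the file extension
#' (`.csv` comma, anything else tab).  Rows are validated and renormalized
#' under the standard policy (see [composition_table()]).
#'
#' @param path file path.
#' @param renorm_tol row-sum tolerance, as in [composition_table()].
#' @return a [composition_table()].
#' @export
read_composition_table <- function(path, renorm_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table must have a header row and at least 2 columns")
  first_col_ids <- !is.numeric(df[[1L]])
  if (first_col_ids) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  } else {
    ids <- NULL
  }
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric cells in component column(s): ",
         paste(colnames(df)[!num], collapse = ", "))
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  composition_table(m, renorm_tol = renorm_tol)
}

#' Write a composition table to CSV/TSV
#'
#' @param table a [composition_table()].
#' @param path output path; `.csv` writes comma-separated, anything else
#'   tab-separated.  Values carry 12 significant digits so a write/read
#'   round trip is stable at that precision.
#' @return the path, invisibly.
#' @export
write_composition_table <- function(table, path) {
  table <- as_composition_table(table)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- signif(unclass(table), 12L)
  utils::write.table(m, path, sep = sep, quote = FALSE,
                     row.names = !is.null(rownames(m)), col.names = TRUE)
  invisible(path)
}

.model_schema <- "cme-model/1"

#' Serialize and restore fitted CME models
#'
#' Writes a fitted model (or bare parameters) as a flat JSON document
#' holding the component names, `h`, the full `K`, `Q`, and fit metadata
#' (per-node objectives, convergence, ridge, seed, reference component).
#' Reading validates the schema version and reproduces the numbers to
#' 12+ significant digits.
#'
#' @param fit a `cme_fit` or [cme_parameters()] object.
#' @param path output path.
#' @return `write_cme_model` returns the path invisibly; `read_cme_model`
#'   returns a `cme_fit`-like list with `params` and metadata.
#' @export
write_cme_model <- function(fit, path) {
  if (inherits(fit, "cme_parameters")) {
    fit <- list(params = fit, objective_per_node = NULL, converged = NULL,
                ridge = NULL, seed = NULL,
                reference = fit$component_names[fit$reference])
  }
  p <- fit$params
  doc <- list(
    schema = .model_schema,
    N = p$N,
    component_names = p$component_names,
    reference = fit$reference,
    h = p$h,
    K = p$K,
    Q = p$Q,
    fit = list(objective_per_node = fit$objective_per_node,
               converged = fit$converged,
               ridge = fit$ridge,
               seed = fit$seed,
               D = fit$D)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_cme_model
#' @export
read_cme_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse model file (corrupt or truncated): ",
                         conditionMessage(e))
                  })
  if (!identical(doc$schema, .model_schema)) {
    stop("unsupported model schema: expected '", .model_schema, "', found '",
         doc$schema, "'")
  }
  ref <- match(doc$reference, doc$component_names)
  K <- as.matrix(doc$K)
  if (!all(dim(K) == doc$N)) stop("model file has a malformed K matrix")
  dimnames(K) <- list(doc$component_names, doc$component_names)
  params <- cme_parameters(doc$h, K,
                           component_names = doc$component_names,
                           reference = ref)
  structure(list(params = params,
                 objective_per_node = doc$fit$objective_per_node,
                 converged = doc$fit$converged,
                 ridge = doc$fit$ridge, seed = doc$fit$seed,
                 reference = doc$reference, D = doc$fit$D),
            class = "cme_fit")
}
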