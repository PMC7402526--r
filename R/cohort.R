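#' Assemble a compounds x cell-types parameter matrix
#'
#' Builds the matrix fed to the principal-component comparison: one row per
#' compound, one column per cell type, holding total Emax, logEC50, or
#' logIC50 values. Undetermined IC50s have no value; the caller must pick an
#' explicit policy, which is recorded in the result's metadata.
#'
#' @param fits Named list (by compound). For `"emaxT"`/`"logEC50"` each
#'   element is a `drug_parameters` or a `fit_result` carrying one. For
#'   `"logIC50"` each element is a named numeric of IC50s (nM, `NA` =
#'   undetermined) or a list of `inhibition_fit`s.
#' @param value_kind One of `"emaxT"`, `"logEC50"`, `"logIC50"`.
#' @param undetermined Policy for missing logIC50 entries: `"error"`
#'   (default), `"omit_compound"`, or `"impute"` (with `impute_value`).
#' @param impute_value Value used under the `"impute"` policy.
#' @return A `compound_matrix`: numeric matrix with compound rownames, cell
#'   types as columns, and attributes `value_kind` and `metadata`.
#' @export
assemble_parameter_matrix <- function(fits,
                                      value_kind = c("emaxT", "logEC50",
                                                     "logIC50"),
                                      undetermined = c("error",
                                                       "omit_compound",
                                                       "impute"),
                                      impute_value = NULL) {
  value_kind <- match.arg(value_kind)
  undetermined <- match.arg(undetermined)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    stop("fits must be a named list (one element per compound)", call. = FALSE)
  compounds <- sort(names(fits))
  row_of <- function(f, compound) {
    if (inherits(f, "fit_result")) f <- f$drug
    if (inherits(f, "drug_parameters")) {
      if (value_kind == "logIC50")
        stop("logIC50 requested but compound ", compound,
             " supplies drug parameters", call. = FALSE)
      return(switch(value_kind,
                    emaxT = f$emax_total,
                    logEC50 = f$log_ec50)[cell_type_ids()])
    }
    if (value_kind != "logIC50")
      stop("compound ", compound, " supplies IC50s but value_kind is ",
           value_kind, call. = FALSE)
    if (is.list(f))
      f <- vapply(f, function(x) if (isTRUE(x$determined)) x$ic50 else NA_real_,
                  numeric(1))
    log(f[cell_type_ids()])
  }
  m <- t(vapply(compounds, function(cmp) row_of(fits[[cmp]], cmp),
                numeric(13)))
  dimnames(m) <- list(compounds, cell_type_ids())
  dropped <- character(0)
  if (anyNA(m)) {
    gaps <- which(is.na(m), arr.ind = TRUE)
    gap_txt <- paste(rownames(m)[gaps[, 1]], colnames(m)[gaps[, 2]],
                     sep = "/", collapse = ", ")
    if (undetermined == "error")
      stop("undetermined entries with no policy: ", gap_txt, call. = FALSE)
    if (undetermined == "omit_compound") {
      dropped <- unique(rownames(m)[gaps[, 1]])
      m <- m[!rownames(m) %in% dropped, , drop = FALSE]
    } else {
      if (is.null(impute_value))
        stop("impute policy requires impute_value", call. = FALSE)
      m[is.na(m)] <- impute_value
    }
  }
  structure(m, value_kind = value_kind,
            metadata = list(undetermined_policy = undetermined,
                            impute_value = impute_value,
                            dropped_compounds = dropped),
            class = c("compound_matrix", "matrix", "array"))
}

#' Principal-component analysis of compound mechanism profiles
#'
#' Column-mean-centered, unscaled PCA via singular value decomposition
#' (the parameter values already share a scale, so no standardization is
#' applied by default; a standardized variant is available). Loading signs
#' are fixed so each loading vector's largest-magnitude entry is positive,
#' making results deterministic. Loadings are annotated with each
#' variable's correlation to each score vector (used to label the variables
#' driving the top components; threshold 0.1 by convention).
#'
#' @param matrix A `compound_matrix` (or plain compounds x variables matrix),
#'   at least 2 rows.
#' @param standardize Also divide columns by their standard deviation
#'   (default `FALSE`).
#' @return A `pca_result`: list with `scores` (compound x component),
#'   `loadings` (variable x component, orthonormal columns),
#'   `variance_explained` (percent per component, summing to 100 over all
#'   components), `loading_correlations`, and `center`.
#' @export
run_pca <- function(matrix, standardize = FALSE) {
  m <- unclass(matrix)
  if (nrow(m) < 2) stop("PCA needs at least 2 rows", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0)) {
    warning("matrix has zero variance; no components beyond rank 0")
    return(structure(list(scores = m[, 0, drop = FALSE],
                          loadings = t(m)[, 0, drop = FALSE],
                          variance_explained = numeric(0),
                          loading_correlations = NULL,
                          center = colMeans(m)),
                     class = "pca_result"))
  }
  if (standardize && any(sds == 0))
    stop("cannot standardize zero-variance columns", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = standardize)
  # drop numerically-zero components beyond the matrix rank
  keep <- pc$sdev > pc$sdev[1] * 1e-10
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  varpct <- 100 * pc$sdev[keep]^2 / sum(pc$sdev[keep]^2)
  corr <- tryCatch(stats::cor(m, scores), error = function(e) NULL)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = varpct,
                 loading_correlations = corr,
                 center = pc$center),
            class = "pca_result")
}
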