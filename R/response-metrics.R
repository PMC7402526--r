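#' Percent inhibition implied by an IC50
#'
#' `100 * conc / (conc + ic50)`: the cumulative suppression of a readout at
#' a given dose under a one-parameter Hill curve (slope 1, full range).
#'
#' @param conc Dose (nM), `>= 0`. Vectorized.
#' @param ic50 Half-inhibitory concentration (nM), `> 0`.
#' @return Percentage in `[0, 100)`.
#' @export
#' @examples
#' percent_inhibition(25, 25)  # 50
percent_inhibition <- function(conc, ic50) {
  100 * hill_occupancy(conc, ic50)
}

#' Fit an IC50 to one readout's normalized dose-response curve
#'
#' Least-squares fit of `value = 1 - conc / (conc + IC50)` (Hill slope 1,
#' asymptotes fixed at 1 and 0). A readout whose observed values never fall
#' below 0.5 within the tested range is reported as undetermined (the
#' behavior of megakaryocyte- and B-lineage readouts in the assay); a curve
#' rising above baseline is undetermined with a monotonicity warning.
#'
#' @param doses Dose panel (nM), at least 4 points.
#' @param values Normalized viable fractions at those doses.
#' @param readout Optional readout label carried into the result.
#' @return An object of class `inhibition_fit`: list with `readout`, `ic50`
#'   (nM, `NA` when undetermined), `determined`, `residual` (sum of squares).
#' @export
fit_ic50 <- function(doses, values, readout = NA_character_) {
  if (length(doses) < 4L)
    stop("at least 4 dose points are required", call. = FALSE)
  if (length(values) != length(doses))
    stop("doses and values must have equal length", call. = FALSE)
  undet <- function(resid = NA_real_) {
    structure(list(readout = readout, ic50 = NA_real_, determined = FALSE,
                   residual = resid), class = "inhibition_fit")
  }
  if (max(values) > 1 + 1e-6 &&
      stats::cor(doses, values, method = "spearman") > 0) {
    warning("readout increases with dose; IC50 undetermined", call. = FALSE)
    return(undet())
  }
  if (min(values) > 0.5) return(undet())
  # start from the dose bracketing the half-way crossing
  below <- which(values <= 0.5)[1]
  start <- log(doses[max(below, 1)])
  df <- data.frame(conc = doses, value = values)
  fit <- tryCatch(
    minpack.lm::nlsLM(value ~ 1 - conc / (conc + exp(lic50)),
                      data = df, start = list(lic50 = start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(undet())
  ic50 <- exp(stats::coef(fit)[["lic50"]])
  structure(list(readout = readout, ic50 = ic50, determined = TRUE,
                 residual = sum(stats::residuals(fit)^2)),
            class = "inhibition_fit")
}

#' Fit IC50s for every live readout of a dose-response dataset
#'
#' @param data A [dose_response_dataset()].
#' @return Named list of [fit_ic50()] results over the 13 live readouts.
#' @export
fit_ic50_profile <- function(data) {
  stopifnot(inherits(data, "dose_response_dataset"))
  stats::setNames(lapply(cell_type_ids(), function(id)
    fit_ic50(data$doses, data$table[, id], readout = id)),
    cell_type_ids())
}

#' Percent-inhibition matrix across the dose panel
#'
#' Undetermined readouts are shown as 0% suppression at every dose.
#'
#' @param fits Named list of `inhibition_fit` objects (per readout).
#' @param doses Dose panel (nM), default [dose_grid()].
#' @return `length(doses) x length(fits)` matrix of percent inhibition.
#' @export
inhibition_matrix <- function(fits, doses = dose_grid()) {
  m <- vapply(fits, function(f) {
    if (!isTRUE(f$determined)) rep(0, length(doses))
    else percent_inhibition(doses, f$ic50)
  }, numeric(length(doses)))
  m <- matrix(m, nrow = length(doses),
              dimnames = list(as.character(doses), names(fits)))
  m
}
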