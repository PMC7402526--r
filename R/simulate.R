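#' Integrate the hematopoiesis model over an assay time grid
#'
#' Because drug concentration is held constant during the in vitro exposure,
#' the system is linear and time-invariant; the default `method = "expm"`
#' propagates the state exactly with per-interval matrix exponentials. The
#' `"lsoda"` method integrates numerically with [deSolve::ode] (implicit-
#' capable, default relative tolerance 1e-8) and clips numerical undershoot
#' below zero; the two agree to integration tolerance.
#'
#' @param sys A `system_parameters` object.
#' @param drug Optional `drug_parameters` (`NULL` = drug-free).
#' @param conc Drug concentration (nM), constant over the run.
#' @param initial State vector from [model_state()].
#' @param times Increasing vector of times (days), typically within 0-9.
#' @param method `"expm"` (exact) or `"lsoda"`.
#' @param rtol,atol Tolerances for the `"lsoda"` method.
#' @return A `trajectory`: data.frame with `time`, the 13 cell-type readouts
#'   (`Neut` reports active + quiescent), `totalViableCells`, and
#'   `totalDeadCells`. The internal 15-state matrix is kept in
#'   `attr(, "states")`.
#' @export
integrate_model <- function(sys, drug = NULL, conc = 0, initial, times,
                            method = c("expm", "lsoda"),
                            rtol = 1e-8, atol = 1e-8) {
  method <- match.arg(method)
  validate_system_parameters(sys)
  if (!is.null(drug)) validate_drug_parameters(drug)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  y0 <- initial[state_names()]
  if (anyNA(y0)) stop("initial state must name all internal species", call. = FALSE)
  A <- rate_matrix(sys, drug, conc)

  if (method == "expm") {
    out <- matrix(NA_real_, length(times), length(y0),
                  dimnames = list(NULL, state_names()))
    t_prev <- times[1]
    y <- y0
    if (times[1] != 0) y <- drop(mat_exp(A * times[1]) %*% y0)
    out[1, ] <- y
    if (length(times) > 1) {
      dts <- diff(times)
      cache <- list()
      for (i in seq_along(dts)) {
        key <- format(dts[i], digits = 15)
        if (is.null(cache[[key]])) cache[[key]] <- mat_exp(A * dts[i])
        y <- drop(cache[[key]] %*% y)
        out[i + 1, ] <- y
      }
    }
  } else {
    rhs <- function(t, y, p) list(drop(A %*% pmax(y, 0)))
    t_run <- times
    added0 <- FALSE
    if (times[1] > 0) { t_run <- c(0, times); added0 <- TRUE }
    sol <- deSolve::ode(y = y0, times = t_run, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
    if (inherits(sol, "try-error") || anyNA(sol))
      stop("ODE integration failed", call. = FALSE)
    out <- unname(sol[, -1, drop = FALSE])
    if (added0) out <- out[-1, , drop = FALSE]
    colnames(out) <- state_names()
    out[out < 0 & out > -atol * 100] <- 0
  }
  as_trajectory(times, out)
}

# matrix exponential via eigendecomposition with a scaling-and-squaring
# Taylor fallback for defective matrices
mat_exp <- function(M) {
  ev <- eigen(M)
  rc <- tryCatch(rcond(ev$vectors), error = function(e) 0)
  if (is.finite(rc) && rc > 1e-10) {
    E <- ev$vectors %*% diag(exp(ev$values), nrow(M)) %*% solve(ev$vectors)
    return(Re(E))
  }
  # scaling and squaring with a truncated series
  s <- max(0L, ceiling(log2(max(1, norm(M, "1")))))
  Ms <- M / 2^s
  E <- diag(nrow(M)); term <- diag(nrow(M))
  for (k in 1:20) {
    term <- term %*% Ms / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

as_trajectory <- function(times, states) {
  readouts <- states[, cell_type_ids(), drop = FALSE]
  readouts[, "Neut"] <- readouts[, "Neut"] + states[, "NeutQ"]
  df <- data.frame(time = times, readouts,
                   totalViableCells = rowSums(readouts),
                   totalDeadCells = states[, "totalDeadCells"],
                   check.names = FALSE)
  structure(df, states = states, class = c("trajectory", "data.frame"))
}

#' Drug-free control kinetics sampled at assay measurement days
#'
#' @param sys A `system_parameters` object.
#' @param initial State vector from [model_state()].
#' @param days Sampling days (default the assay's 0, 2, 3, 4, 5, 6).
#' @param ... Passed to [integrate_model()].
#' @return A `trajectory` at the requested days.
#' @export
simulate_control_kinetics <- function(sys, initial,
                                      days = c(0, 2, 3, 4, 5, 6), ...) {
  if (length(days) == 1L) {
    st <- matrix(initial[state_names()], 1,
                 dimnames = list(NULL, state_names()))
    if (days[1] != 0)
      return(integrate_model(sys, initial = initial, times = days, ...))
    return(as_trajectory(days, st))
  }
  integrate_model(sys, initial = initial, times = days, ...)
}

#' The assay's printed dose panel (nM)
#' @export
dose_grid <- function() c(0.2, 1, 5, 25, 100, 500, 2500)

#' Simulate a vehicle-normalized dose-response table
#'
#' Runs the model to the readout day at each dose and at vehicle (dose 0)
#' from a shared initial state, and reports each treated day-6 readout
#' divided by its vehicle value, mirroring the assay's well-to-vehicle-mean
#' normalization.
#'
#' @param sys A `system_parameters` object.
#' @param drug A `drug_parameters` object.
#' @param doses Dose panel in nM (default [dose_grid()]).
#' @param initial State vector from [model_state()].
#' @param readout_day Day of measurement (default 6).
#' @param ... Passed to [integrate_model()].
#' @return A `dose_response_simulation`: list with `doses` and `normalized`,
#'   a `length(doses) x 14` matrix over [readout_names()].
#' @export
simulate_dose_response <- function(sys, drug, doses = dose_grid(), initial,
                                   readout_day = 6, ...) {
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  day6 <- function(conc) {
    tr <- integrate_model(sys, drug = drug, conc = conc, initial = initial,
                          times = c(0, readout_day), ...)
    unlist(tr[nrow(tr), readout_names()])
  }
  vehicle <- day6(0)
  ratio <- function(treated) {
    out <- treated / vehicle
    # an empty compartment stays empty under treatment: define 0/0 as 1
    empty <- vehicle == 0
    if (any(empty & treated > 0))
      stop("treated counts positive where vehicle is zero; cannot normalize",
           call. = FALSE)
    out[empty] <- 1
    out
  }
  norm <- t(vapply(doses, function(d) ratio(day6(d)),
                   numeric(length(readout_names()))))
  dimnames(norm) <- list(NULL, readout_names())
  structure(list(doses = doses, normalized = norm, readout_day = readout_day),
            class = "dose_response_simulation")
}
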