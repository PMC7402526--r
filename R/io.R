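#' Read and write kinetic count tables
#'
#' The canonical interchange is a tidy (long) CSV with columns `donor_id`,
#' `day`, `readout`, `cells_per_ml`; a wide table (one `day` column plus one
#' column per readout, optionally `donor_id`) is auto-detected and reshaped
#' on read. Unknown readout names and negative counts are rejected.
#'
#' @param path CSV path.
#' @return [read_kinetics()] returns a [kinetic_dataset()].
#' @export
read_kinetics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("readout", "cells_per_ml") %in% names(df))) {
    wide <- intersect(readout_names(), names(df))
    if (!length(wide) || !"day" %in% names(df))
      stop("kinetic CSV needs columns donor_id, day, readout, cells_per_ml ",
           "(or a wide day x readout table)", call. = FALSE)
    if (!"donor_id" %in% names(df)) df$donor_id <- "donor01"
    df <- do.call(rbind, lapply(wide, function(r)
      data.frame(donor_id = df$donor_id, day = df$day, readout = r,
                 cells_per_ml = df[[r]])))
  }
  kinetic_dataset(df)
}

#' @rdname read_kinetics
#' @param data A [kinetic_dataset()].
#' @export
write_kinetics <- function(data, path) {
  utils::write.csv(data$donors, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write dose-response tables
#'
#' Long CSV with columns `compound`, `dose_nM`, `readout`,
#' `normalized_value`. Values are vehicle-normalized (1 = no change).
#'
#' @param path CSV path.
#' @return A [dose_response_dataset()], or a named list of them when the
#'   file holds several compounds.
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound", "dose_nM", "readout", "normalized_value")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("dose-response CSV missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$readout), readout_names())
  if (length(bad))
    stop("unknown readout(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(df$normalized_value < 0))
    stop("normalized values must be non-negative", call. = FALSE)
  one <- function(sub) {
    doses <- sort(unique(sub$dose_nM))
    tab <- matrix(NA_real_, length(doses), length(readout_names()),
                  dimnames = list(NULL, readout_names()))
    tab[cbind(match(sub$dose_nM, doses), match(sub$readout, readout_names()))] <-
      sub$normalized_value
    if (anyNA(tab))
      stop("incomplete dose x readout grid for compound ",
           sub$compound[1], call. = FALSE)
    dose_response_dataset(sub$compound[1], doses, tab)
  }
  split_df <- split(df, df$compound)
  out <- lapply(split_df, one)
  if (length(out) == 1L) out[[1]] else out
}

#' @rdname read_dose_response
#' @param data A [dose_response_dataset()].
#' @export
write_dose_response <- function(data, path) {
  df <- data.frame(
    compound = data$compound,
    dose_nM = rep(data$doses, times = ncol(data$table)),
    readout = rep(colnames(data$table), each = length(data$doses)),
    normalized_value = as.vector(data$table)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check a dose panel against the assay's printed grid
#'
#' @param doses Numeric vector of doses (nM).
#' @return `TRUE` invisibly; stops if the panel is not non-negative and
#'   strictly increasing.
#' @export
check_dose_grid <- function(doses) {
  if (any(doses < 0) || is.unsorted(doses, strictly = TRUE))
    stop("doses must be non-negative and strictly increasing", call. = FALSE)
  invisible(TRUE)
}

#' Write and read model parameters as flat JSON
#'
#' Canonical key names: `kappa_<CellType>`, `rho_<CellType>`,
#' `beta_<Parent>_<Child>`, `delta`, `k_quiescence` for system parameters;
#' `emaxT_<CellType>` and `logEC50_<CellType>` for drug parameters. EC50 is
#' stored as its natural log; the derived `EC50_<CellType>` values are echoed
#' into the file for readability and ignored on read. Out-of-bounds values on
#' read raise a validation error listing the violations.
#'
#' @param params A `system_parameters`, a `drug_parameters`, or a list with
#'   elements `system` and/or `drug`.
#' @param path JSON path.
#' @export
write_parameters <- function(params, path) {
  if (inherits(params, "system_parameters")) params <- list(system = params)
  if (inherits(params, "drug_parameters")) params <- list(drug = params)
  kv <- list()
  if (!is.null(params$system)) {
    s <- params$system
    kv <- c(kv,
            as.list(stats::setNames(s$kappa, paste0("kappa_", names(s$kappa)))),
            as.list(stats::setNames(s$rho, paste0("rho_", names(s$rho)))),
            as.list(stats::setNames(s$beta, paste0("beta_", names(s$beta)))),
            list(delta = s$delta, k_quiescence = s$k_quiescence))
  }
  if (!is.null(params$drug)) {
    d <- params$drug
    kv <- c(kv,
            as.list(stats::setNames(d$emax_total,
                                    paste0("emaxT_", names(d$emax_total)))),
            as.list(stats::setNames(d$log_ec50,
                                    paste0("logEC50_", names(d$log_ec50)))),
            as.list(stats::setNames(exp(d$log_ec50),
                                    paste0("EC50_", names(d$log_ec50)))),
            list(emax_upper_bound = d$emax_upper_bound))
  }
  jsonlite::write_json(kv, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters
#' @param emax_upper_bound Override of the total-Emax upper bound used when
#'   validating drug parameters on read (default: value stored in the file,
#'   else 3).
#' @return `read_parameters()` returns a list with whichever of `system`
#'   (a `system_parameters`) and `drug` (a `drug_parameters`) the file holds.
#' @export
read_parameters <- function(path, emax_upper_bound = NULL) {
  kv <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  grab <- function(prefix, keys) {
    nm <- paste0(prefix, "_", keys)
    found <- nm[nm %in% names(kv)]
    if (!length(found)) return(NULL)
    missing <- setdiff(nm, names(kv))
    if (length(missing))
      stop("parameter file missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    stats::setNames(unlist(kv[nm]), keys)
  }
  kappa <- grab("kappa", cell_type_ids())
  if (!is.null(kappa)) {
    out$system <- system_parameters(
      kappa = kappa,
      rho = grab("rho", renewing_type_ids()),
      beta = grab("beta", branch_edge_ids()),
      delta = kv$delta,
      k_quiescence = if (is.null(kv$k_quiescence)) 0.5 else kv$k_quiescence
    )
  }
  emax <- grab("emaxT", cell_type_ids())
  if (!is.null(emax)) {
    ub <- emax_upper_bound
    if (is.null(ub)) ub <- if (is.null(kv$emax_upper_bound)) 3 else kv$emax_upper_bound
    out$drug <- drug_parameters(
      emax_total = emax,
      log_ec50 = grab("logEC50", cell_type_ids()),
      emax_upper_bound = ub
    )
  }
  if (!length(out))
    stop("no recognizable parameters in ", path, call. = FALSE)
  out
}
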