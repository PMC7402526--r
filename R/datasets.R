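#' Kinetic dataset of drug-free cell counts
#'
#' Wraps per-donor long-format counts (cells/mL per readout per day) together
#' with the across-donor mean table the calibration consumes and the measured
#' day-0 counts used to bound fitted initial conditions.
#'
#' @param donors data.frame with columns `donor_id`, `day`, `readout`,
#'   `cells_per_ml`; readouts from [readout_names()].
#' @return An object of class `kinetic_dataset` with elements `donors`,
#'   `mean_table` (days x 14 matrix), `days`, `day0_counts`.
#' @export
kinetic_dataset <- function(donors) {
  required <- c("donor_id", "day", "readout", "cells_per_ml")
  missing <- setdiff(required, names(donors))
  if (length(missing))
    stop("kinetic data missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(donors$readout), readout_names())
  if (length(bad))
    stop("unknown readout(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(donors$cells_per_ml < 0))
    stop("cell counts must be non-negative", call. = FALSE)
  days <- sort(unique(donors$day))
  agg <- stats::aggregate(cells_per_ml ~ day + readout, donors, mean)
  mean_table <- matrix(NA_real_, length(days), length(readout_names()),
                       dimnames = list(days, readout_names()))
  mean_table[cbind(match(agg$day, days), match(agg$readout, readout_names()))] <-
    agg$cells_per_ml
  day0 <- if (0 %in% days) mean_table[as.character(0), ] else NULL
  structure(list(donors = donors, mean_table = mean_table, days = days,
                 day0_counts = day0),
            class = "kinetic_dataset")
}

#' Dose-response dataset (vehicle-normalized, pooled across donors)
#'
#' @param compound Compound identifier.
#' @param doses Dose panel (nM).
#' @param table `length(doses) x 14` matrix of normalized readouts over
#'   [readout_names()].
#' @param provenance Optional free-form metadata (donor count, normalization).
#' @return An object of class `dose_response_dataset`.
#' @export
dose_response_dataset <- function(compound, doses, table, provenance = list()) {
  if (!is.matrix(table) || nrow(table) != length(doses))
    stop("table must be a doses x readouts matrix", call. = FALSE)
  bad <- setdiff(colnames(table), readout_names())
  if (length(bad))
    stop("unknown readout(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(table < 0)) stop("normalized values must be non-negative", call. = FALSE)
  table <- table[, readout_names(), drop = FALSE]
  structure(list(compound = compound, doses = doses, table = table,
                 provenance = provenance),
            class = "dose_response_dataset")
}

#' Multiplicative lognormal noise model for synthetic assay data
#'
#' @param donor_count Number of virtual donors (the kinetic experiment used
#'   6; dose-response runs used 2-7 per compound).
#' @param cv Coefficient of variation of the multiplicative lognormal noise
#'   applied per readout/day/donor (default 0.2, a surrogate; the assay
#'   reports SEM bars but no noise law).
#' @param seed Seed for reproducibility.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(donor_count = 6L, cv = 0.2, seed = 1L) {
  stopifnot(donor_count >= 1, cv >= 0)
  structure(list(donor_count = as.integer(donor_count), cv = cv,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# lognormal multiplicative factors with mean 1 and the requested CV
rlnorm_unit <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic drug-free kinetic dataset
#'
#' Simulates the control trajectory at the assay's measurement days and
#' perturbs each donor's readouts with multiplicative lognormal noise
#' (mean 1, coefficient of variation `noise$cv`).
#'
#' @param sys A `system_parameters` object.
#' @param initial State vector from [model_state()].
#' @param noise A [noise_model()].
#' @param days Measurement days (default 0, 2, 3, 4, 5, 6).
#' @return A [kinetic_dataset()].
#' @export
generate_kinetic_dataset <- function(sys = default_system_parameters(),
                                     initial = default_initial_state(),
                                     noise = noise_model(),
                                     days = c(0, 2, 3, 4, 5, 6)) {
  tr <- simulate_control_kinetics(sys, initial, days = days)
  truth <- as.matrix(tr[, readout_names()])
  with_seed(noise$seed, {
    donors <- do.call(rbind, lapply(seq_len(noise$donor_count), function(dn) {
      fac <- matrix(rlnorm_unit(length(truth), noise$cv), nrow(truth))
      vals <- truth * fac
      data.frame(donor_id = sprintf("donor%02d", dn),
                 day = rep(days, times = ncol(truth)),
                 readout = rep(readout_names(), each = length(days)),
                 cells_per_ml = as.vector(vals))
    }))
    kinetic_dataset(donors)
  })
}

#' Generate a synthetic vehicle-normalized dose-response dataset
#'
#' Simulates treated and vehicle wells at the readout day, applies
#' multiplicative lognormal noise per well, normalizes each donor's treated
#' readouts to the mean of that donor's six virtual vehicle wells, and pools
#' donors by averaging — mirroring the assay's normalization.
#'
#' @param sys A `system_parameters` object.
#' @param drug A `drug_parameters` object.
#' @param doses Dose panel (nM), default [dose_grid()].
#' @param noise A [noise_model()]; dose-response runs pooled 2-7 donors.
#' @param initial State vector from [model_state()].
#' @param compound Label stored in the dataset.
#' @param n_vehicle_wells Virtual vehicle wells per donor (default 6).
#' @param readout_day Measurement day (default 6).
#' @return A [dose_response_dataset()].
#' @export
generate_dose_response_dataset <- function(sys = default_system_parameters(),
                                           drug,
                                           doses = dose_grid(),
                                           noise = noise_model(donor_count = 4L),
                                           initial = default_initial_state(),
                                           compound = "synthetic",
                                           n_vehicle_wells = 6L,
                                           readout_day = 6) {
  day6 <- function(conc) {
    tr <- integrate_model(sys, drug = drug, conc = conc, initial = initial,
                          times = c(0, readout_day))
    unlist(tr[nrow(tr), readout_names()])
  }
  treated <- t(vapply(doses, day6, numeric(length(readout_names()))))
  vehicle <- day6(0)
  with_seed(noise$seed, {
    per_donor <- lapply(seq_len(noise$donor_count), function(dn) {
      veh_wells <- vapply(seq_len(n_vehicle_wells), function(w)
        vehicle * rlnorm_unit(length(vehicle), noise$cv),
        numeric(length(vehicle)))
      veh_mean <- rowMeans(veh_wells)
      fac <- matrix(rlnorm_unit(length(treated), noise$cv), nrow(treated))
      tab <- sweep(treated * fac, 2, veh_mean, "/")
      tab[, vehicle == 0] <- 1  # empty compartments: 0/0 reported as no change
      tab
    })
    pooled <- Reduce(`+`, per_donor) / length(per_donor)
    colnames(pooled) <- readout_names()
    dose_response_dataset(compound, doses, pooled,
                          provenance = list(donors = noise$donor_count,
                                            cv = noise$cv, seed = noise$seed,
                                            vehicle_wells = n_vehicle_wells))
  })
}
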