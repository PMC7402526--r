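#' Optimizer settings for drug-effect estimation
#'
#' @param lambda L1 regularization weight on the total-Emax parameters
#'   (default 0.1), driving near-zero effects to exactly zero so each
#'   compound is explained by a parsimonious mechanism set.
#' @param weights Named per-readout weights in the objective; default 1
#'   everywhere with `totalDeadCells = 2`, which is needed to resolve
#'   cell-killing from anti-proliferation.
#' @param max_generations,population_size Population-search budget (the
#'   reference procedure used 30 and 300).
#' @param emax_upper_bound Upper bound on total Emax. The printed bound is
#'   2, but reference fits report values up to 2.762; default 3 keeps those
#'   feasible (the discrepancy is deliberate and configurable).
#' @param seed Seed controlling the fit.
#' @param local_search,n_polish,n_hops Elite local refinement and
#'   basin-hopping controls (see [fit_settings()]).
#' @param polish_heuristics Also refine the injected heuristic candidates
#'   (all-zero, depth-based, and killing-variant mechanisms) regardless of
#'   their rank after the population search. Costs a few extra local
#'   searches but protects against the anti-proliferation local optimum
#'   masking a cell-killing mechanism.
#' @return An object of class `drug_fit_settings`.
#' @export
drug_fit_settings <- function(lambda = 0.1,
                              weights = NULL,
                              max_generations = 30L,
                              population_size = 300L,
                              emax_upper_bound = 3,
                              seed = 1L,
                              local_search = TRUE,
                              n_polish = 3L, n_hops = 4L,
                              polish_heuristics = TRUE) {
  stopifnot(lambda >= 0, max_generations >= 1, population_size >= 4)
  w <- stats::setNames(rep(1, length(readout_names())), readout_names())
  w["totalDeadCells"] <- 2
  if (!is.null(weights)) w[names(weights)] <- weights
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  structure(list(lambda = lambda, weights = w,
                 max_generations = as.integer(max_generations),
                 population_size = as.integer(population_size),
                 emax_upper_bound = emax_upper_bound,
                 seed = as.integer(seed), local_search = local_search,
                 n_polish = as.integer(n_polish),
                 n_hops = as.integer(n_hops),
                 polish_heuristics = isTRUE(polish_heuristics)),
            class = "drug_fit_settings")
}

drug_residuals <- function(drug, sys, data, settings, initial) {
  sim <- simulate_dose_response(sys, drug, doses = data$doses,
                                initial = initial,
                                readout_day = data$provenance$readout_day %||% 6)
  res <- sweep(sim$normalized - data$table, 2,
               settings$weights[colnames(data$table)], "*")
  as.vector(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted, L1-regularized dose-response objective
#'
#' `sum_C || w_C (M_C^model - M_C^data) ||^2 + lambda * sum_C |Emax_T,C|`,
#' where the model table comes from [simulate_dose_response()] on the
#' dataset's dose grid. The weight sits inside the norm, so a unit residual
#' on the dead-cell readout contributes `(2 * 1)^2 = 4` at `lambda = 0`.
#'
#' @param drug A `drug_parameters` candidate.
#' @param sys Calibrated `system_parameters`.
#' @param data A [dose_response_dataset()].
#' @param settings A [drug_fit_settings()].
#' @param initial Day-0 state shared by treated and vehicle runs.
#' @return Non-negative scalar.
#' @export
drug_objective <- function(drug, sys, data,
                           settings = drug_fit_settings(),
                           initial = default_initial_state()) {
  sum(drug_residuals(drug, sys, data, settings, initial)^2) +
    settings$lambda * sum(abs(drug$emax_total))
}

drug_vec_names <- function() {
  c(paste0("emaxT_", cell_type_ids()), paste0("logEC50_", cell_type_ids()))
}

decode_drug_vec <- function(p, emax_upper_bound) {
  drug_parameters(
    emax_total = stats::setNames(p[1:13], cell_type_ids()),
    log_ec50 = stats::setNames(p[14:26], cell_type_ids()),
    emax_upper_bound = emax_upper_bound
  )
}

# crude per-readout starting guesses: depth of suppression at the top dose
# and the dose nearest half-maximal suppression. Two candidates are offered:
# the depth itself (anti-proliferation reading) and, when the dead-cell
# readout rises above baseline, a killing reading that pushes deeply
# suppressed types past the Emax_T = 1 threshold.
heuristic_drug_starts <- function(data, emax_upper_bound) {
  mid_log <- (-2.3 + 8.5) / 2
  emax <- numeric(13); lec <- rep(mid_log, 13)
  for (i in seq_along(cell_type_ids())) {
    v <- data$table[, cell_type_ids()[i]]
    depth <- 1 - min(v)
    emax[i] <- min(max(depth, 0), emax_upper_bound)
    if (depth > 0.05) {
      half <- 1 - depth / 2
      lec[i] <- min(max(log(data$doses[which.min(abs(v - half))]), -2.3), 8.5)
    }
  }
  starts <- list(c(emax, lec))
  dead_rise <- max(data$table[, "totalDeadCells"]) - 1
  if (dead_rise > 0.02) {
    killer <- emax
    deep <- emax > 0.5
    killer[deep] <- pmin(emax[deep] + 1, emax_upper_bound)
    starts <- c(starts, list(c(killer, lec)))
  }
  # single-type killing variants: a readout buffered by upstream influx can
  # hide a super-threshold Emax_T behind a modest depth, so offer, per
  # affected type, a candidate pushed past the killing threshold
  for (i in which(emax > 0.15)) {
    v <- emax
    v[i] <- min(1 + emax[i], emax_upper_bound)
    starts <- c(starts, list(c(v, lec)))
  }
  starts
}

#' Estimate the 26 drug-effect parameters from normalized dose-response data
#'
#' Minimizes [drug_objective()] over 13 total-Emax and 13 logEC50 values with
#' the hybrid global/local optimizer. The all-zero mechanism and a crude
#' per-readout heuristic are injected into the initial population, so the
#' fitted objective can never exceed the inert-drug objective. Deterministic
#' for a fixed seed; EC50 is reported alongside its log.
#'
#' @param data A [dose_response_dataset()].
#' @param sys Calibrated `system_parameters`.
#' @param settings A [drug_fit_settings()].
#' @param initial Day-0 state shared by treated and vehicle runs.
#' @return An object of class `fit_result` with elements `drug`
#'   (`drug_parameters`), `ec50` (nM), `objective`, `trace`, `n_eval`,
#'   `seed`, `bounds`, `settings`.
#' @export
fit_drug <- function(data, sys, settings = drug_fit_settings(),
                     initial = default_initial_state()) {
  stopifnot(inherits(data, "dose_response_dataset"))
  validate_system_parameters(sys)
  ub <- settings$emax_upper_bound
  lower <- c(rep(0, 13), rep(-2.3, 13))
  upper <- c(rep(ub, 13), rep(8.5, 13))
  names(lower) <- names(upper) <- drug_vec_names()
  mid_log <- (-2.3 + 8.5) / 2
  resid <- function(p) {
    drug <- decode_drug_vec(p, ub)
    c(drug_residuals(drug, sys, data, settings, initial),
      sqrt(settings$lambda * drug$emax_total))
  }
  objective <- function(p) sum(resid(p)^2)
  zero <- c(rep(0, 13), rep(mid_log, 13))
  heur <- heuristic_drug_starts(data, ub)
  cands <- c(list(zero), heur)
  # refine the base guesses plus the most promising killing variants
  polish_set <- list()
  if (settings$polish_heuristics) {
    raw <- vapply(heur, function(p) sum(resid(p)^2), numeric(1))
    polish_set <- c(list(zero), heur[order(raw)][seq_len(min(3, length(heur)))])
  }
  opt <- hybrid_optimize(objective, lower, upper,
                         seed = settings$seed,
                         max_generations = settings$max_generations,
                         population_size = settings$population_size,
                         init_candidates = cands,
                         polish_candidates = polish_set,
                         residual_fn = resid,
                         local_search = settings$local_search,
                         n_polish = settings$n_polish,
                         n_hops = settings$n_hops)
  drug <- decode_drug_vec(opt$par, ub)
  structure(list(drug = drug, ec50 = ec50(drug),
                 objective = opt$value, trace = opt$trace,
                 n_eval = opt$n_eval, seed = opt$seed,
                 bounds = list(lower = lower, upper = upper),
                 settings = settings),
            class = "fit_result")
}

#' Total-Emax expression matrix across the dose panel
#'
#' The realized effect magnitude `Emax_T * conc / (conc + EC50)` per dose
#' and cell type: the per-cell-type view of a compound's mechanism at
#' increasing concentrations.
#'
#' @param drug A `drug_parameters` object.
#' @param doses Dose panel (nM), default [dose_grid()].
#' @return `length(doses) x 13` matrix (rows named by dose, columns by cell
#'   type); entries in `[0, Emax_T]`, non-decreasing in dose.
#' @export
emax_expression_matrix <- function(drug, doses = dose_grid()) {
  validate_drug_parameters(drug)
  ec <- ec50(drug)
  vals <- vapply(cell_type_ids(),
                 function(id) drug$emax_total[[id]] *
                   hill_occupancy(doses, ec[[id]]),
                 numeric(length(doses)))
  matrix(vals, nrow = length(doses),
         dimnames = list(as.character(doses), cell_type_ids()))
}
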