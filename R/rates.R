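#' Fractional receptor-style occupancy of a simple Hill curve (slope 1)
#'
#' @param conc Drug concentration (nM), `>= 0`. Vectorized.
#' @param ec50 Half-maximal concentration (nM), `> 0`.
#' @return `conc / (ec50 + conc)`, in `[0, 1)`.
#' @export
#' @examples
#' hill_occupancy(25, 25)   # 0.5
hill_occupancy <- function(conc, ec50) {
  if (any(conc < 0)) stop("conc must be non-negative", call. = FALSE)
  if (any(ec50 <= 0)) stop("ec50 must be positive", call. = FALSE)
  conc / (ec50 + conc)
}

#' Split a total Emax into anti-proliferation and cell-killing components
#'
#' Under the assumption that a drug first blocks proliferation and only
#' kills once proliferation is fully blocked, a single total effect
#' `Emax_T` decomposes as `Emax_AP = min(1, Emax_T)` and
#' `Emax_CK = max(0, Emax_T - 1)`.
#'
#' @param emax_total Total Emax (unitless), `>= 0`. Vectorized.
#' @return List with components `ap` (anti-proliferation fraction, `[0, 1]`)
#'   and `ck` (cell-killing coefficient, 1/day scale).
#' @export
#' @examples
#' decompose_emax(2.014)  # ap = 1, ck = 1.014
decompose_emax <- function(emax_total) {
  if (any(emax_total < 0)) stop("emax_total must be non-negative", call. = FALSE)
  ap <- pmin(1, emax_total)
  ck <- pmax(0, emax_total - 1)
  names(ap) <- names(ck) <- names(emax_total)
  list(ap = ap, ck = ck)
}

#' Drug-attenuated division rate
#'
#' The anti-proliferation effect scales the basal proliferation rate:
#' `kappa = kappa0 * (1 - min(1, Emax_T) * conc / (ec50 + conc))`.
#'
#' @param kappa0 Basal proliferation rate (1/day), `>= 0`.
#' @param emax_total Total Emax, `>= 0`.
#' @param conc Drug concentration (nM).
#' @param ec50 EC50 (nM).
#' @return Effective rate in `[0, kappa0]` (1/day).
#' @export
effective_division_rate <- function(kappa0, emax_total, conc, ec50) {
  if (any(kappa0 < 0)) stop("kappa0 must be non-negative", call. = FALSE)
  ap <- decompose_emax(emax_total)$ap
  kappa0 * (1 - ap * hill_occupancy(conc, ec50))
}

#' Drug cell-killing flux out of a compartment
#'
#' `max(0, Emax_T - 1) * conc / (ec50 + conc) * count`; identically zero for
#' purely anti-proliferative effects (`Emax_T <= 1`).
#'
#' @param emax_total Total Emax, `>= 0`.
#' @param conc Drug concentration (nM).
#' @param ec50 EC50 (nM).
#' @param count Compartment concentration (cells/mL), `>= 0`.
#' @return Killing flux (cells/mL/day).
#' @export
killing_flux <- function(emax_total, conc, ec50, count) {
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  ck <- decompose_emax(emax_total)$ck
  ck * hill_occupancy(conc, ec50) * count
}

# internal state layout: 13 live types, quiescent neutrophils, total dead
state_names <- function() c(cell_type_ids(), "NeutQ", "totalDeadCells")

#' Construct a model state vector
#'
#' @param counts Named numeric over [cell_type_ids()] (cells/mL).
#' @param quiescent_neutrophils Quiescent-pool concentration (cells/mL);
#'   internal sub-state, reported within the `Neut` readout.
#' @param total_dead Accumulated dead cells (cells/mL).
#' @return Named numeric of length 15 in canonical state order.
#' @export
model_state <- function(counts, quiescent_neutrophils = 0, total_dead = 0) {
  counts <- counts[cell_type_ids()]
  if (anyNA(counts)) stop("counts must name all 13 cell types", call. = FALSE)
  x <- c(counts, quiescent_neutrophils, total_dead)
  names(x) <- state_names()
  if (any(x < 0)) stop("state concentrations must be non-negative", call. = FALSE)
  x
}

#' Linear rate matrix of the model at a fixed drug concentration
#'
#' With the drug held constant during integration every flux is linear in the
#' state, so the whole system is `dx/dt = A x`. Division consumes one parent
#' and yields two daughters that independently renew (probability `rho`) or
#' differentiate, giving the self term `(2 rho - 1) kappa [C]` and
#' differentiation outflow `2 (1 - rho) kappa [C]` split by the branching
#' fractions. Lymphoid progenitors convert to B cells as a first-order,
#' division-free flux `kappa_LymP [LymP]`. Terminal types proliferate at net
#' rate `kappa [C]` and die at `delta [C]` into the dead pool. Active
#' neutrophils transfer to a quiescent pool that neither divides nor
#' differentiates but is drug-killed like active neutrophils. Killing fluxes
#' move cells from every compartment into the dead pool.
#'
#' @param sys A `system_parameters` object.
#' @param drug Optional `drug_parameters`; `NULL` means drug-free.
#' @param conc Drug concentration (nM), constant over the integration.
#' @return 15 x 15 matrix over [state_names()] (internal layout).
#' @keywords internal
rate_matrix <- function(sys, drug = NULL, conc = 0) {
  sn <- state_names()
  A <- matrix(0, length(sn), length(sn), dimnames = list(sn, sn))
  topo <- build_reference_topology()
  ct <- cell_types()
  ec <- if (!is.null(drug)) ec50(drug)

  kappa_eff <- sys$kappa
  kill_rate <- stats::setNames(numeric(13), cell_type_ids())
  if (!is.null(drug) && conc > 0) {
    kappa_eff <- effective_division_rate(sys$kappa, drug$emax_total, conc, ec)
    kill_rate <- decompose_emax(drug$emax_total)$ck * hill_occupancy(conc, ec)
    names(kappa_eff) <- names(kill_rate) <- cell_type_ids()
  }

  for (id in cell_type_ids()) {
    k <- kappa_eff[[id]]
    if (ct$has_renewal[ct$id == id]) {
      rho <- sys$rho[[id]]
      A[id, id] <- A[id, id] + (2 * rho - 1) * k
      out <- 2 * (1 - rho) * k
      kids <- topo$edges$child[topo$edges$parent == id]
      for (kid in kids) {
        edge <- paste(id, kid, sep = "_")
        frac <- if (edge %in% names(sys$beta)) sys$beta[[edge]] else 1
        A[kid, id] <- A[kid, id] + out * frac
      }
    } else if (id == "LymP") {
      # division-free conversion to B; anti-proliferation still attenuates it
      A["LymP", "LymP"] <- A["LymP", "LymP"] - k
      A["B", "LymP"] <- A["B", "LymP"] + k
    } else {
      # terminal: net proliferation and death into the dead pool
      A[id, id] <- A[id, id] + k - sys$delta
      A["totalDeadCells", id] <- A["totalDeadCells", id] + sys$delta
    }
    # drug killing removes live cells into the dead pool
    if (kill_rate[[id]] > 0) {
      A[id, id] <- A[id, id] - kill_rate[[id]]
      A["totalDeadCells", id] <- A["totalDeadCells", id] + kill_rate[[id]]
    }
  }
  # active neutrophils feed the quiescent pool; the pool is inert except for
  # drug killing at the neutrophil parameters
  A["Neut", "Neut"] <- A["Neut", "Neut"] - sys$k_quiescence
  A["NeutQ", "Neut"] <- A["NeutQ", "Neut"] + sys$k_quiescence
  if (kill_rate[["Neut"]] > 0) {
    A["NeutQ", "NeutQ"] <- A["NeutQ", "NeutQ"] - kill_rate[["Neut"]]
    A["totalDeadCells", "NeutQ"] <- A["totalDeadCells", "NeutQ"] + kill_rate[["Neut"]]
  }
  A
}

#' Time-derivative of the model state
#'
#' Evaluates the right-hand side of the differentiation/renewal/death system
#' at a state, including drug anti-proliferation and cell-killing effects.
#' The drug concentration has zero derivative (constant in vitro exposure).
#'
#' @param state Named state vector from [model_state()].
#' @param sys A `system_parameters` object.
#' @param drug Optional `drug_parameters` (`NULL` = drug-free).
#' @param conc Drug concentration (nM).
#' @return Named derivative vector (cells/mL/day) over the internal state.
#' @export
evaluate_rhs <- function(state, sys, drug = NULL, conc = 0) {
  validate_system_parameters(sys)
  if (!is.null(drug)) validate_drug_parameters(drug)
  if (anyNA(state[state_names()]))
    stop("state must name all internal species", call. = FALSE)
  if (any(state < 0))
    stop("state concentrations must be non-negative", call. = FALSE)
  A <- rate_matrix(sys, drug, conc)
  drop(A %*% state[state_names()])
}
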