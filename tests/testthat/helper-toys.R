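# Toy parameter builders used across tests: a full 13-type parameter object
# with every rate zeroed (valid under the bounds) and selective overrides.

toy_system <- function(kappa = NULL, rho = NULL, beta = NULL,
                       delta = 0, k_quiescence = 0) {
  k <- stats::setNames(rep(0, 13), cell_type_ids())
  r <- stats::setNames(rep(0, 7),
                       c("HSC", "MPP", "GMP", "GranP", "Gran", "MonoP", "ErythI"))
  r["HSC"] <- 0.5
  b <- c(MPP_GMP = 0.25, MPP_ErythI = 0.25, MPP_MK = 0.25, MPP_LymP = 0.25,
         GMP_GranP = 0.5, GMP_MonoP = 0.5)
  if (!is.null(kappa)) k[names(kappa)] <- kappa
  if (!is.null(rho)) r[names(rho)] <- rho
  if (!is.null(beta)) b[names(beta)] <- beta
  system_parameters(kappa = k, rho = r, beta = b, delta = delta,
                    k_quiescence = k_quiescence)
}

toy_state <- function(..., quiescent = 0, dead = 0) {
  counts <- stats::setNames(rep(0, 13), cell_type_ids())
  over <- c(...)
  if (length(over)) counts[names(over)] <- over
  model_state(counts, quiescent_neutrophils = quiescent, total_dead = dead)
}

# inert drug-effect object (no effect at any dose)
inert_drug <- function() {
  drug_parameters(
    emax_total = stats::setNames(rep(0, 13), cell_type_ids()),
    log_ec50 = stats::setNames(rep(3, 13), cell_type_ids())
  )
}

# single-target drug: total Emax on one cell type, everything else inert
sparse_drug <- function(type, emax, ec50_nM) {
  e <- stats::setNames(rep(0, 13), cell_type_ids())
  l <- stats::setNames(rep(3, 13), cell_type_ids())
  e[type] <- emax
  l[type] <- log(ec50_nM)
  drug_parameters(emax_total = e, log_ec50 = l)
}
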