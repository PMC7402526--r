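#' Synthetic reference system parameters
#'
#' The assay's fitted system parameters are not published in a reusable
#' table, so the package ships a synthetic reference parameter set chosen
#' once to produce realistic six-day multi-lineage expansion kinetics
#' (stem/progenitor compartments growing, committed compartments fed by
#' differentiation, terminal compartments turning over into the dead pool).
#' It is the default input of the synthetic-data generator and of worked
#' examples; it is a plausible stand-in, not a fit to assay data.
#'
#' @return A `system_parameters` object.
#' @export
default_system_parameters <- function() {
  system_parameters(
    kappa = c(HSC = 0.9, MPP = 1.2, GMP = 1.3, GranP = 1.5, Gran = 1.2,
              MonoP = 1.4, Mono = 0.5, Neut = 0.3, ErythI = 1.6,
              ErythII = 0.7, MK = 0.4, LymP = 0.8, B = 0.5),
    rho = c(HSC = 0.9, MPP = 0.45, GMP = 0.4, GranP = 0.3, Gran = 0.3,
            MonoP = 0.3, ErythI = 0.45),
    beta = c(MPP_GMP = 0.4, MPP_ErythI = 0.3, MPP_MK = 0.1, MPP_LymP = 0.2,
             GMP_GranP = 0.55, GMP_MonoP = 0.45),
    delta = 0.3,
    k_quiescence = 0.5
  )
}

#' Synthetic reference day-0 state
#'
#' Day-0 seeding of a thawed CD34+ culture: counts concentrated in the
#' stem/progenitor compartments with small committed populations, an empty
#' quiescent pool, and a dead-cell pool reflecting post-thaw mortality.
#' Synthetic stand-in chosen once; see [default_system_parameters()].
#'
#' @return A state vector from [model_state()] (cells/mL).
#' @export
default_initial_state <- function() {
  model_state(
    counts = c(HSC = 5000, MPP = 8000, GMP = 1000, GranP = 200, Gran = 50,
               MonoP = 200, Mono = 50, Neut = 20, ErythI = 300,
               ErythII = 50, MK = 100, LymP = 200, B = 20),
    quiescent_neutrophils = 0,
    total_dead = 2000
  )
}

#' Reference drug-effect parameters for eight characterized compounds
#'
#' Published per-cell-type EC50 (nM) and total-Emax values for docetaxel,
#' paclitaxel, the CDK inhibitors abemaciclib, dinaciclib, palbociclib and
#' ribociclib, the PI3K inhibitor pictilisib, and the negative control
#' thalidomide. These serve as fixture inputs for forward simulation,
#' expression matrices, and cohort analysis; EC50 values above the top
#' tested dose of 2500 nM are model extrapolations.
#'
#' @param compound Optional compound name; if given, returns that compound's
#'   [drug_parameters()] object instead of the full table.
#' @return A data.frame (`compound`, `cell_type`, `ec50_nM`, `emax_total`)
#'   or a single `drug_parameters` object.
#' @export
#' @examples
#' head(reference_drug_params())
#' reference_drug_params("docetaxel")$emax_total[["Gran"]]
reference_drug_params <- function(compound = NULL) {
  path <- system.file("extdata", "reference_drug_params.csv",
                      package = "hemaQSP", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(compound)) return(tab)
  sub <- tab[tab$compound == compound, ]
  if (nrow(sub) != 13L)
    stop("unknown compound: ", compound, call. = FALSE)
  drug_parameters(
    emax_total = stats::setNames(sub$emax_total, sub$cell_type),
    log_ec50 = stats::setNames(log(sub$ec50_nM), sub$cell_type)
  )
}

#' Names of the reference compounds
#' @export
reference_compounds <- function() unique(reference_drug_params()$compound)
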