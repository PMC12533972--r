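# Right-hand side of the nine coupled population ODEs and its flux
# decomposition.
#
# The model tracks one cubic millimeter of injured muscle over days
# post-injury. Injury enters only through the initial density of damaged
# myonuclei (Md); there is no ongoing damage process. Immune populations
# (N, Nd, M, M1, M2) clear the debris and hand off to the myogenic lineage
# (QSC, ASC, Mc); the coupling is strictly one-way, immune -> myogenic.

# Individual flux expressions, evaluated once and shared between equations.
# Names encode source/mechanism; all are non-negative for non-negative
# states and parameters.
flux_core <- function(y, p) {
  c(
    N_phago_Md   = p[["cNMd"]] * y[["N"]] * y[["Md"]],
    M1_clear_Md  = p[["cM1Md"]] * y[["M1"]] * y[["Md"]],
    N_influx     = p[["cNin"]] * y[["Md"]],
    N_efflux     = p[["cNout"]] * y[["N"]],
    M1_clear_Nd  = p[["cM1Nd"]] * y[["M1"]] * y[["Nd"]],
    M_influx     = p[["cMin"]] * y[["N"]],
    M_to_M1      = p[["cMM1"]] * y[["M"]] * (y[["Nd"]] + y[["Md"]]),
    M_efflux     = p[["cMout"]] * y[["M"]],
    M1_to_M2     = if (p[["cM1M2"]] * y[["M1"]] == 0) 0 else
                     p[["cM1M2"]] * y[["M1"]] /
                       (p[["cM1M2inhib"]] + y[["Nd"]] + y[["Md"]]),
    M2_efflux    = p[["cM2out"]] * y[["M2"]],
    QSC_act_N    = p[["cQSCN"]] * y[["QSC"]] * y[["N"]],
    QSC_act_Md   = p[["cQSCMd"]] * y[["QSC"]] * y[["Md"]],
    ASC_deact    = p[["cASCM2"]] * y[["ASC"]] * y[["M2"]],
    ASC_prolif   = p[["cASCpro"]] * y[["ASC"]] * y[["M1"]],
    ASC_diff     = p[["cASCdiff"]] * y[["ASC"]] * y[["M2"]],
    Mc_efflux    = p[["cMcout"]] * y[["Mc"]]
  )
}

# Signed incidence of fluxes in each equation; rhs = signs %*% fluxes.
flux_sign_matrix <- function() {
  f <- c("N_phago_Md", "M1_clear_Md", "N_influx", "N_efflux", "M1_clear_Nd",
         "M_influx", "M_to_M1", "M_efflux", "M1_to_M2", "M2_efflux",
         "QSC_act_N", "QSC_act_Md", "ASC_deact", "ASC_prolif", "ASC_diff",
         "Mc_efflux")
  s <- matrix(0, nrow = length(state_names), ncol = length(f),
              dimnames = list(state_names, f))
  s["Md", c("N_phago_Md", "M1_clear_Md")] <- -1
  s["N", "N_influx"] <- 1
  s["N", c("N_efflux", "N_phago_Md")] <- -1
  s["Nd", "N_phago_Md"] <- 1
  s["Nd", "M1_clear_Nd"] <- -1
  s["M", "M_influx"] <- 1
  s["M", c("M_to_M1", "M_efflux")] <- -1
  s["M1", "M_to_M1"] <- 1
  s["M1", "M1_to_M2"] <- -1
  s["M2", "M1_to_M2"] <- 1
  s["M2", "M2_efflux"] <- -1
  s["QSC", c("QSC_act_N", "QSC_act_Md")] <- -1
  s["QSC", "ASC_deact"] <- 1
  s["ASC", c("QSC_act_N", "QSC_act_Md", "ASC_prolif")] <- 1
  s["ASC", c("ASC_deact", "ASC_diff")] <- -1
  s["Mc", "ASC_diff"] <- 1
  s["Mc", "Mc_efflux"] <- -1
  s
}

# Fast unvalidated right-hand side used inside the integrator. Written out
# term by term (not via the sign matrix) to keep per-call cost low.
rhs_core <- function(y, p) {
  dead <- y[["Nd"]] + y[["Md"]]
  phago <- p[["cNMd"]] * y[["N"]] * y[["Md"]]
  pol <- p[["cMM1"]] * y[["M"]] * dead
  # the conversion term is exactly 0 when its numerator is 0, even if the
  # saturation denominator is degenerate (cM1M2inhib = Nd = Md = 0)
  num <- p[["cM1M2"]] * y[["M1"]]
  trans <- if (num == 0) 0 else num / (p[["cM1M2inhib"]] + dead)
  act <- p[["cQSCN"]] * y[["QSC"]] * y[["N"]] +
    p[["cQSCMd"]] * y[["QSC"]] * y[["Md"]]
  deact <- p[["cASCM2"]] * y[["ASC"]] * y[["M2"]]
  diff_ <- p[["cASCdiff"]] * y[["ASC"]] * y[["M2"]]
  c(
    Md = -phago - p[["cM1Md"]] * y[["M1"]] * y[["Md"]],
    N = p[["cNin"]] * y[["Md"]] - p[["cNout"]] * y[["N"]] - phago,
    Nd = phago - p[["cM1Nd"]] * y[["M1"]] * y[["Nd"]],
    M = p[["cMin"]] * y[["N"]] - pol - p[["cMout"]] * y[["M"]],
    M1 = pol - trans,
    M2 = trans - p[["cM2out"]] * y[["M2"]],
    QSC = -act + deact,
    ASC = act - deact + p[["cASCpro"]] * y[["ASC"]] * y[["M1"]] - diff_,
    Mc = diff_ - p[["cMcout"]] * y[["Mc"]]
  )
}

#' Population rate equations
#'
#' Evaluate the time derivative of each of the nine populations at a given
#' state. The equations are, with all densities in cells/mm^3 and time in
#' days:
#'
#' * `dMd/dt = -cNMd N Md - cM1Md M1 Md` (debris cleared by neutrophils and
#'   M1 macrophages)
#' * `dN/dt = cNin Md - cNout N - cNMd N Md` (damage-driven influx, exit,
#'   and phagocytosis-induced death)
#' * `dNd/dt = cNMd N Md - cM1Nd M1 Nd`
#' * `dM/dt = cMin N - cMM1 M (Nd + Md) - cMout M`
#' * `dM1/dt = cMM1 M (Nd + Md) - cM1M2 M1 / (cM1M2inhib + Nd + Md)`
#'   (M1-to-M2 conversion is inhibited while debris remains)
#' * `dM2/dt = cM1M2 M1 / (cM1M2inhib + Nd + Md) - cM2out M2`
#' * `dQSC/dt = -cQSCN QSC N - cQSCMd QSC Md + cASCM2 ASC M2`
#' * `dASC/dt = cQSCN QSC N + cQSCMd QSC Md - cASCM2 ASC M2
#'   + cASCpro ASC M1 - cASCdiff ASC M2`
#' * `dMc/dt = cASCdiff ASC M2 - cMcout Mc`
#'
#' @param state A [cell_state()] (or coercible named vector).
#' @param params A [rate_parameters()] (or coercible named vector).
#' @return Named numeric vector of nine derivatives (cells/mm^3 per day).
#' @examples
#' regen_rhs(default_initial_state(), fitted_rate_parameters())
#' @export
regen_rhs <- function(state, params) {
  state <- as_cell_state(state)
  params <- as_rate_parameters(params)
  rhs_core(unclass(state), unclass(params))
}

#' Individual flux terms of the rate equations
#'
#' Decompose the right-hand side into its individual mass-flux expressions,
#' one entry per distinct term (shared terms such as the neutrophil
#' phagocytosis flux `cNMd N Md` are reported once). The signed sum of
#' fluxes per equation reproduces [regen_rhs()].
#'
#' @inheritParams regen_rhs
#' @return A tibble with columns `flux` (term name) and `value`
#'   (cells/mm^3 per day, all non-negative).
#' @export
flux_terms <- function(state, params) {
  state <- as_cell_state(state)
  params <- as_rate_parameters(params)
  f <- flux_core(unclass(state), unclass(params))
  tibble::tibble(flux = names(f), value = as.numeric(f))
}
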