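#' Model state and initial conditions
#'
#' The model tracks seven dynamic variables (all uM): cdG, the lumped GTP
#' pool (GTP + GDP), the lumped alarmone pool ((p)ppGpp = ppGpp + pppGpp),
#' GMP, and the three phosphorylated PTS-Ntr pools. `EIP_tot` is total
#' phosphorylated EI-Ntr, i.e. free EI~P plus the EI~P.pyruvate complex;
#' complexes of the fast PEP/Pyr binding reactions are resolved
#' algebraically at every right-hand-side evaluation, not carried as state.
#'
#' `default_state()` returns the standard initial condition: cdG 0.3, GTP
#' 1300, (p)ppGpp 100, GMP 20, and the PTS pools fully phosphorylated
#' (EI~P 10, NPr~P 30, EIIA~P 30). The initial cdG slightly exceeds the
#' oscillation maximum (0.28 uM); it is a transient starting point, relaxed
#' within the first cycle.
#'
#' @param cdG,GTP,ppGpp,GMP,EIP_tot,NPrP,EIIAP Concentrations (uM).
#' @return A named numeric vector of length 7.
#' @export
model_state <- function(cdG, GTP, ppGpp, GMP, EIP_tot, NPrP, EIIAP) {
  c(cdG = cdG, GTP = GTP, ppGpp = ppGpp, GMP = GMP,
    EIP_tot = EIP_tot, NPrP = NPrP, EIIAP = EIIAP)
}

#' @rdname model_state
#' @export
default_state <- function() {
  model_state(cdG = 0.3, GTP = 1300, ppGpp = 100, GMP = 20,
              EIP_tot = 10, NPrP = 30, EIIAP = 30)
}

state_names <- function() {
  c("cdG", "GTP", "ppGpp", "GMP", "EIP_tot", "NPrP", "EIIAP")
}

#' Validate a model state
#'
#' Checks non-negativity (tolerating excursions above -1e-8 uM, which are
#' attributed to solver round-off and clipped) and the PTS pool bounds
#' `EIP_tot <= EI_T`, `NPrP <= NPr_T`, `EIIAP <= EIIA_T` (with the same
#' tolerance), so that free concentrations computed as total minus
#' phosphorylated can never go negative.
#'
#' @param state Named numeric state vector.
#' @param params Parameter set (for the PTS totals).
#' @return The validated (possibly clipped) state vector.
#' @export
validate_state <- function(state, params = default_params()) {
  tol <- 1e-8
  state <- state[state_names()]
  if (any(is.na(state)))
    stop("state must contain the seven variables ",
         paste(state_names(), collapse = ", "))
  if (any(state < -tol))
    stop("negative concentration in state: ",
         paste(names(state)[state < -tol], collapse = ", "))
  caps <- c(EIP_tot = params$EI_T, NPrP = params$NPr_T, EIIAP = params$EIIA_T)
  over <- state[names(caps)] - caps
  if (any(over > tol))
    stop("phosphorylated PTS pool exceeds its total: ",
         paste(names(caps)[over > tol], collapse = ", "))
  state <- pmax(state, 0)
  state[names(caps)] <- pmin(state[names(caps)], caps)
  state
}

#' Glutamine inhibition factor of EI-Ntr autophosphorylation
#'
#' Glutamine binds the GAF domain of EI-Ntr and inhibits phosphoryl transfer
#' from PEP. The forward autophosphorylation rate is multiplied by
#' `(K4 + eps * Gln) / (K4 + Gln)`, which falls monotonically from 1 (no
#' glutamine) to the residual fraction `eps` at saturating glutamine.
#'
#' @param Gln Glutamine concentration (uM), non-negative.
#' @param params Parameter set.
#' @return A dimensionless factor in `[eps, 1]`.
#' @examples
#' glutamine_factor(0)       # 1: uninhibited
#' glutamine_factor(10000)   # close to eps = 0.1
#' @export
glutamine_factor <- function(Gln, params = default_params()) {
  if (any(!is.finite(Gln)) || any(Gln < 0))
    stop("Gln must be finite and non-negative")
  (params$K4 + params$eps * Gln) / (params$K4 + Gln)
}

#' Quasi-steady-state partition of the EI-Ntr pool
#'
#' PEP binding to unphosphorylated EI and pyruvate binding to EI~P are fast
#' relative to phosphotransfer, so the four EI forms are resolved
#' algebraically: the unphosphorylated pool `EI_T - EIP_tot` splits between
#' free EI and the EI.PEP complex according to `Kd1`, and the phosphorylated
#' pool `EIP_tot` splits between free EI~P and the EI~P.Pyr complex
#' according to `Kd2`.
#'
#' @param EIP_tot Total phosphorylated EI-Ntr (uM), in `[0, EI_T]`.
#' @param signal A [nutrient_signal()] (PEP and Pyr are used).
#' @param params Parameter set.
#' @return A named list with `EI_free`, `EI_PEP`, `EIP_free`, `EIP_Pyr`
#'   (uM); the four sum to `EI_T`.
#' @export
partition_EI <- function(EIP_tot, signal, params = default_params()) {
  signal <- as_signal(signal)
  if (EIP_tot < -1e-8 || EIP_tot > params$EI_T + 1e-8)
    stop("EIP_tot must lie in [0, EI_T]")
  EIP_tot <- min(max(EIP_tot, 0), params$EI_T)
  U <- params$EI_T - EIP_tot
  f_pep <- (signal$PEP / params$Kd1) / (1 + signal$PEP / params$Kd1)
  f_pyr <- (signal$Pyr / params$Kd2) / (1 + signal$Pyr / params$Kd2)
  EI_PEP <- U * f_pep
  EIP_Pyr <- EIP_tot * f_pyr
  list(EI_free = U - EI_PEP, EI_PEP = EI_PEP,
       EIP_free = EIP_tot - EIP_Pyr, EIP_Pyr = EIP_Pyr)
}

#' SpoT synthetase/hydrolase partition
#'
#' SpoT is bifunctional: NPr~P (indirectly) activates its (p)ppGpp
#' synthetase activity while EIIA~P inhibits its hydrolase activity. Both
#' effects are folded into the synthetase:hydrolase ratio
#' `alpha = K_SpoT * NPrP/(NPrP + K2) * (EIIAP + K3)/K3`, which partitions
#' total SpoT into a synthetase fraction `f_sd = alpha/(1+alpha)` and a
#' hydrolase fraction `f_hd = 1/(1+alpha)`.
#'
#' @param NPrP,EIIAP Phosphorylated NPr and EIIA-Ntr (uM), non-negative.
#' @param params Parameter set.
#' @return A named list with `alpha`, `f_sd`, `f_hd`; `f_sd + f_hd == 1`.
#' @examples
#' spot_split(NPrP = 1.58, EIIAP = 1.58)  # rich condition: f_sd ~ 0.087
#' @export
spot_split <- function(NPrP, EIIAP, params = default_params()) {
  if (any(!is.finite(c(NPrP, EIIAP))) || NPrP < 0 || EIIAP < 0)
    stop("NPrP and EIIAP must be finite and non-negative")
  alpha <- params$K_SpoT * (NPrP / (NPrP + params$K2)) *
    ((EIIAP + params$K3) / params$K3)
  list(alpha = alpha, f_sd = alpha / (1 + alpha), f_hd = 1 / (1 + alpha))
}

#' Right-hand side of the seven-variable model
#'
#' Computes the time derivatives (uM/min) of the model state at given
#' nutrient signals and total DGC / PDE abundances.
#'
#' Fluxes:
#' \itemize{
#'   \item cdG synthesis: `k_s_cdG * DGC * K1^2/(K1^2 + cdG^2) *
#'     GTP^2/(GTP^2 + Km1^2)` -- DGC activity is product-inhibited by cdG
#'     binding its I-site (cooperative, Hill exponent 2) and saturates in
#'     its substrate GTP; each catalytic event consumes 2 GTP.
#'   \item cdG degradation: `k_d_cdG * PDE * cdG/(cdG + Km2)`, yielding
#'     2 GMP per cdG (the pGpG intermediate is lumped out).
#'   \item (p)ppGpp synthesis / hydrolysis by the SpoT synthetase and
#'     hydrolase fractions, Michaelis-Menten in GTP and (p)ppGpp
#'     respectively; hydrolysis returns the pool to GTP.
#'   \item GTP/GMP interconversion: first order both ways
#'     (`k_s_GTP * GMP - k_d_GTP * GTP`).
#'   \item PTS phosphorelay: glutamine-gated EI autophosphorylation from the
#'     EI.PEP complex, back-transfer to pyruvate from the EI~P.Pyr complex,
#'     and the reversible EI~P <-> NPr and NPr~P <-> EIIA transfers with
#'     equal forward/back rate constants. Both EI and EI.PEP accept the
#'     phosphoryl group back from NPr~P.
#' }
#'
#' The stoichiometry conserves total guanine:
#' `2*d(cdG) + d(GTP) + d(GMP) + d(ppGpp)` is identically zero.
#'
#' @param state Named state vector (see [model_state()]).
#' @param signal A [nutrient_signal()].
#' @param dgc_level,pde_level Total DGC and PDE abundances (scaled uM).
#' @param params Parameter set.
#' @return Named numeric vector of the 7 derivatives (uM/min).
#' @export
model_rhs <- function(state, signal, dgc_level, pde_level,
                      params = default_params()) {
  signal <- as_signal(signal)
  if (dgc_level < 0 || pde_level < 0)
    stop("dgc_level and pde_level must be non-negative")
  state <- validate_state(state, params)
  p <- params

  cdG <- state[["cdG"]]; GTP <- state[["GTP"]]; ppGpp <- state[["ppGpp"]]
  GMP <- state[["GMP"]]; EIP_tot <- state[["EIP_tot"]]
  NPrP <- state[["NPrP"]]; EIIAP <- state[["EIIAP"]]

  # cdG fluxes (synthesis consumes 2 GTP; degradation releases 2 GMP)
  v_syn_cdG <- p$k_s_cdG * dgc_level * p$K1^2 / (p$K1^2 + cdG^2) *
    GTP^2 / (GTP^2 + p$Km1^2)
  v_deg_cdG <- p$k_d_cdG * pde_level * cdG / (cdG + p$Km2)

  # SpoT partition and (p)ppGpp fluxes
  split <- spot_split(NPrP, EIIAP, p)
  v_syn_pp <- p$k_s_ppGpp * split$f_sd * GTP / (GTP + p$Km3)
  v_deg_pp <- p$k_d_ppGpp * split$f_hd * ppGpp / (ppGpp + p$Km4)

  # GTP <-> GMP interconversion
  v_gmp_gtp <- p$k_s_GTP * GMP
  v_gtp_gmp <- p$k_d_GTP * GTP

  # PTS-Ntr relay with quasi-steady-state PEP/Pyr binding
  ei <- partition_EI(EIP_tot, signal, p)
  EI_u <- ei$EI_free + ei$EI_PEP         # total unphosphorylated EI
  NPr_free <- p$NPr_T - NPrP
  EIIA_free <- p$EIIA_T - EIIAP
  gf <- glutamine_factor(signal$Gln, p)

  d_EIP <- p$k1 * gf * ei$EI_PEP - p$k_1 * ei$EIP_Pyr -
    p$k2 * EIP_tot * NPr_free + p$k2 * NPrP * EI_u
  d_NPrP <- p$k2 * EIP_tot * NPr_free - p$k2 * NPrP * EI_u -
    (p$k3 * NPrP * EIIA_free - p$k3 * NPr_free * EIIAP)
  d_EIIAP <- p$k3 * NPrP * EIIA_free - p$k3 * NPr_free * EIIAP

  c(cdG = v_syn_cdG - v_deg_cdG,
    GTP = v_gmp_gtp - v_gtp_gmp - v_syn_pp + v_deg_pp - 2 * v_syn_cdG,
    ppGpp = v_syn_pp - v_deg_pp,
    GMP = 2 * v_deg_cdG + v_gtp_gmp - v_gmp_gtp,
    EIP_tot = d_EIP, NPrP = d_NPrP, EIIAP = d_EIIAP)
}

#' Total guanine content of a state
#'
#' The conserved moiety of the nucleotide sub-network: cdG carries two
#' guanine bases (it is made from 2 GTP and degraded to 2 GMP), so
#' `2*cdG + GTP + GMP + ppGpp` is invariant along any trajectory -- the
#' nutrient signals exchange phosphoryl groups, never guanine.
#'
#' @param state Named state vector.
#' @return Total guanine (uM).
#' @examples
#' total_guanine(default_state())  # 1420.6
#' @export
total_guanine <- function(state) {
  2 * state[["cdG"]] + state[["GTP"]] + state[["GMP"]] + state[["ppGpp"]]
}
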