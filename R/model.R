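# Core model operations: time-varying elastance, chamber and vascular
# pressures, Bernoulli valve flow and the closed-loop volume balance.
# These are the reference (pure-R) definitions; the C++ engine implements
# the same equations and is property-tested against circulation_rhs().

#' Normalized activation waveform
#'
#' Double-Hill activation used by all four chambers, evaluated at a cycle
#' phase. The waveform is 0 outside the chamber's activation window, rises
#' and falls smoothly inside it, and is normalized so its peak is exactly 1.
#'
#' @param t_cycle cycle phase; values outside `[0, 1)` are wrapped by modulo
#' @param chamber an [chamber_params()] object
#' @return activation in `[0, 1]`, vectorized over `t_cycle`
#' @export
activation_waveform <- function(t_cycle, chamber) {
  phase <- t_cycle %% 1
  x <- (phase - chamber$t_activation_onset) %% 1
  x <- x / chamber$t_activation_duration
  .hill_raw(x) / chamber$act_norm
}

#' Time-varying elastance
#'
#' `E(t) = E_min + a(t) * (E_es - E_min)` with the normalized double-Hill
#' activation `a(t)`: the chamber elastance runs from its diastolic minimum
#' to exactly `E_es` at peak activation, periodically and continuously.
#'
#' @inheritParams activation_waveform
#' @return elastance in mmHg/mL, vectorized over `t_cycle`
#' @export
elastance_waveform <- function(t_cycle, chamber) {
  a <- activation_waveform(t_cycle, chamber)
  chamber$E_min + a * (chamber$E_es - chamber$E_min)
}

#' Instantaneous chamber pressure
#'
#' Activation-weighted blend of the ESPVR line and the exponential EDPVR:
#' `P = a * E_es * (V - V0) + (1 - a) * P_ed(V)` with
#' `a = (e_t - E_min) / (E_es - E_min)` and
#' `P_ed(V) = edpvr_alpha * (exp(edpvr_beta * V) - 1)`. At full activation
#' the chamber sits on its ESPVR, at zero activation on its EDPVR.
#' Transiently negative pressures are permitted (they drive the suction
#' logic).
#'
#' @param V chamber volume (mL), vectorized
#' @param e_t instantaneous elastance from [elastance_waveform()]
#' @param chamber an [chamber_params()] object
#' @return pressure in mmHg
#' @export
chamber_pressure <- function(V, e_t, chamber) {
  if (any(V < 0)) stop("chamber volume must be >= 0")
  a <- (e_t - chamber$E_min) / (chamber$E_es - chamber$E_min)
  a * chamber$E_es * (V - chamber$V0) +
    (1 - a) * chamber$edpvr_alpha * expm1(chamber$edpvr_beta * V)
}

#' Unidirectional Bernoulli valve flow
#'
#' Flow through an orifice valve solves `dP = R_valve * Q + B * Q^2` with
#' `B = rho / (2 * (K_ORIFICE * A)^2)` (Q in mL/s, A in cm^2, dP in mmHg;
#' `K_ORIFICE^2` = 1333.22 converts dyn/cm^2 to mmHg). The valve is
#' unidirectional: flow is 0 whenever the upstream pressure does not exceed
#' the downstream pressure, and strictly increasing in the pressure gradient
#' otherwise.
#'
#' @param P_up,P_down upstream / downstream pressures (mmHg), vectorized
#' @param A orifice area (cm^2)
#' @param R_valve linear valve resistance (mmHg·s/mL), may be 0
#' @param rho blood density (g/mL)
#' @return flow in mL/s
#' @export
valve_flow <- function(P_up, P_down, A, R_valve, rho = 1.05) {
  stopifnot(A > 0, R_valve >= 0, rho > 0)
  dp <- P_up - P_down
  B <- rho / (2 * (K_ORIFICE * A)^2)
  disc <- pmax(R_valve^2 + 4 * B * dp, 0)
  q <- (-R_valve + sqrt(disc)) / (2 * B)
  q[dp <= 0] <- 0
  q
}

#' All ten compartment pressures at a state
#'
#' Chamber pressures come from [chamber_pressure()] at the instantaneous
#' elastance; vascular pressures are linear, `P_X = V_X / C_X`.
#'
#' @param state an [sim_state()]
#' @param params an [circuit_params()]
#' @param chambers named list (LA, LV, RA, RV) of [chamber_params()]
#' @param t time (s); the cycle phase is `t * HR / 60 mod 1`
#' @return named numeric: LAP, LVP, RAP, RVP, SAP, SCP, SVP, PAP, PCP, PVP
#' @export
compartment_pressures <- function(state, params, chambers, t = state$t) {
  v <- state$volumes
  phase <- (t * params$HR / 60) %% 1
  pch <- function(role, vol) {
    ch <- chambers[[role]]
    chamber_pressure(vol, elastance_waveform(phase, ch), ch)
  }
  c(LAP = pch("LA", v[["V_LA"]]), LVP = pch("LV", v[["V_LV"]]),
    RAP = pch("RA", v[["V_RA"]]), RVP = pch("RV", v[["V_RV"]]),
    SAP = v[["V_SA"]] / params$C_SA, SCP = v[["V_SC"]] / params$C_SC,
    SVP = v[["V_SV"]] / params$C_SV, PAP = v[["V_PA"]] / params$C_PA,
    PCP = v[["V_PC"]] / params$C_PC, PVP = v[["V_PV"]] / params$C_PV)
}

# outflow throttle for near-empty compartments (numerical guard)
.floor_factor <- function(V, v_floor) pmin(1, pmax(0, V / v_floor))

#' Closed-loop volume balance (right-hand side)
#'
#' Each compartment volume's derivative is inflow minus outflow along the
#' loop LV -> aortic valve (+ systemic characteristic impedance) -> SA -> SC
#' -> SV -> RA -> tricuspid valve -> RV -> pulmonary valve (+ pulmonary
#' characteristic impedance) -> PA -> PC -> PV -> LA -> mitral valve -> LV.
#' Device flows must already be resolved: VA-ECMO withdraws from SV and
#' returns to SA, the Impella withdraws from the LV and returns to SA.
#' The derivatives sum to zero exactly (pumps only redistribute volume).
#'
#' Outflows from a compartment whose volume is below `v_floor` are linearly
#' throttled, which is the engine's negative-volume guard.
#'
#' @inheritParams compartment_pressures
#' @param devices list with resolved flows in L/min: `q_impella`, `q_vaecmo`
#' @param v_floor throttle floor (mL)
#' @return named derivative vector (mL/s), same order as the state volumes
#' @export
circulation_rhs <- function(state, params, chambers,
                            devices = list(q_impella = 0, q_vaecmo = 0),
                            t = state$t, v_floor = 1.0) {
  v <- state$volumes
  P <- compartment_pressures(state, params, chambers, t)
  f <- function(nm) .floor_factor(v[[nm]], v_floor)

  q_mv <- f("V_LA") * valve_flow(P[["LAP"]], P[["LVP"]], params$A_MV,
                                 params$R_MV, params$rho)
  q_av <- f("V_LV") * valve_flow(P[["LVP"]], P[["SAP"]], params$A_AV,
                                 params$R_AV + params$R_SZ0, params$rho)
  q_tv <- f("V_RA") * valve_flow(P[["RAP"]], P[["RVP"]], params$A_TV,
                                 params$R_TV, params$rho)
  q_pav <- f("V_RV") * valve_flow(P[["RVP"]], P[["PAP"]], params$A_PAV,
                                  params$R_PAV + params$R_PZ0, params$rho)

  rflow <- function(p1, p2, R, n1, n2) {
    q <- (P[[p1]] - P[[p2]]) / R
    q * if (q > 0) f(n1) else f(n2)
  }
  q_sa_sc <- rflow("SAP", "SCP", params$R_SA, "V_SA", "V_SC")
  q_sc_sv <- rflow("SCP", "SVP", params$R_SC, "V_SC", "V_SV")
  q_sv_ra <- rflow("SVP", "RAP", params$R_SV, "V_SV", "V_RA")
  q_pa_pc <- rflow("PAP", "PCP", params$R_PA, "V_PA", "V_PC")
  q_pc_pv <- rflow("PCP", "PVP", params$R_PC, "V_PC", "V_PV")
  q_pv_la <- rflow("PVP", "LAP", params$R_PV, "V_PV", "V_LA")

  q_imp <- f("V_LV") * devices$q_impella * 1000 / 60
  q_ec <- f("V_SV") * devices$q_vaecmo * 1000 / 60

  d <- c(V_LA = q_pv_la - q_mv,
         V_LV = q_mv - q_av - q_imp,
         V_RA = q_sv_ra - q_tv,
         V_RV = q_tv - q_pav,
         V_SA = q_av + q_imp + q_ec - q_sa_sc,
         V_SC = q_sa_sc - q_sc_sv,
         V_SV = q_sc_sv - q_sv_ra - q_ec,
         V_PA = q_pav - q_pa_pc,
         V_PC = q_pa_pc - q_pc_pv,
         V_PV = q_pc_pv - q_pv_la)
  attr(d, "flows") <- c(q_mv = q_mv, q_av = q_av, q_tv = q_tv, q_pav = q_pav,
                        q_sa_sc = q_sa_sc, q_sc_sv = q_sc_sv,
                        q_sv_ra = q_sv_ra, q_pa_pc = q_pa_pc,
                        q_pc_pv = q_pc_pv, q_pv_la = q_pv_la,
                        q_impella = q_imp, q_vaecmo = q_ec)
  d
}
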