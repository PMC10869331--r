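# Parameter containers: circuit constants, chamber elastance parameters and
# the shipped scenario presets.

#' Circuit parameters of the closed-loop circulation
#'
#' Collects every resistance, compliance, valve orifice area and global
#' constant of the 5-element systemic and pulmonary
#' resistance-capacitance networks. Resistances are in mmHg·s/mL,
#' compliances in mL/mmHg, orifice areas in cm^2, heart rate in beats/min,
#' total stressed volume in mL, blood density in g/mL.
#'
#' Defaults are the NORMAL-scenario calibration (see the shipped presets and
#' the methods vignette for how unprinted constants were chosen).
#'
#' @param R_MV,R_AV,R_TV,R_PAV linear valve resistances
#' @param R_SZ0,R_PZ0 characteristic impedances of the systemic and pulmonary
#'   circulation (in series with the aortic and pulmonary valves)
#' @param R_SA,R_SC,R_SV systemic arterial, capillary and venous resistances
#' @param R_PA,R_PC,R_PV pulmonary arterial, capillary and venous resistances
#' @param C_SA,C_SC,C_SV,C_PA,C_PC,C_PV compartment compliances
#' @param A_MV,A_AV,A_TV,A_PAV valve orifice areas
#' @param HR heart rate
#' @param V_total total stressed blood volume
#' @param rho blood density
#' @return an object of class `ecp_circuit` (named list)
#' @export
circuit_params <- function(R_MV = 0.004, R_AV = 0.005, R_TV = 0.003,
                           R_PAV = 0.004,
                           R_SZ0 = 0.051, R_SA = 0.806, R_SC = 0.143,
                           R_SV = 0.020,
                           R_PZ0 = 0.0024, R_PA = 0.0288, R_PC = 0.0120,
                           R_PV = 0.0048,
                           C_SA = 1.6, C_SC = 4.0, C_SV = 70, C_PA = 3.0,
                           C_PC = 5.0, C_PV = 8.0,
                           A_MV = 4.0, A_AV = 3.0, A_TV = 5.0, A_PAV = 3.5,
                           HR = 80, V_total = 1100, rho = 1.05) {
  p <- list(R_MV = R_MV, R_AV = R_AV, R_TV = R_TV, R_PAV = R_PAV,
            R_SZ0 = R_SZ0, R_SA = R_SA, R_SC = R_SC, R_SV = R_SV,
            R_PZ0 = R_PZ0, R_PA = R_PA, R_PC = R_PC, R_PV = R_PV,
            C_SA = C_SA, C_SC = C_SC, C_SV = C_SV, C_PA = C_PA,
            C_PC = C_PC, C_PV = C_PV,
            A_MV = A_MV, A_AV = A_AV, A_TV = A_TV, A_PAV = A_PAV,
            HR = HR, V_total = V_total, rho = rho)
  bad <- names(p)[vapply(p, function(x) !is.numeric(x) || length(x) != 1 ||
                           !is.finite(x) || x <= 0, logical(1))]
  if (length(bad))
    stop("circuit parameters must be single positive numbers; offending: ",
         paste(bad, collapse = ", "))
  structure(p, class = "ecp_circuit")
}

#' Derived systemic and pulmonary vascular resistance in Wood units
#'
#' The systemic resistive path is R_SZ0 + R_SA + R_SC + R_SV, the pulmonary
#' path R_PZ0 + R_PA + R_PC + R_PV (valve resistances excluded).
#'
#' @param params an `ecp_circuit`
#' @return resistance in Wood units
#' @export
svr_wu <- function(params)
  mmhg_s_ml_to_wu(params$R_SZ0 + params$R_SA + params$R_SC + params$R_SV)

#' @rdname svr_wu
#' @export
pvr_wu <- function(params)
  mmhg_s_ml_to_wu(params$R_PZ0 + params$R_PA + params$R_PC + params$R_PV)

#' Chamber elastance parameters
#'
#' One cardiac chamber of the time-varying-elastance model. The chamber
#' pressure blends a linear end-systolic pressure-volume relation (ESPVR,
#' slope `E_es`, volume intercept `V0`) with an exponential end-diastolic
#' relation (EDPVR) `P_ed(V) = edpvr_alpha * (exp(edpvr_beta * V) - 1)`,
#' weighted by the normalized double-Hill activation waveform.
#'
#' Activation timing is expressed as fractions of the cardiac cycle; cycle
#' phase 0 is ventricular activation onset, so atrial activation uses an
#' onset close to 1 (its peak precedes the next ventricular contraction).
#'
#' @param role one of "LA", "LV", "RA", "RV"
#' @param E_es end-systolic elastance (mmHg/mL)
#' @param E_min diastolic (minimal) elastance (mmHg/mL)
#' @param V0 ESPVR volume intercept (mL)
#' @param edpvr_alpha,edpvr_beta EDPVR constants (mmHg, 1/mL)
#' @param t_activation_onset activation onset as a cycle fraction
#' @param t_activation_duration activation window length as a cycle fraction
#' @return an object of class `ecp_chamber`
#' @export
chamber_params <- function(role, E_es, E_min, V0, edpvr_alpha, edpvr_beta,
                           t_activation_onset = 0,
                           t_activation_duration = 0.63) {
  role <- match.arg(role, c("LA", "LV", "RA", "RV"))
  stopifnot(is.numeric(E_es), is.numeric(E_min), E_min > 0, E_es >= E_min,
            V0 >= 0, edpvr_alpha > 0, edpvr_beta > 0,
            t_activation_onset >= 0, t_activation_onset < 1,
            t_activation_duration > 0, t_activation_duration < 1)
  structure(list(role = role, E_es = E_es, E_min = E_min, V0 = V0,
                 edpvr_alpha = edpvr_alpha, edpvr_beta = edpvr_beta,
                 t_activation_onset = t_activation_onset,
                 t_activation_duration = t_activation_duration,
                 act_norm = .hill_norm()),
            class = "ecp_chamber")
}

# peak of the raw double-Hill waveform over the normalized window; used to
# normalize activation to exactly 1 (so peak elastance equals E_es)
.hill_norm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      x <- seq(1e-6, 1 - 1e-6, length.out = 20001)
      o <- stats::optimize(.hill_raw, lower = x[which.max(.hill_raw(x))] - 1e-4,
                           upper = x[which.max(.hill_raw(x))] + 1e-4,
                           maximum = TRUE, tol = 1e-12)
      cache <<- o$objective
    }
    cache
  }
})

# raw (un-normalized) double-Hill activation on the window x in [0, 1]
.hill_raw <- function(x) {
  r1 <- (x / .act_const$tau1)^.act_const$n1
  r2 <- (x / .act_const$tau2)^.act_const$n2
  out <- (r1 / (1 + r1)) / (1 + r2)
  out[x <= 0 | x >= 1] <- 0
  out
}

#' Simulation state
#'
#' The instantaneous volumes (mL) of the ten compartments of the closed loop
#' plus the simulation time. The closed loop conserves the total volume: the
#' devices only redistribute blood.
#'
#' @param V_LA,V_LV,V_RA,V_RV chamber volumes
#' @param V_SA,V_SC,V_SV systemic arterial/capillary/venous volumes
#' @param V_PA,V_PC,V_PV pulmonary arterial/capillary/venous volumes
#' @param t simulation time (s)
#' @return an object of class `ecp_state`: list with `volumes` (named, in
#'   engine order) and `t`
#' @export
sim_state <- function(V_LA, V_LV, V_RA, V_RV, V_SA, V_SC, V_SV,
                      V_PA, V_PC, V_PV, t = 0) {
  v <- c(V_LA = V_LA, V_LV = V_LV, V_RA = V_RA, V_RV = V_RV,
         V_SA = V_SA, V_SC = V_SC, V_SV = V_SV,
         V_PA = V_PA, V_PC = V_PC, V_PV = V_PV)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all compartment volumes must be finite and >= 0")
  structure(list(volumes = v, t = t), class = "ecp_state")
}

.state_order <- c("V_LA", "V_LV", "V_RA", "V_RV", "V_SA", "V_SC", "V_SV",
                  "V_PA", "V_PC", "V_PV")

#' Load a scenario preset
#'
#' Presets ship as JSON under `inst/extdata/presets` and define the full
#' circuit, the four chambers, device defaults, the initial volume
#' distribution and engine settings:
#' \describe{
#'   \item{NORMAL}{healthy physiology (LV Ees 1.6, RV Ees 0.44 mmHg/mL,
#'     PVR 0.8 WU, SVR 17 WU)}
#'   \item{LVF}{left ventricular failure: LV Ees 0.4, RV Ees 0.5, PVR 0.8,
#'     SVR 11.7 WU}
#'   \item{BVF}{biventricular failure: LV Ees 0.4, RV Ees 0.2, PVR 0.8,
#'     SVR 11.7 WU}
#'   \item{BVF_PH}{biventricular failure with pulmonary hypertension:
#'     as BVF but PVR 6.0 WU (pulmonary characteristic impedance scaled
#'     linearly with PVR)}
#' }
#'
#' @param name preset name, case-insensitive
#' @return an object of class `ecp_scenario`: list with `name`, `circuit`,
#'   `chambers` (list LA/LV/RA/RV of `ecp_chamber`), `devices`, `initial`
#'   (an `ecp_state`), and `engine` settings
#' @export
scenario_preset <- function(name = c("NORMAL", "LVF", "BVF", "BVF_PH")) {
  name <- toupper(name)
  name <- match.arg(name)
  path <- system.file("extdata", "presets",
                      paste0(tolower(name), ".json"), package = "ecpella")
  if (!nzchar(path)) stop("preset file for ", name, " not found")
  load_scenario_json(path)
}

# build an ecp_scenario from a parsed preset/config list
build_scenario <- function(cfg, source = "<config>") {
  need <- c("name", "circuit", "chambers", "devices", "initial_volumes",
            "engine")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop(source, ": missing sections: ", paste(missing, collapse = ", "))

  circuit <- do.call(circuit_params,
                     c(cfg$circuit,
                       list(V_total = sum(unlist(cfg$initial_volumes)))))
  chambers <- lapply(c(LA = "LA", LV = "LV", RA = "RA", RV = "RV"),
                     function(role) {
                       cc <- cfg$chambers[[role]]
                       if (is.null(cc)) stop(source, ": chamber ", role,
                                             " missing")
                       do.call(chamber_params, c(list(role = role), cc))
                     })
  devices <- do.call(device_settings, cfg$devices)
  iv <- cfg$initial_volumes
  if (!setequal(names(iv), .state_order))
    stop(source, ": initial_volumes must name exactly: ",
         paste(.state_order, collapse = ", "))
  initial <- do.call(sim_state, iv[.state_order])
  eng <- modifyList(list(dt = 2e-4, decimation = 5, limiter_gain = 1.0,
                         v_floor = 1.0, p_max = 500), cfg$engine)
  sc <- structure(list(name = cfg$name, circuit = circuit,
                       chambers = chambers, devices = devices,
                       initial = initial, engine = eng),
                  class = "ecp_scenario")
  .check_preset_invariants(sc)
  sc
}

load_scenario_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_scenario(cfg, source = basename(path))
}

# printed scenario-defining values must survive any edit of the preset files
.check_preset_invariants <- function(sc) {
  tol <- 1e-6
  chk <- function(cond, what)
    if (!cond) stop("preset ", sc$name, " violates its defining value: ", what)
  if (sc$name %in% c("LVF", "BVF", "BVF_PH")) {
    chk(abs(sc$chambers$LV$E_es - 0.4) < tol, "LV E_es must be 0.4 mmHg/mL")
    chk(abs(svr_wu(sc$circuit) - 11.7) < 1e-3, "SVR must be 11.7 WU")
  }
  if (sc$name == "LVF")
    chk(abs(sc$chambers$RV$E_es - 0.5) < tol, "RV E_es must be 0.5 mmHg/mL")
  if (sc$name %in% c("BVF", "BVF_PH"))
    chk(abs(sc$chambers$RV$E_es - 0.2) < tol, "RV E_es must be 0.2 mmHg/mL")
  if (sc$name %in% c("LVF", "BVF"))
    chk(abs(pvr_wu(sc$circuit) - 0.8) < 1e-3, "PVR must be 0.8 WU")
  if (sc$name == "BVF_PH")
    chk(abs(pvr_wu(sc$circuit) - 6.0) < 1e-3, "PVR must be 6.0 WU")
  invisible(sc)
}

# chamber list -> 4x8 matrix for the C++ engine (rows LA, LV, RA, RV)
.chambers_matrix <- function(chambers) {
  m <- t(vapply(chambers[c("LA", "LV", "RA", "RV")], function(ch)
    c(ch$E_es, ch$E_min, ch$V0, ch$edpvr_alpha, ch$edpvr_beta,
      ch$t_activation_onset, ch$t_activation_duration, ch$act_norm),
    numeric(8)))
  colnames(m) <- c("E_es", "E_min", "V0", "alpha", "beta", "onset", "dur",
                   "norm")
  m
}

.circuit_vector <- function(params) unlist(unclass(params))
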