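# Configuration loading/validation, result serialization and test fixture
# generation.

.config_keys <- list(
  top = c("schema_version", "name", "description", "scenario", "circuit",
          "chambers", "devices", "initial_volumes", "engine", "schedule",
          "output"),
  circuit = c("R_MV", "R_AV", "R_TV", "R_PAV", "R_SZ0", "R_SA", "R_SC",
              "R_SV", "R_PZ0", "R_PA", "R_PC", "R_PV", "C_SA", "C_SC",
              "C_SV", "C_PA", "C_PC", "C_PV", "A_MV", "A_AV", "A_TV",
              "A_PAV", "HR", "rho", "SVR_WU", "PVR_WU"),
  chamber = c("E_es", "E_min", "V0", "edpvr_alpha", "edpvr_beta",
              "t_activation_onset", "t_activation_duration"),
  devices = c("vaecmo_flow", "impella_level", "vvecmo_on", "Hb",
              "SaO2_native", "SaO2_vv"),
  engine = c("dt", "decimation", "limiter_gain", "v_floor", "p_max"),
  schedule = c("settle_initial", "settle_per_level", "levels", "duration"),
  output = c("dir", "decimation", "verbosity"))

# collect every unknown key so the error names all of them at once
.validate_keys <- function(cfg) {
  bad <- character(0)
  note <- function(keys, allowed, where)
    c(bad, paste0(where, ": ", setdiff(keys, allowed)))
  bad <- note(names(cfg), .config_keys$top, "top level")
  for (sec in c("circuit", "devices", "engine", "schedule", "output"))
    if (!is.null(cfg[[sec]]))
      bad <- note(names(cfg[[sec]]), .config_keys[[sec]], sec)
  if (!is.null(cfg$chambers)) {
    bad <- note(names(cfg$chambers), c("LA", "LV", "RA", "RV"), "chambers")
    for (ch in intersect(names(cfg$chambers), c("LA", "LV", "RA", "RV")))
      bad <- note(names(cfg$chambers[[ch]]), .config_keys$chamber,
                  paste0("chambers$", ch))
  }
  if (!is.null(cfg$initial_volumes))
    bad <- note(names(cfg$initial_volumes), .state_order, "initial_volumes")
  bad <- bad[!grepl(": $", bad)]
  if (length(bad))
    stop("unknown configuration keys:\n  ", paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

#' Load and validate a run configuration
#'
#' A run configuration is JSON with an optional `scenario` preset name plus
#' override blocks (`circuit`, `chambers`, `devices`, `engine`,
#' `initial_volumes`, `schedule`, `output`). Preset values are merged first
#' and overrides win. Unknown keys anywhere are rejected, all reported at
#' once. The circuit block accepts `SVR_WU`/`PVR_WU`: given alone they
#' rescale the corresponding element resistances proportionally; given
#' together with element-level overrides they must agree with the element
#' sum (else an error).
#'
#' @param path path to a `.json` configuration file
#' @return an `ecp_config`: list with the resolved `scenario`
#'   (an `ecp_scenario`), `schedule` (an `ecp_schedule`), `output` options
#'   and `cycle_length` (s)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    stop("YAML configurations are not supported in this build ",
         "(no YAML parser available offline); please supply JSON")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  .validate_keys(cfg)

  base <- if (!is.null(cfg$scenario)) scenario_preset(cfg$scenario)
          else scenario_preset("NORMAL")
  preset_path <- system.file("extdata", "presets",
                             paste0(tolower(base$name), ".json"),
                             package = "ecpella")
  merged <- jsonlite::read_json(preset_path, simplifyVector = TRUE)

  circ_over <- cfg$circuit
  svr_req <- circ_over$SVR_WU
  pvr_req <- circ_over$PVR_WU
  circ_over$SVR_WU <- NULL
  circ_over$PVR_WU <- NULL
  for (sec in c("devices", "engine"))
    if (!is.null(cfg[[sec]]))
      merged[[sec]] <- modifyList(merged[[sec]], cfg[[sec]])
  if (length(circ_over))
    merged$circuit <- modifyList(merged$circuit, circ_over)
  if (!is.null(cfg$chambers))
    for (ch in names(cfg$chambers))
      merged$chambers[[ch]] <- modifyList(merged$chambers[[ch]],
                                          cfg$chambers[[ch]])
  if (!is.null(cfg$initial_volumes))
    merged$initial_volumes <- modifyList(merged$initial_volumes,
                                         as.list(cfg$initial_volumes))

  # Wood-unit totals: rescale when given alone, error on inconsistency
  merged$circuit <- .apply_wu(merged$circuit, svr_req, pvr_req,
                              overrode = names(circ_over))
  sc <- build_scenario2(merged, source = basename(path))

  schedule <- .resolve_schedule(cfg$schedule, sc)
  structure(list(scenario = sc, schedule = schedule,
                 output = modifyList(list(dir = ".", decimation = NULL,
                                          verbosity = 1),
                                     as.list(cfg$output)),
                 cycle_length = 60 / sc$circuit$HR),
            class = "ecp_config")
}

# build_scenario without the printed-value invariant check (user overrides
# may legitimately move Ees/PVR away from the named preset's values)
build_scenario2 <- function(cfg, source) {
  nm <- cfg$name
  cfg$name <- "NORMAL"
  sc <- build_scenario(cfg, source = source)
  sc$name <- nm
  sc
}

.apply_wu <- function(circ, svr_req, pvr_req, overrode) {
  syst <- c("R_SZ0", "R_SA", "R_SC", "R_SV")
  pulm <- c("R_PZ0", "R_PA", "R_PC", "R_PV")
  fix <- function(circ, req, els, label) {
    if (is.null(req)) return(circ)
    have <- mmhg_s_ml_to_wu(sum(unlist(circ[els])))
    if (any(els %in% overrode)) {
      if (abs(have - req) > 1e-6 * req)
        stop(label, "_WU override (", req, ") is inconsistent with the ",
             "element-level resistances (sum = ", signif(have, 6), " WU)")
    } else {
      for (e in els) circ[[e]] <- circ[[e]] * req / have
    }
    circ
  }
  circ <- fix(circ, svr_req, syst, "SVR")
  fix(circ, pvr_req, pulm, "PVR")
}

.resolve_schedule <- function(sch, sc) {
  dt <- sc$engine$dt
  if (is.null(sch)) {
    return(schedule(data.frame(duration = 20,
                               impella_level = sc$devices$impella_level,
                               vaecmo_flow = sc$devices$vaecmo_flow),
                    dt = dt))
  }
  if (!is.null(sch$duration)) {
    return(schedule(data.frame(duration = sch$duration,
                               impella_level = sc$devices$impella_level,
                               vaecmo_flow = sc$devices$vaecmo_flow),
                    dt = dt))
  }
  build_protocol_schedule(
    vaecmo_flow = sc$devices$vaecmo_flow,
    settle_initial = if (is.null(sch$settle_initial)) 100
                     else sch$settle_initial,
    settle_per_level = if (is.null(sch$settle_per_level)) 50
                       else sch$settle_per_level,
    levels = if (is.null(sch$levels)) 1:9 else unlist(sch$levels),
    dt = dt)
}

#' Write simulation results to disk
#'
#' Time series are written as `timeseries.csv` (the spec'd channel columns),
#' sweeps as `summary.csv` (one row per scenario x VA-ECMO flow x Impella
#' level); both get a JSON sidecar with provenance, and a manifest listing
#' every file with its MD5 hash. Re-running with identical inputs produces
#' identical hashes.
#'
#' @param result an `ecp_ts` or `ecp_sweep`
#' @param dir output directory (created if missing)
#' @return invisibly, the manifest data.frame (`file`, `md5`)
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)
  if (inherits(result, "ecp_ts")) {
    csv <- file.path(dir, "timeseries.csv")
    cols <- c("t", "LAP", "LVP", "SAP", "SCP", "SVP", "RAP", "RVP", "PAP",
              "PCP", "PVP", "V_LA", "V_LV", "V_RA", "V_RV", "Q_impella",
              "Q_vaecmo", "suction")
    write.csv(as.data.frame(result)[, cols], csv, row.names = FALSE)
    side <- file.path(dir, "timeseries.json")
    sch <- attr(result, "schedule")
    jsonlite::write_json(
      list(dt = attr(result, "dt"), decimation = attr(result, "decimation"),
           HR = attr(result, "HR"),
           schedule = as.data.frame(sch),
           params = unclass(attr(result, "params"))),
      side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(csv, side)
  } else if (inherits(result, "ecp_sweep")) {
    csv <- file.path(dir, "summary.csv")
    write.csv(result$grid, csv, row.names = FALSE)
    side <- file.path(dir, "sweep.json")
    jsonlite::write_json(
      list(protocol = result$protocol, provenance = result$provenance),
      side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(csv, side)
  } else stop("write_results handles ecp_ts and ecp_sweep objects")
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Synthetic fixtures with exactly known analytics
#'
#' Small constructed signals for unit testing:
#' \describe{
#'   \item{constant}{a flat `ecp_ts` (every channel constant): zero stroke
#'     work, trivially converged}
#'   \item{drifting}{an `ecp_ts` whose SAP grows by `drift` (default 5%)
#'     per beat: must be flagged non-converged}
#'   \item{rectangular_loop}{an `ecp_pvloop` tracing a `dV` x `dP` rectangle
#'     (area `dV * dP`), sampled densely along the perimeter}
#'   \item{settled_normal}{a short real run of the NORMAL preset}
#' }
#'
#' @param kind fixture kind
#' @param duration seconds (time-series kinds)
#' @param HR heart rate (beats/min)
#' @param dV,dP,V_start,P_start rectangle geometry (mL, mmHg)
#' @param n_side samples per rectangle side
#' @param drift per-beat relative SAP drift
#' @return an `ecp_ts` or `ecp_pvloop`
#' @export
make_fixture <- function(kind = c("constant", "drifting", "rectangular_loop",
                                  "settled_normal"),
                         duration = 10, HR = 80, dV = 40, dP = 50,
                         V_start = 60, P_start = 10, n_side = 50,
                         drift = 0.05) {
  kind <- match.arg(kind)
  if (kind == "rectangular_loop") {
    ramp <- seq(0, 1, length.out = n_side + 1)[-(n_side + 1)]
    # each side includes its starting corner and stops short of the next
    loop <- data.frame(
      volume = c(V_start + dV * ramp, rep(V_start + dV, n_side),
                 V_start + dV * (1 - ramp), rep(V_start, n_side)),
      pressure = c(rep(P_start, n_side), P_start + dP * ramp,
                   rep(P_start + dP, n_side), P_start + dP * (1 - ramp)))
    return(structure(loop, ventricle = "LV",
                     class = c("ecp_pvloop", "data.frame")))
  }
  if (kind == "settled_normal")
    return(simulate_scenario(scenario_preset("NORMAL"), duration = duration))
  dt_s <- 1e-3
  t <- seq(0, duration, by = dt_s)
  period <- 60 / HR
  sap <- if (kind == "constant") rep(90, length(t))
         else 90 * (1 + drift)^(t / period)
  zero <- rep(0, length(t))
  ts <- data.frame(t = t, LAP = 8, LVP = 60, RAP = 4, RVP = 15, SAP = sap,
                   SCP = 20, SVP = 6, PAP = 14, PCP = 10, PVP = 9,
                   V_LA = 45, V_LV = 120, V_RA = 40, V_RV = 115, V_SA = 144,
                   V_SC = 72, V_SV = 420, V_PA = 36, V_PC = 50, V_PV = 72,
                   Q_av = zero, Q_impella = zero, Q_vaecmo = zero,
                   suction = zero, impella_level = zero)
  structure(ts, dt = dt_s, decimation = 1, HR = HR,
            schedule = schedule(data.frame(duration = duration,
                                           impella_level = 0,
                                           vaecmo_flow = 0), dt = dt_s),
            class = c("ecp_ts", "data.frame"))
}
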