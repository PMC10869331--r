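# Per-beat haemodynamic analytics: PV loops, stroke work, pressure-volume
# area, beat summaries and global oxygen delivery.

#' Extract a ventricular pressure-volume loop from one beat
#'
#' @param beat an `ecp_beat` from [segment_beats()]
#' @param ventricle "LV" or "RV"
#' @return an `ecp_pvloop` data.frame with columns `volume` (mL) and
#'   `pressure` (mmHg), in time order over one cardiac cycle
#' @export
pv_loop <- function(beat, ventricle = c("LV", "RV")) {
  ventricle <- match.arg(ventricle)
  cols <- if (ventricle == "LV") c("V_LV", "LVP") else c("V_RV", "RVP")
  loop <- data.frame(volume = beat[[cols[1]]], pressure = beat[[cols[2]]])
  structure(loop, ventricle = ventricle,
            class = c("ecp_pvloop", "data.frame"))
}

# loop closure check: first and last point within one sample's travel
.check_closed <- function(loop) {
  n <- nrow(loop)
  if (n < 3) stop("PV loop needs at least 3 points")
  dv <- diff(loop$volume); dp <- diff(loop$pressure)
  step <- sqrt(dv^2 + dp^2)
  gap <- sqrt((loop$volume[1] - loop$volume[n])^2 +
                (loop$pressure[1] - loop$pressure[n])^2)
  # strictly periodic beats close to within one sample's travel; allow a
  # small fraction of the loop extent for nearly-settled beats
  diag <- sqrt(diff(range(loop$volume))^2 + diff(range(loop$pressure))^2)
  if (gap > max(max(step), 0.05 * diag) + 1e-9)
    stop("PV loop is not closed: end-to-start gap ", signif(gap, 4),
         " exceeds one sample's travel (", signif(max(step), 4),
         ") and 5% of the loop extent")
  invisible(TRUE)
}

#' Stroke work of a PV loop
#'
#' The area enclosed by one cardiac cycle's pressure-volume loop,
#' `SW = |closed-contour integral of P dV|`, computed with the shoelace rule
#' over the ordered samples (the loop is closed by joining the last point
#' back to the first).
#'
#' @param loop an `ecp_pvloop`; must be closed to within one sample's travel
#' @param check_closed verify closure first (disabled inside the beat
#'   pipeline, where a complete fixed-period beat is closed by wrap-around
#'   even when consecutive beats still differ slightly, as under heavy
#'   suction)
#' @return stroke work in mmHg·mL (non-negative)
#' @export
stroke_work <- function(loop, check_closed = TRUE) {
  if (check_closed) .check_closed(loop)
  v <- loop$volume; p <- loop$pressure
  v2 <- c(v[-1], v[1]); p2 <- c(p[-1], p[1])
  abs(sum(v * p2 - v2 * p)) / 2
}

#' Pressure-volume area of a beat
#'
#' Total mechanical energy of one beat: `PVA = SW + PE`, where the potential
#' energy PE is the area between the ESPVR line and the EDPVR curve from the
#' ESPVR volume intercept `V0` to the end-systolic volume (taken as the
#' loop's minimal volume), bounded below by the EDPVR; integrated with the
#' trapezoid rule on a 0.1 mL grid. If the end-systolic volume does not
#' exceed `V0`, PE is 0 (with a warning).
#'
#' @param loop an `ecp_pvloop`
#' @param chamber the matching ventricle's [chamber_params()]
#' @param check_closed see [stroke_work()]
#' @return PVA in mmHg·mL, with attributes `SW` and `PE`
#' @export
pressure_volume_area <- function(loop, chamber, check_closed = TRUE) {
  sw <- stroke_work(loop, check_closed = check_closed)
  v_es <- min(loop$volume)
  if (v_es <= chamber$V0) {
    warning("end-systolic volume (", signif(v_es, 4),
            " mL) does not exceed V0 (", chamber$V0, " mL); PE set to 0")
    pe <- 0
  } else {
    grid <- seq(chamber$V0, v_es, by = 0.1)
    if (grid[length(grid)] < v_es) grid <- c(grid, v_es)
    f <- pmax(0, chamber$E_es * (grid - chamber$V0) -
                chamber$edpvr_alpha * expm1(chamber$edpvr_beta * grid))
    pe <- sum(diff(grid) * (f[-1] + f[-length(f)]) / 2)
  }
  structure(sw + pe, SW = sw, PE = pe)
}

#' Summarize one beat
#'
#' Produces the per-beat haemodynamic indices: native cardiac output
#' (time-averaged trans-aortic-valve flow, which excludes the Impella), the
#' total systemic flow CO + Impella + VA-ECMO, time-averaged arterial and
#' atrial pressures, LV end-diastolic pressure (LV pressure at maximal LV
#' volume), per-ventricle stroke work and pressure-volume area, the device
#' flows and the suction flag (minimum LAP at or below 0 anywhere in the
#' beat).
#'
#' @param beat an `ecp_beat`
#' @param settings an [device_settings()]; `vaecmo_flow` is taken from the
#'   recorded series (they agree by construction for engine output)
#' @param chambers chamber list for SW/PVA; defaults to the beat's attribute
#' @return one-row data.frame (a BeatSummary)
#' @export
beat_summary <- function(beat, settings,
                         chambers = attr(beat, "chambers")) {
  co <- mean(beat$Q_av) * 60 / 1000
  q_imp <- mean(beat$Q_impella)
  q_ec <- if (!is.null(beat$Q_vaecmo)) mean(beat$Q_vaecmo)
          else settings$vaecmo_flow
  iedv <- which.max(beat$V_LV)
  out <- data.frame(
    CO = co,
    total_systemic_flow = co + q_imp + q_ec,
    mean_AP = mean(beat$SAP),
    mean_RAP = mean(beat$RAP),
    mean_LAP = mean(beat$LAP),
    LVEDP = beat$LVP[iedv],
    Q_impella = q_imp,
    Q_vaecmo = q_ec,
    suction = any(beat$LAP <= 0))
  if (!is.null(chambers)) {
    lv <- pv_loop(beat, "LV"); rv <- pv_loop(beat, "RV")
    out$SW_LV <- stroke_work(lv, check_closed = FALSE)
    out$SW_RV <- stroke_work(rv, check_closed = FALSE)
    out$PVA_LV <- suppressWarnings(as.numeric(
      pressure_volume_area(lv, chambers$LV, check_closed = FALSE)))
    out$PVA_RV <- suppressWarnings(as.numeric(
      pressure_volume_area(rv, chambers$RV, check_closed = FALSE)))
  }
  out
}

#' Global oxygen delivery under combined support
#'
#' `DO2 = 1.34 * 10 * Hb * SaO2 * (CO + Impella flow)
#'        + 1.34 * 10 * Hb * 1.0 * VA-ECMO flow`
#' in mL O2/min: the native-lung pathway (heart plus Impella) carries blood
#' at the patient's arterial saturation, while the VA-ECMO oxygenator
#' returns fully saturated blood. 1.34 mL O2/g is the haemoglobin oxygen
#' capacity and the factor 10 converts g/dL to g/L.
#'
#' @param Hb haemoglobin (g/dL)
#' @param SaO2 arterial saturation of the native-lung pathway (fraction)
#' @param CO native cardiac output (L/min)
#' @param Q_impella Impella flow (L/min)
#' @param Q_vaecmo VA-ECMO flow (L/min)
#' @return DO2 in mL O2/min, vectorized
#' @export
global_do2 <- function(Hb, SaO2, CO, Q_impella = 0, Q_vaecmo = 0) {
  if (any(SaO2 < 0 | SaO2 > 1)) stop("SaO2 must lie in [0, 1]")
  if (any(c(Hb, CO, Q_impella, Q_vaecmo) < 0))
    stop("Hb and all flows must be >= 0")
  1.34 * 10 * Hb * SaO2 * (CO + Q_impella) + 1.34 * 10 * Hb * 1.0 * Q_vaecmo
}

#' Summarize a steady-state snapshot
#'
#' Averages [beat_summary()] over the complete beats inside one snapshot
#' window; the suction flag is TRUE if any beat flags it.
#'
#' @param snapshot one element of [extract_steady_snapshots()] output
#' @param settings an [device_settings()]; defaults to the snapshot's
#'   schedule settings
#' @return one-row data.frame with the window's settings, convergence flag
#'   and averaged BeatSummary columns
#' @export
summarize_snapshot <- function(snapshot, settings = NULL) {
  if (is.null(settings))
    settings <- device_settings(vaecmo_flow = snapshot$vaecmo_flow,
                                impella_level = snapshot$impella_level)
  beats <- segment_beats(snapshot$window)
  if (!length(beats)) stop("snapshot window contains no complete beat")
  rows <- do.call(rbind, lapply(beats, beat_summary, settings = settings))
  out <- as.data.frame(lapply(rows[setdiff(names(rows), "suction")], mean))
  out$suction <- any(rows$suction)
  cbind(data.frame(impella_level = snapshot$impella_level,
                   vaecmo_flow = snapshot$vaecmo_flow,
                   converged = snapshot$converged), out)
}
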