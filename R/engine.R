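# Simulation engine: protocol schedules, the fixed-step RK4 run (C++ core),
# steady-state snapshot extraction and beat segmentation.

#' Build a staircase protocol schedule
#'
#' The standard experiment holds VA-ECMO flow constant while the Impella
#' support level climbs a staircase: an initial settling segment without
#' Impella (P0), then one segment per level. With the defaults (100 s
#' initial, 50 s per level, levels P1..P9) the total duration is 550 s.
#'
#' @param vaecmo_flow constant VA-ECMO flow for the whole run (L/min)
#' @param settle_initial duration of the Impella-free first segment (s)
#' @param settle_per_level duration of each level segment (s)
#' @param levels Impella levels visited after the initial segment
#' @param dt integrator step (s)
#' @return an object of class `ecp_schedule`: data.frame with columns
#'   `duration`, `impella_level`, `vaecmo_flow`; attributes `dt` and
#'   `total_duration`
#' @export
build_protocol_schedule <- function(vaecmo_flow = 0, settle_initial = 100,
                                    settle_per_level = 50, levels = 1:9,
                                    dt = 2e-4) {
  stopifnot(settle_initial > 0, settle_per_level > 0, vaecmo_flow >= 0,
            all(levels %in% 0:9))
  seg <- data.frame(duration = c(settle_initial,
                                 rep(settle_per_level, length(levels))),
                    impella_level = as.integer(c(0, levels)),
                    vaecmo_flow = vaecmo_flow)
  schedule(seg, dt = dt)
}

#' Assemble a schedule from explicit segments
#'
#' @param segments data.frame with columns `duration` (s), `impella_level`
#'   (0..9), `vaecmo_flow` (L/min)
#' @param dt integrator step (s)
#' @return an `ecp_schedule`
#' @export
schedule <- function(segments, dt = 2e-4) {
  need <- c("duration", "impella_level", "vaecmo_flow")
  stopifnot(is.data.frame(segments), all(need %in% names(segments)),
            all(segments$duration >= 0), all(segments$impella_level %in% 0:9),
            all(segments$vaecmo_flow >= 0), dt > 0)
  structure(segments[, need], dt = dt,
            total_duration = sum(segments$duration),
            class = c("ecp_schedule", "data.frame"))
}

#' Run a closed-loop simulation
#'
#' Integrates the circulation with the fixed-step explicit 4th-order
#' Runge-Kutta scheme at step `dt`, switching device settings at segment
#' boundaries. The run is fully deterministic. Any pressure exceeding
#' `p_max` in magnitude aborts with a diagnostic.
#'
#' @param params an [circuit_params()]
#' @param chambers named list (LA, LV, RA, RV) of [chamber_params()]
#' @param schedule an `ecp_schedule` (see [build_protocol_schedule()])
#' @param initial an [sim_state()]; volumes must sum to `params$V_total`
#' @param dt integrator step (s); defaults to the schedule's `dt`
#' @param decimation output thinning: one stored sample every `decimation`
#'   steps (default 5, i.e. 1 ms at the default step)
#' @param limiter_gain suction-limiter slope, (L/min)/mmHg
#' @param v_floor outflow throttle floor (mL)
#' @param p_max blow-up abort threshold (mmHg)
#' @param hq Impella H-Q table (see [default_hq_table()])
#' @return an `ecp_ts` data.frame: `t`, the ten pressures, the ten volumes,
#'   `Q_av` (trans-aortic flow mL/s), `Q_impella` and `Q_vaecmo` (L/min),
#'   `suction` (0/1) and `impella_level`; attributes carry `dt`,
#'   `decimation`, `HR`, `chambers`, `params` and the schedule
#' @export
run_simulation <- function(params, chambers, schedule, initial,
                           dt = attr(schedule, "dt"), decimation = 5,
                           limiter_gain = 1.0, v_floor = 1.0, p_max = 500,
                           hq = default_hq_table()) {
  stopifnot(inherits(schedule, "ecp_schedule"), inherits(initial, "ecp_state"))
  if (abs(sum(initial$volumes) - params$V_total) > 1e-6 * params$V_total)
    stop("initial volumes sum to ", sum(initial$volumes),
         " mL but V_total is ", params$V_total, " mL")
  m <- sim_run_cpp(initial$volumes[.state_order], .circuit_vector(params),
                   .chambers_matrix(chambers), .hq_matrix(hq),
                   schedule$duration, as.integer(schedule$impella_level),
                   schedule$vaecmo_flow, dt, as.integer(decimation),
                   limiter_gain, v_floor, p_max)
  ts <- as.data.frame(m)
  structure(ts, dt = dt, decimation = decimation, HR = params$HR,
            chambers = chambers, params = params, schedule = schedule,
            limiter_gain = limiter_gain,
            class = c("ecp_ts", "data.frame"))
}

#' Run a preset scenario
#'
#' Convenience wrapper binding a scenario preset's parameters, chambers,
#' initial state and engine settings to [run_simulation()].
#'
#' @param scenario an `ecp_scenario` from [scenario_preset()]
#' @param schedule an `ecp_schedule`; defaults to a device-free run of
#'   `duration` seconds
#' @param duration used only when `schedule` is NULL
#' @param ... overrides passed on to [run_simulation()]
#' @return an `ecp_ts`
#' @export
simulate_scenario <- function(scenario, schedule = NULL, duration = 20, ...) {
  stopifnot(inherits(scenario, "ecp_scenario"))
  if (is.null(schedule))
    schedule <- schedule(data.frame(
      duration = duration,
      impella_level = scenario$devices$impella_level,
      vaecmo_flow = scenario$devices$vaecmo_flow), dt = scenario$engine$dt)
  eng <- scenario$engine
  args <- modifyList(list(params = scenario$circuit,
                          chambers = scenario$chambers,
                          schedule = schedule, initial = scenario$initial,
                          dt = eng$dt, decimation = eng$decimation,
                          limiter_gain = eng$limiter_gain,
                          v_floor = eng$v_floor, p_max = eng$p_max),
                     list(...))
  do.call(run_simulation, args)
}

# re-attach ecp_ts attributes to a row-subset window
.ts_window <- function(ts, idx) {
  w <- as.data.frame(ts)[idx, , drop = FALSE]
  rownames(w) <- NULL
  for (a in c("dt", "decimation", "HR", "chambers", "params", "schedule",
              "limiter_gain"))
    attr(w, a) <- attr(ts, a)
  class(w) <- c("ecp_ts", "data.frame")
  w
}

#' Extract per-segment steady-state windows
#'
#' For every schedule segment, returns the analysis window ending `lead`
#' seconds (default 2 s) before the segment's end and spanning an integer
#' number of complete cardiac cycles (`n_beats`, at least 1). A segment is
#' flagged non-converged when the beat-to-beat mean systemic arterial
#' pressure varies by more than 1% across the window.
#'
#' @param ts an `ecp_ts` from [run_simulation()]
#' @param schedule the schedule that produced `ts` (defaults to its
#'   attribute)
#' @param n_beats number of complete beats per window
#' @param lead gap between window end and segment end (s)
#' @param tol_converged relative beat-to-beat mean-SAP spread accepted as
#'   steady state
#' @return list of snapshots, one per segment: list with `window` (an
#'   `ecp_ts`), `segment`, `impella_level`, `vaecmo_flow`, `t_start`,
#'   `t_end`, `converged`
#' @export
extract_steady_snapshots <- function(ts, schedule = attr(ts, "schedule"),
                                     n_beats = 4, lead = 2,
                                     tol_converged = 0.01) {
  stopifnot(inherits(ts, "ecp_ts"), n_beats >= 1)
  HR <- attr(ts, "HR")
  period <- 60 / HR
  ends <- cumsum(schedule$duration)
  starts <- c(0, ends[-length(ends)])
  lapply(seq_len(nrow(schedule)), function(i) {
    if (schedule$duration[i] < n_beats * period + lead + period)
      stop("segment ", i, " (", schedule$duration[i],
           " s) is too short for ", n_beats, " beats plus the ", lead,
           " s lead")
    t_end <- ends[i] - lead
    t_start <- t_end - n_beats * period
    idx <- which(ts$t >= t_start - 1e-9 & ts$t < t_end - 1e-9)
    w <- .ts_window(ts, idx)
    # beat-to-beat mean SAP over consecutive period-length chunks
    beat_id <- floor((w$t - t_start + 1e-9) / period)
    msap <- tapply(w$SAP, beat_id, mean)
    conv <- (max(msap) - min(msap)) <= tol_converged * max(mean(msap), 1e-12)
    list(window = w, segment = i,
         impella_level = schedule$impella_level[i],
         vaecmo_flow = schedule$vaecmo_flow[i],
         t_start = t_start, t_end = t_end, converged = unname(conv))
  })
}

#' Cut a time series into complete cardiac cycles
#'
#' Beats start at ventricular activation onset (cycle phase 0, i.e. times
#' that are integer multiples of the period 60/HR). Only beats fully inside
#' the series are returned; at the fixed sampling step every beat carries
#' the same number of samples whenever the period is a multiple of the
#' sample spacing (true for the defaults).
#'
#' @param ts an `ecp_ts` (or window thereof)
#' @param HR heart rate (beats/min); defaults to the series attribute
#' @return list of `ecp_beat` data.frames
#' @export
segment_beats <- function(ts, HR = attr(ts, "HR")) {
  stopifnot(is.data.frame(ts), !is.null(HR))
  period <- 60 / HR
  t0 <- ts$t[1]
  t1 <- ts$t[nrow(ts)]
  dt_s <- median(diff(ts$t))
  k0 <- ceiling((t0 - 1e-9) / period)
  out <- list()
  k <- k0
  while ((k + 1) * period <= t1 + dt_s / 2 + 1e-9) {
    idx <- which(ts$t >= k * period - 1e-9 & ts$t < (k + 1) * period - 1e-9)
    b <- .ts_window(ts, idx)
    class(b) <- c("ecp_beat", class(b))
    attr(b, "beat_index") <- k
    out[[length(out) + 1]] <- b
    k <- k + 1
  }
  out
}
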