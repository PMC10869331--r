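# The four protocol sweeps: VA-ECMO flow x Impella support level grids in
# left-ventricular failure, biventricular failure, biventricular failure
# with pulmonary hypertension, and the oxygen-delivery comparison with and
# without VV-ECMO.

.protocol_scenarios <- list(`1` = "LVF", `2` = "BVF", `3` = "BVF_PH",
                            `4` = c("BVF", "BVF_PH"))

#' Run a protocol sweep
#'
#' Protocols 1-3 sweep VA-ECMO flow 0..5 L/min in 0.5 steps; for each flow a
#' single simulation runs the in-run Impella staircase (settling segment at
#' P0, then P1..P9), and the steady window before each level change yields
#' one summary row, giving an 11 x 10 grid. Protocol 1 uses the LVF preset,
#' protocol 2 BVF, protocol 3 BVF with pulmonary hypertension. Protocol 4
#' runs BVF and BVF_PH with the VA-ECMO axis capped at 4 L/min and appends
#' global DO2 with the native-lung saturation (`do2_native`, SaO2 0.40) and
#' with VV-ECMO (`do2_vv`, SaO2 0.80) to every cell (Hb from the preset,
#' 10 g/dL).
#'
#' @param n protocol number, 1-4
#' @param overrides named list of engine/settling overrides:
#'   `settle_initial`, `settle_per_level` (s), `vaecmo_flows` (L/min grid),
#'   `levels`, `n_beats`, `decimation`, `dt`
#' @return an `ecp_sweep`: list with `protocol`, `grid` (tidy data.frame,
#'   one row per scenario x VA-ECMO flow x Impella level) and `provenance`
#'   (parameter hash and engine settings)
#' @export
run_protocol <- function(n, overrides = list()) {
  if (!(length(n) == 1 && n %in% 1:4)) stop("protocol must be 1, 2, 3 or 4")
  opt <- modifyList(list(settle_initial = 100, settle_per_level = 50,
                         vaecmo_flows = seq(0, if (n == 4) 4 else 5, by = 0.5),
                         levels = 1:9, n_beats = 4, decimation = 5,
                         dt = NULL), overrides)
  scenarios <- .protocol_scenarios[[as.character(n)]]
  grids <- lapply(scenarios, function(nm) {
    sc <- scenario_preset(nm)
    g <- sweep_scenario(sc, vaecmo_flows = opt$vaecmo_flows,
                        settle_initial = opt$settle_initial,
                        settle_per_level = opt$settle_per_level,
                        levels = opt$levels, n_beats = opt$n_beats,
                        decimation = opt$decimation, dt = opt$dt)
    if (n == 4) {
      dev <- sc$devices
      g$do2_native <- global_do2(dev$Hb, dev$SaO2_native, g$CO, g$Q_impella,
                                 g$Q_vaecmo)
      g$do2_vv <- global_do2(dev$Hb, dev$SaO2_vv, g$CO, g$Q_impella,
                             g$Q_vaecmo)
    }
    g
  })
  grid <- do.call(rbind, grids)
  rownames(grid) <- NULL
  prov <- list(parameter_hash = .sweep_hash(scenarios, opt),
               engine = opt, scenarios = scenarios)
  structure(list(protocol = n, grid = grid, provenance = prov),
            class = "ecp_sweep")
}

# one scenario's full VA-ECMO x Impella grid
sweep_scenario <- function(scenario, vaecmo_flows, settle_initial = 100,
                           settle_per_level = 50, levels = 1:9, n_beats = 4,
                           decimation = 5, dt = NULL) {
  if (is.null(dt)) dt <- scenario$engine$dt
  rows <- lapply(vaecmo_flows, function(ec) {
    sch <- build_protocol_schedule(vaecmo_flow = ec,
                                   settle_initial = settle_initial,
                                   settle_per_level = settle_per_level,
                                   levels = levels, dt = dt)
    ts <- simulate_scenario(scenario, schedule = sch, decimation = decimation)
    snaps <- extract_steady_snapshots(ts, n_beats = n_beats)
    do.call(rbind, lapply(snaps, summarize_snapshot))
  })
  grid <- do.call(rbind, rows)
  cbind(data.frame(scenario = scenario$name), grid)
}

# deterministic provenance hash (no external digest dependency): md5 of the
# serialized inputs
.sweep_hash <- function(scenarios, opt) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(utils::capture.output(utils::str(
    list(scenarios = scenarios, opt = opt,
         presets = lapply(scenarios, function(nm)
           unclass(scenario_preset(nm)$circuit))))), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

#' Per-VA-ECMO-flow maximum achieved Impella flow
#'
#' For each VA-ECMO flow of a sweep, the maximum steady per-beat-mean
#' Impella flow across support levels P0-P9. In the pulmonary-hypertension
#' scenario the suction limiter caps these maxima.
#'
#' @param result an `ecp_sweep` from [run_protocol()]
#' @param scenario optional scenario name filter (for protocol 4 results)
#' @return data.frame with `vaecmo_flow` and `max_impella_flow` (L/min)
#' @export
max_impella_flow <- function(result, scenario = NULL) {
  stopifnot(inherits(result, "ecp_sweep"))
  g <- result$grid
  if (!is.null(scenario)) g <- g[g$scenario == scenario, ]
  agg <- stats::aggregate(Q_impella ~ vaecmo_flow, data = g, FUN = max)
  names(agg)[2] <- "max_impella_flow"
  agg[order(agg$vaecmo_flow), ]
}

#' @export
print.ecp_sweep <- function(x, ...) {
  cat("ECPELLA protocol", x$protocol, "sweep:",
      paste(unique(x$grid$scenario), collapse = ", "), "\n")
  cat(nrow(x$grid), "cells;", sum(!x$grid$converged),
      "non-converged; parameter hash", x$provenance$parameter_hash, "\n")
  invisible(x)
}
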