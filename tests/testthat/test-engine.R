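# Schedules, the RK4 engine, snapshots and beat segmentation.

test_that("protocol schedule arithmetic", {
  sch <- build_protocol_schedule()
  expect_equal(attr(sch, "total_duration"), 550)  # 100 + 9 x 50
  expect_equal(nrow(sch), 10)
  expect_equal(sch$impella_level, as.integer(c(0, 1:9)))
  sch10 <- build_protocol_schedule(settle_per_level = 10)
  expect_equal(attr(sch10, "total_duration"), 190)
  expect_equal(nrow(build_protocol_schedule(levels = 4)), 2)
  expect_error(build_protocol_schedule(settle_initial = 0))
})

test_that("zero-duration schedule returns the initial sample only", {
  sc <- scenario_preset("NORMAL")
  sch <- schedule(data.frame(duration = 0, impella_level = 0,
                             vaecmo_flow = 0), dt = sc$engine$dt)
  ts <- simulate_scenario(sc, schedule = sch)
  expect_equal(nrow(ts), 1)
  expect_equal(ts$t, 0)
  expect_equal(unlist(ts[1, state_volume_cols]),
               sc$initial$volumes[ecpella:::.state_order],
               ignore_attr = TRUE)
})

test_that("NORMAL steady state is periodic at 60/HR and physiological", {
  ts <- cached_settled_run("NORMAL", 30)
  w <- ts[ts$t >= 26 & ts$t < 29, ]
  # period 0.75 s at HR 80: the signal one period later is the same
  sap <- w$SAP
  lag <- round(0.75 / (attr(ts, "dt") * attr(ts, "decimation")))
  expect_lt(max(abs(sap[seq_len(length(sap) - lag)] -
                      sap[-seq_len(lag)])), 0.01 * mean(sap))
  # baseline plausibility gate
  s <- summarize_snapshot(extract_steady_snapshots(ts, n_beats = 4)[[1]])
  expect_gte(s$CO, 4);  expect_lte(s$CO, 6)
  expect_gte(s$mean_AP, 70); expect_lte(s$mean_AP, 110)
  expect_gte(s$mean_LAP, 0); expect_lte(s$mean_LAP, 15)
  expect_gte(s$mean_RAP, 0); expect_lte(s$mean_RAP, 15)
})

test_that("total volume is conserved through a simulation", {
  ts <- cached_settled_run("NORMAL", 30)
  tot <- rowSums(ts[, state_volume_cols])
  expect_lt(max(abs(tot - tot[1])), 1e-6 * tot[1])
})

test_that("identical configuration reproduces a bit-identical series", {
  sc <- scenario_preset("BVF")
  sch <- build_protocol_schedule(vaecmo_flow = 2, settle_initial = 3,
                                 settle_per_level = 3, levels = c(2, 5))
  a <- simulate_scenario(sc, schedule = sch)
  b <- simulate_scenario(sc, schedule = sch)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("device settings in the output follow the schedule at every sample", {
  sc <- scenario_preset("BVF")
  sch <- build_protocol_schedule(vaecmo_flow = 1.5, settle_initial = 4,
                                 settle_per_level = 4, levels = c(3, 8))
  ts <- simulate_scenario(sc, schedule = sch)
  expected <- function(t) c(0, 3, 8)[findInterval(t, c(0, 4, 8),
                                                  rightmost.closed = FALSE)]
  # drop the final boundary sample (t = 12) which carries the last segment
  inner <- ts$t < 12
  expect_equal(ts$impella_level[inner], expected(ts$t[inner]))
})

test_that("engine aborts with a diagnostic on numerical blow-up", {
  sc <- scenario_preset("NORMAL")
  expect_error(simulate_scenario(sc, duration = 5, p_max = 50),
               "blow-up")
})

test_that("snapshot windows end 2 s before each alteration and flag drift", {
  ts <- cached_settled_run("NORMAL", 30)
  sn <- extract_steady_snapshots(ts, n_beats = 4)[[1]]
  dt_s <- attr(ts, "dt") * attr(ts, "decimation")
  expect_equal(sn$t_end, 30 - 2)
  expect_equal(max(sn$window$t), 28 - dt_s, tolerance = 1e-9)
  expect_equal(sn$t_end - sn$t_start, 4 * 0.75)
  expect_true(sn$converged)
  # constant synthetic series converges; drifting one is flagged
  expect_true(extract_steady_snapshots(make_fixture("constant"),
                                       n_beats = 4)[[1]]$converged)
  expect_false(extract_steady_snapshots(make_fixture("drifting"),
                                        n_beats = 4)[[1]]$converged)
  # segment too short for the window: error names the segment
  short <- make_fixture("constant", duration = 3)
  expect_error(extract_steady_snapshots(short, n_beats = 4), "segment 1")
})

test_that("beat segmentation cuts complete onset-aligned cycles", {
  ts3 <- make_fixture("constant", duration = 3, HR = 80)
  expect_length(segment_beats(ts3), 4)             # 3 s / 0.75 s
  expect_length(segment_beats(make_fixture("constant", duration = 0.7)), 0)
  beats <- segment_beats(ts3)
  expect_length(unique(vapply(beats, nrow, integer(1))), 1)
  # boundaries align with ventricular activation onset: E_LV is minimal at
  # the first sample of each beat of a real run
  ts <- cached_settled_run("NORMAL", 30)
  sn <- extract_steady_snapshots(ts, n_beats = 4)[[1]]
  b <- segment_beats(sn$window)[[2]]
  lv <- attr(ts, "chambers")$LV
  phases <- (b$t * attr(ts, "HR") / 60) %% 1
  e <- elastance_waveform(phases, lv)
  expect_equal(e[1], min(e), tolerance = 1e-9)
  expect_equal(e[1], lv$E_min)
})

test_that("RK4 at the default step is converged (dt halving)", {
  sc <- scenario_preset("NORMAL")
  get_settled <- function(dt) {
    sch <- schedule(data.frame(duration = 20, impella_level = 0,
                               vaecmo_flow = 0), dt = dt)
    ts <- simulate_scenario(sc, schedule = sch, dt = dt,
                            decimation = round(0.001 / dt))
    summarize_snapshot(extract_steady_snapshots(ts, n_beats = 4)[[1]])
  }
  a <- get_settled(2e-4)
  b <- get_settled(1e-4)
  for (col in c("CO", "mean_AP", "mean_LAP"))
    expect_lt(abs(a[[col]] - b[[col]]) / abs(b[[col]]), 0.005)
})
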