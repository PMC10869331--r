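# PV-loop analytics, beat summaries and oxygen delivery.

test_that("stroke work: rectangle, degenerate and open loops", {
  rect <- make_fixture("rectangular_loop", dV = 40, dP = 50)
  expect_equal(stroke_work(rect), 2000)
  thin <- make_fixture("rectangular_loop", dV = 0, dP = 50)
  expect_equal(stroke_work(thin), 0)
  open <- rect[1:80, ]
  class(open) <- class(rect)
  expect_error(stroke_work(open), "not closed")
})

test_that("stroke work agrees with an independent contour oracle on beats", {
  for (nm in c("LVF", "BVF")) {
    ts <- cached_settled_run(nm, 30)
    sn <- extract_steady_snapshots(ts, n_beats = 4)[[1]]
    for (b in segment_beats(sn$window)[1:2]) {
      for (v in c("LV", "RV")) {
        loop <- pv_loop(b, v)
        expect_equal(stroke_work(loop), trapz_loop_area(loop),
                     tolerance = 1e-3)
      }
    }
  }
})

test_that("pressure-volume area: triangle closed form and PVA >= SW", {
  # near-linear (negligible) EDPVR: PE is the analytic ESPVR triangle
  ch <- chamber_params("LV", E_es = 2, E_min = 0.05, V0 = 20,
                       edpvr_alpha = 1e-9, edpvr_beta = 1e-9)
  rect <- make_fixture("rectangular_loop", dV = 40, dP = 50, V_start = 60)
  pva <- pressure_volume_area(rect, ch)
  expect_equal(attr(pva, "PE"), 0.5 * 2 * (60 - 20)^2, tolerance = 1e-4)
  expect_equal(as.numeric(pva), 2000 + 0.5 * 2 * 40^2, tolerance = 1e-3)
  # end-systolic volume at V0: PVA reduces to SW
  at_v0 <- make_fixture("rectangular_loop", dV = 40, dP = 50, V_start = 20)
  expect_equal(suppressWarnings(
    as.numeric(pressure_volume_area(at_v0, ch))), 2000, tolerance = 1e-6)
  # below V0: PE zero with a warning
  low <- make_fixture("rectangular_loop", dV = 40, dP = 50, V_start = 5)
  expect_warning(pva_low <- pressure_volume_area(low, ch), "V0")
  expect_equal(attr(pva_low, "PE"), 0)
})

test_that("beat summary implements the stated definitions", {
  b <- make_fixture("constant", duration = 0.75)
  b$Q_av <- 50                 # mL/s -> CO 3 L/min
  b$Q_impella <- 2.5
  b$Q_vaecmo <- 4.0
  s <- beat_summary(b, device_settings(vaecmo_flow = 4, impella_level = 5))
  expect_equal(s$CO, 3)
  expect_equal(s$total_systemic_flow, 3 + 2.5 + 4)   # CO + Impella + ECMO
  expect_equal(s$mean_AP, 90)
  expect_false(s$suction)
  # zero aortic flow under full support mirrors "total ECPELLA support"
  b$Q_av <- 0
  expect_equal(beat_summary(b, device_settings())$total_systemic_flow, 6.5)
  # LAP at or below zero anywhere in the beat flags suction
  b$LAP <- -1
  expect_true(beat_summary(b, device_settings())$suction)
  # devices off: total systemic flow equals CO
  plain <- make_fixture("constant", duration = 0.75)
  plain$Q_av <- 70
  s0 <- beat_summary(plain, device_settings())
  expect_equal(s0$total_systemic_flow, s0$CO)
  # LVEDP is the pressure at maximal LV volume
  plain$V_LV <- seq(60, 130, length.out = nrow(plain))
  plain$LVP <- seq(5, 12, length.out = nrow(plain))
  expect_equal(beat_summary(plain, device_settings())$LVEDP, 12)
})

test_that("SW <= PVA on simulated beats of every preset", {
  for (nm in c("NORMAL", "LVF", "BVF", "BVF_PH")) {
    ts <- cached_settled_run(nm, 30)
    s <- summarize_snapshot(extract_steady_snapshots(ts, n_beats = 4)[[1]])
    expect_lte(s$SW_LV, s$PVA_LV + 1e-9)
    expect_lte(s$SW_RV, s$PVA_RV + 1e-9)
  }
})

test_that("global DO2 evaluates the printed equation", {
  expect_equal(global_do2(10, 0.5, 0), 0)
  # Hb 10, SaO2 0.8, CO + Impella = 3, ECMO 4
  expect_equal(global_do2(10, 0.8, CO = 1, Q_impella = 2, Q_vaecmo = 4),
               857.6)
  expect_equal(global_do2(20, 0.8, 1, 2, 4),
               2 * global_do2(10, 0.8, 1, 2, 4))      # linear in Hb
  # strictly increasing in every argument
  base <- global_do2(10, 0.5, 2, 1, 3)
  expect_gt(global_do2(11, 0.5, 2, 1, 3), base)
  expect_gt(global_do2(10, 0.6, 2, 1, 3), base)
  expect_gt(global_do2(10, 0.5, 2.5, 1, 3), base)
  expect_gt(global_do2(10, 0.5, 2, 1.5, 3), base)
  expect_gt(global_do2(10, 0.5, 2, 1, 3.5), base)
  expect_error(global_do2(10, 1.2, 2), "SaO2")
  expect_error(global_do2(-1, 0.5, 2))
})
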