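# Core model operations: elastance, chamber pressure, valve flow, pressures
# and the closed-loop volume balance.

lv <- chamber_params("LV", E_es = 0.4, E_min = 0.05, V0 = 10,
                     edpvr_alpha = 0.225, edpvr_beta = 0.03)

test_that("wood-unit conversion round-trips and matches the definition", {
  expect_equal(wu_to_mmhg_s_ml(1), 0.06)          # 1 mmHg·min/L in mmHg·s/mL
  expect_equal(mmhg_s_ml_to_wu(wu_to_mmhg_s_ml(11.7)), 11.7)
  p <- scenario_preset("BVF_PH")$circuit
  expect_equal(svr_wu(p), 11.7, tolerance = 1e-6)
  expect_equal(pvr_wu(p), 6.0, tolerance = 1e-6)
})

test_that("elastance waveform spans [E_min, E_es], peaks at E_es, wraps phase", {
  # activation-zero limit: late diastole for a ventricle (onset 0, dur 0.63)
  expect_equal(elastance_waveform(0.80, lv), lv$E_min)
  # peak equals E_es (normalized activation)
  grid <- seq(0, 1, by = 1e-4)
  e <- elastance_waveform(grid, lv)
  expect_equal(max(e), lv$E_es, tolerance = 1e-6)
  expect_true(all(e >= lv$E_min - 1e-12 & e <= lv$E_es + 1e-12))
  # periodicity and modulo normalization, never an error
  expect_equal(elastance_waveform(1.3, lv), elastance_waveform(0.3, lv))
  expect_equal(elastance_waveform(-0.7, lv), elastance_waveform(0.3, lv))
})

test_that("elastance matches an independent double-Hill oracle", {
  x <- c(0.1, 0.25, 0.4, 0.55, 0.7)
  a <- oracle_activation(x)
  got <- elastance_waveform(x * lv$t_activation_duration, lv)
  expect_equal(got, lv$E_min + a * (lv$E_es - lv$E_min), tolerance = 1e-6)
  # mid-activation blend: a(t) = 0.5 implies E halfway between E_min and E_es
  xm <- uniroot(function(z) oracle_activation(z) - 0.5, c(0.01, 0.3))$root
  expect_equal(elastance_waveform(xm * lv$t_activation_duration, lv),
               lv$E_min + 0.5 * (lv$E_es - lv$E_min), tolerance = 1e-4)
})

test_that("chamber pressure blends ESPVR and EDPVR", {
  # full activation at V = V0 sits on the ESPVR intercept
  expect_equal(chamber_pressure(lv$V0, lv$E_es, lv), 0)
  # zero activation at V = 0: EDPVR passes through the origin
  expect_equal(chamber_pressure(0, lv$E_min, lv), 0)
  # full activation, Ees 0.4, V - V0 = 100 -> 40 mmHg
  expect_equal(chamber_pressure(lv$V0 + 100, lv$E_es, lv), 40)
  # arbitrary activation: equals the blend computed by hand
  a <- 0.37; V <- 95
  e_t <- lv$E_min + a * (lv$E_es - lv$E_min)
  expect_equal(chamber_pressure(V, e_t, lv),
               a * 0.4 * (V - 10) + (1 - a) * 0.225 * expm1(0.03 * V))
  expect_error(chamber_pressure(-1, lv$E_es, lv), "volume")
})

test_that("valve flow is unidirectional and solves the orifice quadratic", {
  expect_equal(valve_flow(10, 15, A = 3, R_valve = 0.005), 0)  # closed
  # R = 0: pure Bernoulli, quadrupling the gradient doubles the flow
  q1 <- valve_flow(14, 10, A = 3, R_valve = 0)
  q4 <- valve_flow(26, 10, A = 3, R_valve = 0)
  expect_equal(q4 / q1, 2, tolerance = 1e-12)
  # root-finding oracle: dP = R q + B q^2 with B = rho/(2*(K*A)^2)
  A <- 3; R <- 0.005; rho <- 1.05
  B <- rho / (2 * (ecpella:::K_ORIFICE * A)^2)
  oracle <- uniroot(function(q) R * q + B * q^2 - 10, c(0, 1e5),
                    tol = 1e-12)$root
  expect_equal(valve_flow(20, 10, A, R, rho), oracle, tolerance = 1e-9)
  # strictly increasing in the gradient
  dp <- seq(0.5, 80, length.out = 50)
  expect_true(all(diff(valve_flow(10 + dp, 10, A, R)) > 0))
})

test_that("compartment pressures match a hand-computed table", {
  sc <- scenario_preset("NORMAL")
  st <- sim_state(V_LA = 45, V_LV = 120, V_RA = 40, V_RV = 115, V_SA = 180,
                  V_SC = 90, V_SV = 125, V_PA = 36, V_PC = 25, V_PV = 27,
                  t = 0.3)
  P <- compartment_pressures(st, sc$circuit, sc$chambers)
  # vascular: linear compliances
  expect_equal(unname(P["SAP"]), 180 / 2.0)
  expect_equal(unname(P["SCP"]), 90 / 5.0)
  expect_equal(unname(P["SVP"]), 125 / 25)
  expect_equal(unname(P["PAP"]), 36 / 2.0)
  expect_equal(unname(P["PCP"]), 25 / 2.5)
  expect_equal(unname(P["PVP"]), 27 / 3.0)
  # zero volume gives zero vascular pressure
  st0 <- sim_state(45, 120, 40, 115, 0, 90, 125, 36, 25, 27)
  expect_equal(unname(compartment_pressures(st0, sc$circuit,
                                            sc$chambers)["SAP"]), 0)
  # chambers: blend evaluated independently at the same phase
  phase <- (0.3 * sc$circuit$HR / 60) %% 1
  for (role in c("LA", "LV", "RA", "RV")) {
    ch <- sc$chambers[[role]]
    a <- oracle_activation(((phase - ch$t_activation_onset) %% 1) /
                             ch$t_activation_duration)
    V <- st$volumes[[paste0("V_", role)]]
    expected <- a * ch$E_es * (V - ch$V0) +
      (1 - a) * ch$edpvr_alpha * expm1(ch$edpvr_beta * V)
    expect_equal(unname(P[[paste0(substr(role, 1, 2), "P")]]), expected,
                 tolerance = 1e-5)
  }
})

test_that("circulation_rhs is zero at pressure equilibrium and conservative", {
  sc <- scenario_preset("NORMAL")
  p <- sc$circuit
  # all pressures equal 10 mmHg in diastole (no activation at phase 0.75)
  vdia <- function(ch) log(10 / ch$edpvr_alpha + 1) / ch$edpvr_beta
  st <- sim_state(V_LA = vdia(sc$chambers$LA), V_LV = vdia(sc$chambers$LV),
                  V_RA = vdia(sc$chambers$RA), V_RV = vdia(sc$chambers$RV),
                  V_SA = 10 * p$C_SA, V_SC = 10 * p$C_SC, V_SV = 10 * p$C_SV,
                  V_PA = 10 * p$C_PA, V_PC = 10 * p$C_PC, V_PV = 10 * p$C_PV,
                  t = 0.75 * 60 / p$HR)
  d <- circulation_rhs(st, p, sc$chambers)
  expect_equal(unname(d), rep(0, 10), tolerance = 1e-10, ignore_attr = TRUE)

  # conservation: derivatives sum to zero for arbitrary states and devices
  set.seed(42)
  for (i in 1:25) {
    st <- do.call(sim_state, c(as.list(10 + runif(10, 0, 200)),
                               list(t = runif(1, 0, 2))))
    d <- circulation_rhs(st, p, sc$chambers,
                         devices = list(q_impella = runif(1, 0, 4),
                                        q_vaecmo = runif(1, 0, 5)))
    expect_lt(abs(sum(d)) / max(sum(abs(d)), 1e-9), 1e-12)
  }
})

test_that("circulation_rhs matches a hand-traced Kirchhoff balance", {
  sc <- scenario_preset("NORMAL")
  p <- sc$circuit
  st <- sim_state(V_LA = 50, V_LV = 110, V_RA = 45, V_RV = 100, V_SA = 170,
                  V_SC = 80, V_SV = 140, V_PA = 40, V_PC = 30, V_PV = 30,
                  t = 0.75 * 60 / p$HR)  # diastole, valves MV/TV open
  P <- compartment_pressures(st, p, sc$chambers)
  d <- circulation_rhs(st, p, sc$chambers)
  # SC node has no valves or devices: dV_SC = (SAP-SCP)/R_SA - (SCP-SVP)/R_SC
  expect_equal(unname(d["V_SC"]),
               (P[["SAP"]] - P[["SCP"]]) / p$R_SA -
                 (P[["SCP"]] - P[["SVP"]]) / p$R_SC, tolerance = 1e-10)
  # PA node: pulmonary valve inflow minus arterial runoff
  q_pav <- valve_flow(P[["RVP"]], P[["PAP"]], p$A_PAV, p$R_PAV + p$R_PZ0,
                      p$rho)
  expect_equal(unname(d["V_PA"]),
               q_pav - (P[["PAP"]] - P[["PCP"]]) / p$R_PA, tolerance = 1e-10)
})

test_that("pure-R rhs agrees with the C++ engine rhs", {
  sc <- scenario_preset("BVF_PH")
  p <- sc$circuit
  hq <- default_hq_table()
  set.seed(7)
  for (i in 1:20) {
    vols <- 5 + runif(10, 0, 180)
    t <- runif(1, 0, 1.5)
    level <- sample(0:9, 1)
    ec <- sample(seq(0, 5, 0.5), 1)
    st <- do.call(sim_state, c(as.list(vols), list(t = t)))
    P <- compartment_pressures(st, p, sc$chambers)
    lim <- suction_limiter(P[["LAP"]],
                           impella_flow(level, P[["SAP"]] - P[["LVP"]], hq))
    d_r <- circulation_rhs(st, p, sc$chambers,
                           devices = list(q_impella = lim$Q_effective,
                                          q_vaecmo = ec), t = t)
    d_c <- ecpella:::sim_rhs_cpp(st$volumes, ecpella:::.circuit_vector(p),
                                 ecpella:::.chambers_matrix(sc$chambers),
                                 ecpella:::.hq_matrix(hq), t, level, ec,
                                 1.0, 1.0)
    expect_equal(unname(d_r), unname(d_c$dVdt), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(unname(P), unname(d_c$pressures), tolerance = 1e-10)
  }
})

test_that("valve flows are non-negative throughout a simulation", {
  ts <- cached_settled_run("NORMAL", 30)
  expect_true(all(ts$Q_av >= 0))
  expect_true(all(ts$Q_impella >= 0))
})
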