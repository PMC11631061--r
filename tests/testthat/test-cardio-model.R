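# Chamber activation, pressure-volume law, valve law, and the closed-loop
# simulator's structural invariants.

test_that("activation rises from zero to a single peak and relaxes", {
  expect_identical(activation(0, 300, 60), 0)
  expect_identical(activation(-50, 300, 60), 0)

  t <- seq(0, 1000, by = 1)
  a <- activation(t, 300, 60)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(max(a), 1, tolerance = 1e-6)
  # exactly one interior local maximum
  d <- diff(a)
  n_max <- sum(d[-length(d)] > 0 & d[-1] <= 0)
  expect_identical(n_max, 1L)
  # continuity at the rise/decay junction
  expect_lt(abs(activation(300 - 1e-9, 300, 60) -
                  activation(300 + 1e-9, 300, 60)), 1e-6)
  # decay: three time constants past the active phase, < 5% of peak
  expect_lt(activation(300 + 3 * 60, 300, 60), 0.05 * max(a))
  expect_equal(activation(300 + 3 * 60, 300, 60), exp(-3),
               tolerance = 1e-12)
  expect_error(activation(10, -1, 60), "positive")
  expect_error(activation(10, 300, 0), "positive")
})

test_that("chamber pressure law matches its closed form", {
  cp <- chamber_params(V0 = 50, E_act = 2, P_ref = 0.5, k = 2,
                       d_act = 300, tau = 50)
  expect_equal(chamber_pressure(cp, 50, 0), 0)
  expect_equal(chamber_pressure(cp, 60, 0), 0.5 * (exp(0.2 * 2) - 1))
  # active term scales linearly with contractility
  cp1 <- chamber_params(V0 = 50, E_act = 2, c = 0.5, P_ref = 0.5, k = 2,
                        d_act = 300, tau = 50)
  cp2 <- chamber_params(V0 = 50, E_act = 2, c = 1.0, P_ref = 0.5, k = 2,
                        d_act = 300, tau = 50)
  passive <- chamber_pressure(cp, 70, 0)
  act1 <- chamber_pressure(cp1, 70, 1) - passive
  act2 <- chamber_pressure(cp2, 70, 1) - passive
  expect_equal(act2, 2 * act1)
  # monotone non-decreasing in V above V0
  v <- seq(50, 150, by = 1)
  expect_true(all(diff(chamber_pressure(cp, v, 0.5)) > 0))
  expect_error(chamber_pressure(cp, -1, 0), "non-negative")
})

test_that("valves are ideal diodes, with inertance when enabled", {
  expect_identical(valve_flow(10, 10, R = 0.005), 0)
  expect_identical(valve_flow(0, 10, R = 0.005), 0)   # closed, no leak
  q1 <- valve_flow(15, 10, R = 0.005)
  q2 <- valve_flow(20, 10, R = 0.005)
  expect_gt(q1, 0)
  expect_gt(q2, q1)
  expect_equal(q1, 5 / 0.005)
  # inertance: flow is a state; closed valve with no gradient stays shut
  st <- valve_flow(5, 10, R = 0.005, L = 3e-4, q = 0)
  expect_identical(st$q, 0)
  expect_identical(st$dq_dt, 0)
  st <- valve_flow(15, 10, R = 0.005, L = 3e-4, q = 100)
  expect_equal(st$dq_dt, (5 - 0.005 * 100) / 3e-4)
})

test_that("total blood volume is conserved to round-off over 50 beats", {
  circ <- circulation_params()
  sim <- simulate_model(hfpef_phenotype(), circ, n_beats = 50)
  tot <- rowSums(sim$full_trajectory[, c("v_la", "v_lv", "v_ra", "v_rv",
                                         "v_sa", "v_sv", "v_pa", "v_pv")])
  expect_lt(max(abs(tot - circ$V_tot)) / circ$V_tot, 1e-6)
})

test_that("steady state is periodic and flows are consistent", {
  run <- baseline_run()
  expect_true(run$steady_converged)
  tr <- run$trajectory
  n <- nrow(tr) - 1L
  # periodicity: endpoints of the steady beat agree
  for (col in c("v_la", "v_lv", "p_la", "p_lv"))
    expect_lt(abs(tr[[col]][1] - tr[[col]][n + 1]) /
                max(abs(tr[[col]][1]), 1), 1e-3)
  # beat-averaged mitral flow = beat-averaged aortic flow = CO within 1%
  q_mv <- mean(tr$q_mv[seq_len(n)])
  q_av <- mean(tr$q_av[seq_len(n)])
  expect_lt(abs(q_mv - q_av) / q_av, 0.01)
  co_flow <- q_av * 60 / 1000
  expect_lt(abs(co_flow - run$metrics$co) / run$metrics$co, 0.01)
  # metric-level invariants
  m <- run$metrics
  expect_gte(m$lvedv, m$sv)
  expect_lte(m$mlap, m$peak_lap)
})

test_that("without active contraction the loop relaxes to static equilibrium", {
  circ <- circulation_params()
  sim <- simulate_model(hfpef_phenotype(), circ, n_beats = 80,
                        activation_const = 0)
  tr <- sim$trajectory
  last <- nrow(tr)
  ps <- unlist(tr[last, c("p_la", "p_lv", "p_ra", "p_rv", "p_sa", "p_sv",
                          "p_pa", "p_pv")])
  expect_lt(sim$metrics$co, 0.01)           # no pump, no flow
  expect_lt(max(ps) - min(ps), 0.1)         # pressures equalized
})

test_that("open-valve relaxation matches the closed-form RC equilibrium", {
  ph <- hfpef_phenotype(pericardial_constraint_enabled = FALSE)
  circ <- circulation_params(pericardium = list(enabled = FALSE, P_ref = 1,
                                                k = 8, V0 = 520))
  eq <- static_equilibrium(ph, circ, a_const = 0)
  sim <- simulate_model(ph, circ, n_beats = 40, valves_open = TRUE,
                        activation_const = 0)
  tr <- sim$trajectory
  last <- nrow(tr)
  ps <- unlist(tr[last, c("p_la", "p_lv", "p_ra", "p_rv", "p_sa", "p_sv",
                          "p_pa", "p_pv")])
  expect_true(all(abs(ps - eq$pressure) / eq$pressure < 0.005))
  vols <- unlist(tr[last, c("v_la", "v_lv", "v_ra", "v_rv", "v_sa",
                            "v_sv", "v_pa", "v_pv")])
  expect_equal(unname(vols), unname(eq$volumes), tolerance = 0.005)
})

test_that("compiled chamber pressures agree with the R law along a beat", {
  run <- baseline_run()
  tr <- run$trajectory
  heart <- apply_phenotype(hfpef_phenotype())
  peri <- circulation_params()$pericardium
  vh <- tr$v_la + tr$v_lv + tr$v_ra + tr$v_rv
  p_peri <- peri$P_ref * (vh / peri$V0)^peri$k
  # LV activation is exported in the trajectory; subtract the pericardial
  # component and compare with the R-side chamber law
  p_r <- chamber_pressure(heart$LV, tr$v_lv, pmin(tr$act_lv, 1)) + p_peri
  expect_equal(p_r, tr$p_lv, tolerance = 1e-8)
})

test_that("stiffer LV passive properties raise steady-state mLAP", {
  run <- baseline_run()
  stiffer <- hfpef_phenotype(lv_passive_stiffness_scale =
                               hfpef_phenotype()$lv_passive_stiffness_scale * 1.5)
  run2 <- steady_regulated(stiffer, circulation_params())
  expect_gt(run2$metrics$mlap, run$metrics$mlap)
})

test_that("atrial myopathy weakens the A wave and raises mLAP", {
  run <- baseline_run()
  myo <- hfpef_phenotype(atrial_contractility_fraction = 0.5)
  run2 <- steady_regulated(myo, circulation_params())
  expect_lt(run2$metrics$a_peak, run$metrics$a_peak)
  expect_gt(run2$metrics$mlap, run$metrics$mlap)
})

test_that("beat metrics compute time averages and E/A structure", {
  # constant LA pressure -> mLAP equals it exactly
  tm <- activation_timing(60, 150)
  m <- beat_metrics(fake_beat(p_la = 10), tm)
  expect_equal(m$mlap, 10)
  expect_equal(m$peak_lap, 10)
  # single unbroken diastolic wave -> fused, no ratio
  t <- (0:999) / 1000
  q1 <- 300 * exp(-((t - 0.6) / 0.08)^2 / 2)
  m1 <- beat_metrics(fake_beat(q_mv = q1), tm)
  expect_true(m1$ea_fused)
  expect_true(is.na(m1$ea_ratio))
  # two separated waves -> E/A recovered (E after ventricular onset at
  # 150 ms, A at the cycle start = atrial systole)
  q2 <- 300 * exp(-((t - 0.55) / 0.06)^2 / 2) +
    200 * exp(-((t - 0.06) / 0.04)^2 / 2)
  m2 <- beat_metrics(fake_beat(q_mv = q2), tm)
  expect_false(m2$ea_fused)
  expect_equal(m2$ea_ratio, 1.5, tolerance = 0.05)
  # non-periodic trace warns but still computes
  bad <- fake_beat(p_la = 10)
  bad$v_lv[nrow(bad)] <- bad$v_lv[1] * 1.2
  expect_warning(mb <- beat_metrics(bad, tm), "periodic")
  expect_equal(mb$mlap, 10)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(chamber_params(V0 = -1, E_act = 1, P_ref = 1, k = 1,
                              d_act = 100, tau = 50))
  expect_error(activation_timing(20, 100))
  expect_error(activation_timing(60, 500))
  expect_error(hfpef_phenotype(atrial_contractility_fraction = 0))
  expect_error(hfpef_phenotype(atrial_contractility_fraction = 1.2))
  expect_error(circulation_params(V_tot = 100), "V_tot")
  tm <- activation_timing(75, 200)
  expect_equal(tm$cycle_length, 800)
})
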