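test_that("Kp,uu clearance algebra matches the closed form and inverts", {
  expect_identical(kpuu_from_clearances(45, 0), 1)
  expect_identical(kpuu_from_clearances(45, 45), 0.5)
  expect_equal(kpuu_from_clearances(45, 100.16), 0.31, tolerance = 1e-4)
  expect_error(kpuu_from_clearances(0, 10), "cl_int_pd")

  expect_identical(clpgp_from_kpuu(1, 45), 0)
  expect_identical(clpgp_from_kpuu(0.5, 45), 45)
  expect_equal(clpgp_from_kpuu(0.48, 45), 45 * (1 - 0.48) / 0.48)
  expect_equal(clpgp_from_kpuu(0.48, 45), 48.75)
  expect_error(clpgp_from_kpuu(0, 45), "kpuu")
  expect_error(clpgp_from_kpuu(1.2, 45), "kpuu")

  # round-trip to 1e-12 relative across the unit interval
  for (k in seq(0.05, 1, by = 0.05)) {
    expect_equal(kpuu_from_clearances(45, clpgp_from_kpuu(k, 45)), k,
                 tolerance = 1e-12)
  }
})

test_that("well-stirred hepatic clearance behaves and respects induction", {
  # closed form: Q fu CLint / (Q + fu CLint) = 90*21.2/111.2
  expect_equal(hepatic_clearance(106, 0.2, 90, 1), 1908 / 111.2,
               tolerance = 1e-12)
  expect_equal(hepatic_clearance(106, 0.2, 90, 1), 17.16, tolerance = 1e-3)
  # doubling intrinsic clearance is the same as a twofold induction
  expect_equal(hepatic_clearance(53, 0.36, 97, 2),
               hepatic_clearance(106, 0.36, 97, 1))
  # vanishing unbound fraction kills clearance
  expect_lt(hepatic_clearance(106, 1e-9, 90, 1), 1e-5)
  # bounded by hepatic blood flow, monotone in every argument
  grid <- expand.grid(cl = c(10, 106, 1e4), fu = c(0.1, 0.9), q = c(45, 97))
  cls <- mapply(hepatic_clearance, grid$cl, grid$fu, grid$q)
  expect_true(all(cls < grid$q))
  expect_true(all(diff(sapply(c(10, 50, 200), hepatic_clearance,
                              fu_maternal = 0.3, q_hepatic = 90)) > 0))
  expect_error(hepatic_clearance(-1, 0.3, 90), "cl_hep_int")
})

test_that("perfusion-limited passive clearance saturates at placental flow", {
  expect_equal(effective_pd_clearance(1e9, 45), 45, tolerance = 1e-6)
  expect_equal(effective_pd_clearance(45, 45), 22.5)
  expect_equal(effective_pd_clearance(10, 45), 450 / 55)
  expect_equal(effective_pd_clearance(10, 45), 8.18, tolerance = 1e-3)
  expect_lte(effective_pd_clearance(30, 45), 30)
  expect_error(effective_pd_clearance(0, 45), "cl_int_pd")
})

test_that("the right-hand side matches hand-computed fluxes", {
  params <- simple_params(cl_total = 5, v_m = 50, v_f = 5, fu_m = 0.4,
                          fu_f = 0.4, cl_int_pd = 1e6, cl_int_pgp = 0)
  ab <- absorption_params("im", ka_fast = 1.5, ka_slow = 0.2,
                          fraction_fast = 0.5)

  # zero state -> zero derivative
  d0 <- pbpk_rhs(state_vector(), 0, params, ab)
  expect_true(all(d0 == 0))

  # detailed balance: no efflux, no fetal elimination, no maternal
  # elimination, equal unbound concentrations -> zero net flux everywhere
  p_bal <- simple_params(cl_total = 0, v_m = 50, v_f = 5, fu_m = 0.2,
                         fu_f = 0.5, cl_int_pgp = 0)
  # fu_m * a_m/v_m == fu_f * a_f/v_f  with a_m = 10: a_f = 10*0.2/50*5/0.5
  st <- state_vector(a_maternal = 10, a_fetal = 10 * 0.2 / 50 * 5 / 0.5)
  d_bal <- pbpk_rhs(st, 0, p_bal, ab)
  expect_equal(unname(d_bal["a_maternal"]), 0, tolerance = 1e-14)
  expect_equal(unname(d_bal["a_fetal"]), 0, tolerance = 1e-14)

  # arithmetic oracle: single nonzero maternal amount
  clpd_eff <- 45 * 1e6 / (1e6 + 45)
  st2 <- state_vector(a_maternal = 10)
  d2 <- pbpk_rhs(st2, 0, params, ab)
  cm <- 10 / 50
  expect_equal(unname(d2["a_maternal"]), -(5 * cm + clpd_eff * 0.4 * cm))
  expect_equal(unname(d2["a_fetal"]), clpd_eff * 0.4 * cm)
  expect_equal(unname(d2["elim_maternal"]), 5 * cm)
  # depots decay first-order
  st3 <- state_vector(depot_fast = 4, depot_slow = 6)
  d3 <- pbpk_rhs(st3, 0, params, ab)
  expect_equal(unname(d3["depot_fast"]), -1.5 * 4)
  expect_equal(unname(d3["depot_slow"]), -0.2 * 6)
  expect_equal(unname(d3["a_maternal"]), 1.5 * 4 + 0.2 * 6)
})

test_that("zero dose input yields an identically zero profile", {
  reg0 <- regimen("nothing", 0, 0, acs_absorption("BET"))
  prof <- simulate_regimen(reg0, acs_params("BET"), tmax = 12)
  expect_true(all(prof$mp_ng_ml == 0))
  expect_true(all(prof$uv_ng_ml == 0))
})

test_that("i.v. bolus with no placental transfer matches the one-compartment closed form", {
  D <- 8; V <- 50; CL <- 5
  params <- simple_params(cl_total = CL, v_m = V, cl_int_pd = 0)
  prof <- simulate_regimen(iv_regimen(D), params, tmax = 24)
  analytic <- D / V * exp(-CL / V * prof$time_h) * 1000  # mg/L -> ng/ml
  expect_equal(prof$mp_ng_ml, analytic, tolerance = 1e-7)
  expect_true(all(prof$uv_ng_ml == 0))
})

test_that("constant infusion reaches the Kp,uu steady state of the clearance algebra", {
  params <- simple_params(cl_total = 5, cl_int_pgp = 30)
  ratio <- steady_state_unbound_ratio(params, hours = 300)
  expect_equal(ratio, model_kpuu(params), tolerance = 5e-4)
  # no efflux, no fetal elimination -> unbound equilibrium at 1
  params1 <- simple_params(cl_total = 5, cl_int_pgp = 0, fu_m = 0.3,
                           fu_f = 0.45)
  expect_equal(steady_state_unbound_ratio(params1, hours = 300), 1,
               tolerance = 5e-4)
})

test_that("steady-state UV/MP decreases strictly with the efflux clearance", {
  ratios <- vapply(c(0, 10, 30, 90), function(clpgp) {
    steady_state_unbound_ratio(simple_params(cl_total = 5,
                                             cl_int_pgp = clpgp),
                               hours = 250)
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("solutions are dose-linear, time-shift equivariant and mass-conserving", {
  regs <- builtin_regimens()
  pb <- acs_params("BET")
  pd <- acs_params("DEX")

  # dose linearity to < 1e-6 relative
  lambda <- 3.7
  base <- simulate_regimen(regs$BET_ref, pb)
  scaled_reg <- regimen("scaled", regs$BET_ref$doses$time_h,
                        regs$BET_ref$doses$amount_mg * lambda,
                        regs$BET_ref$absorption)
  scaled <- simulate_regimen(scaled_reg, pb)
  keep <- base$mp_ng_ml > 1e-6
  expect_lt(max(abs(scaled$mp_ng_ml[keep] / base$mp_ng_ml[keep] - lambda)),
            lambda * 1e-6)
  keep_f <- base$uv_ng_ml > 1e-6
  expect_lt(max(abs(scaled$uv_ng_ml[keep_f] / base$uv_ng_ml[keep_f] - lambda)),
            lambda * 1e-6)

  # shifting all dose times by 6 h shifts the solution by 6 h
  shift <- 6
  shifted_reg <- regimen("shifted", regs$DEX_ref$doses$time_h + shift,
                         regs$DEX_ref$doses$amount_mg, regs$DEX_ref$absorption)
  p1 <- simulate_regimen(regs$DEX_ref, pd, grid = seq(0, 48, 0.05))
  p2 <- simulate_regimen(shifted_reg, pd, grid = seq(shift, 48 + shift, 0.05))
  expect_equal(p2$mp_ng_ml, p1$mp_ng_ml, tolerance = 1e-8)
  expect_equal(p2$uv_ng_ml, p1$uv_ng_ml, tolerance = 1e-8)

  # mass balance well below 0.1% for every built-in regimen
  for (nm in names(regs)) {
    params <- if (attr(regs[[nm]], "drug") == "BET") pb else pd
    expect_lt(mass_balance_error(simulate_regimen(regs[[nm]], params)), 1e-3)
  }
  # and for infusion dosing
  expect_lt(mass_balance_error(
    simulate_regimen(infusion_regimen(24, 6), pb, tmax = 24)), 1e-3)
})

test_that("compiled and R right-hand sides produce the same solution", {
  pb <- acs_params("BET")
  reg <- builtin_regimens()$BET_ref
  grid <- seq(0, 48, 0.5)
  a <- simulate_regimen(reg, pb, grid = grid, engine = "compiled")
  b <- simulate_regimen(reg, pb, grid = grid, engine = "R")
  expect_equal(a$mp_ng_ml, b$mp_ng_ml, tolerance = 1e-7)
  expect_equal(a$uv_ng_ml, b$uv_ng_ml, tolerance = 1e-7)
})

test_that("simulation rejects grids that do not cover the dose times", {
  reg <- builtin_regimens()$BET_ref
  expect_error(simulate_regimen(reg, acs_params("BET"),
                                grid = seq(0, 12, 0.5)),
               "cover all dose times")
})
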