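test_that("AAFE matches hand-computed fold errors and is symmetric", {
  expect_equal(aafe(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(aafe(c(2, 4, 10), c(1, 2, 5)), 2)
  # fold errors do not cancel: (2,1) and (1,2) average to 2, not 1
  expect_equal(aafe(c(2, 1), c(1, 2)), 2)
  expect_equal(aafe(c(2, 1), c(1, 2)), aafe(c(1, 2), c(2, 1)))
  # a single 10-fold error among exact predictions
  expect_equal(aafe(c(1, 1, 10, 1), c(1, 1, 1, 1)), 10^(1 / 4))
  expect_error(aafe(c(1, 2), c(1, 0)), "positive")
  expect_error(aafe(1:3, 1:2), "equal length")
})

test_that("the Emax fit recovers known UV/MP ratio curves", {
  t <- seq(0.5, 24, length.out = 20)
  ratio <- 0.59 * t / (2 + t)
  mp <- 30 * exp(-0.1 * t)
  dy <- observed_dyads(sprintf("d%02d", 1:20), t, mp, mp * ratio)
  fit <- fit_emax_uvmp(dy)
  expect_equal(fit$plateau, 0.59, tolerance = 1e-3 / 0.59)
  expect_equal(fit$t50, 2, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)

  # flat ratio at late times: the plateau is the asymptote
  tl <- c(50, 80, 120, 200, 400)
  mpl <- rep(10, 5)
  fit2 <- fit_emax_uvmp(observed_dyads(letters[1:5], tl, mpl, mpl * 0.5))
  expect_equal(fit2$plateau, 0.5, tolerance = 0.02)

  # degenerate data: all times equal
  expect_error(fit_emax_uvmp(observed_dyads(letters[1:4], rep(3, 4),
                                            rep(10, 4), rep(5, 4))),
               "degenerate")
})

test_that("the Emax fit tolerates noise and ignores ordering and time units", {
  t <- withr::with_seed(11, runif(50, 1, 24))
  ratio_true <- 0.59 * t / (2 + t)
  noise <- withr::with_seed(12, rlnorm(50, 0, sqrt(log(1 + 0.2^2))))
  mp <- 25 * exp(-0.08 * t)
  dy <- observed_dyads(sprintf("d%02d", 1:50), t, mp, mp * ratio_true * noise)
  fit <- fit_emax_uvmp(dy)
  expect_equal(fit$plateau, 0.59, tolerance = 0.1)

  # ordering invariance
  perm <- withr::with_seed(13, sample(50))
  fit_p <- fit_emax_uvmp(dy[perm, ])
  expect_equal(fit_p$plateau, fit$plateau, tolerance = 1e-6)
  expect_equal(fit_p$t50, fit$t50, tolerance = 1e-6)

  # uniform time rescaling rescales t50 and leaves the plateau
  dy_min <- observed_dyads(dy$dyad_id, dy$time_post_dose_h * 60,
                           dy$mp_ng_ml, dy$uv_ng_ml)
  fit_min <- fit_emax_uvmp(dy_min)
  expect_equal(fit_min$plateau, fit$plateau, tolerance = 1e-5)
  expect_equal(fit_min$t50, fit$t50 * 60, tolerance = 1e-4)
})

test_that("the plateau translates to Kp,uu through the unbound-fraction ratio", {
  expect_equal(plateau_to_kpuu(0.6, 0.3, 0.3), 0.6)
  expect_equal(plateau_to_kpuu(0.59, 0.8136, 1), 0.48, tolerance = 1e-3)
  # the shipped default fu ratio realizes the same translation
  d <- drug_params("DEX", fu_maternal = 0.32, v_maternal = 75, v_fetal = 5)
  expect_equal(plateau_to_kpuu(0.59, d$fu_maternal, d$fu_fetal), 0.48,
               tolerance = 1e-3)
  # algebraic inverse
  k <- plateau_to_kpuu(0.59, 0.32, 0.3933)
  expect_equal(k / (0.32 / 0.3933), 0.59)
  expect_error(plateau_to_kpuu(0, 0.3, 0.3), "plateau")
})

test_that("Kp,uu calibration recovers the generating efflux on clean data", {
  reg <- builtin_regimens()$BET_ref
  params_true <- acs_params("BET", kpuu = 0.5)
  dy <- generate_dyads(30, reg, params_true, sampling_window = c(1, 24),
                       noise_cv = 0, seed = 5)
  cal <- calibrate_kpuu(dy, reg, params_true, n_boot = 100, seed = 99)
  expect_equal(cal$kpuu_hat, 0.5, tolerance = 0.01 / 0.5)
  expect_gte(cal$aafe, 1)
  expect_lt(cal$aafe, 1.01)
  expect_true(cal$ci_low <= cal$kpuu_hat && cal$kpuu_hat <= cal$ci_high)
  expect_equal(cal$cl_int_pgp_hat,
               clpgp_from_kpuu(cal$kpuu_hat, effective_pd_clearance(
                 1e6, params_true$physiology$q_placenta)))
  # noise-free objective is unimodal on the grid: one sign change of slope
  s <- sign(diff(cal$objective))
  expect_lte(sum(diff(s[s != 0]) != 0), 1)

  # no-efflux data drive the estimate to the top of the grid
  params_free <- acs_params("BET", kpuu = 0.999)
  dy2 <- generate_dyads(20, reg, params_free, noise_cv = 0, seed = 6)
  cal2 <- calibrate_kpuu(dy2, reg, params_free, n_boot = 50, seed = 7)
  expect_gte(cal2$kpuu_hat, 0.95)
})

test_that("calibration validates its inputs", {
  reg <- builtin_regimens()$BET_ref
  params <- acs_params("BET")
  dy <- generate_dyads(10, reg, params, noise_cv = 0, seed = 1)
  expect_error(calibrate_kpuu(dy[1:3, ], reg, params), "at least 5")
  expect_error(calibrate_kpuu(dy, reg, params, kpuu_grid = numeric(0)),
               "empty")
  expect_error(calibrate_kpuu(dy, reg, params, kpuu_grid = c(0.5, 0.3)),
               "sorted")
  expect_error(calibrate_kpuu(dy, reg, params, kpuu_grid = c(0.5, 1.2)),
               "kpuu_grid")
})
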