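test_that("constructors reject out-of-range values with informative messages", {
  expect_error(drug_params("X", fu_maternal = 1.5, v_maternal = 50, v_fetal = 5),
               "fu_maternal.*1\\.5.*1")
  expect_error(drug_params("X", fu_maternal = 0, v_maternal = 50, v_fetal = 5),
               "fu_maternal")
  expect_error(drug_params("X", fu_maternal = 0.3, v_maternal = 0, v_fetal = 5),
               "v_maternal")
  expect_error(drug_params("X", fu_maternal = 0.3, v_maternal = 50, v_fetal = 5,
                           cl_hep_int = -1), "cl_hep_int")
  expect_error(absorption_params("im", ka_fast = 0.2, ka_slow = 1.5),
               "ka_fast")
  expect_error(absorption_params("im", ka_fast = 0), "ka_fast")
  expect_error(absorption_params("im", t_lag = -0.5), "t_lag")
  expect_error(absorption_params("iv_infusion"), "infusion_duration")
  expect_error(placental_transfer(-1, 10), "cl_int_pd")
  expect_error(placental_transfer(45, -1), "cl_int_pgp")
  expect_error(maternal_physiology(30, q_hepatic = 0, q_placenta = 45),
               "q_hepatic")
  expect_error(maternal_physiology(30, 90, 45, cyp3a_induction_factor = 0.5),
               "cyp3a_induction_factor")
  expect_error(regimen("r", c(0, 0), 6, absorption_params("im")),
               "strictly increasing")
  expect_error(regimen("r", numeric(0), numeric(0), absorption_params("im")),
               "at least one dose")
  expect_error(regimen("r", c(-1, 12), 6, absorption_params("im")),
               "dose time")
  expect_error(observed_dyads("a", 0, 1, 1), "time_post_dose_h")
  expect_error(observed_dyads("a", 2, 0, 1), "quantification")
  expect_error(concentration_profile(c(0, 1), c(1, -1), c(0, 0)), ">= 0")
  expect_error(concentration_profile(c(1, 0), c(1, 1), c(0, 0)), "increasing")
  expect_error(population_spec(0), "n_subjects")
  expect_error(population_spec(10, cv_map = c(nonsense = 30)),
               "unknown key.*nonsense")
})

test_that("single-phase absorption is exactly the fraction_fast = 1 case", {
  a <- absorption_params("im", ka_fast = 2.85, ka_slow = 2.85, t_lag = 0.2)
  expect_identical(a$fraction_fast, 1)
  dual <- absorption_params("im", fraction_fast = 0.5, ka_fast = 1.5,
                            ka_slow = 0.2, t_lag = 1.5)
  expect_equal(dual$fraction_fast, 0.5)
})

test_that("fu_fetal defaults to fu_maternal / 0.8136", {
  d <- drug_params("DEX", fu_maternal = 0.32, v_maternal = 75, v_fetal = 5)
  expect_equal(d$fu_fetal, 0.32 / 0.8136)
  d2 <- drug_params("DEX", fu_maternal = 0.32, fu_fetal = 0.5,
                    v_maternal = 75, v_fetal = 5)
  expect_equal(d2$fu_fetal, 0.5)
})

test_that("a minimal DEX config validates and echoes its clearance", {
  raw <- list(
    drug = list(name = "DEX", fu_maternal = 0.32, v_maternal = 75,
                v_fetal = 5, cl_hep_int = 106),
    absorption = list(route = "im", ka_fast = 2.85, t_lag = 0.2),
    placental = list(cl_int_pd = 1e6, cl_int_pgp = 48.75),
    physiology = list(gestational_week = 38, q_hepatic = 97, q_placenta = 45,
                      cyp3a_induction_factor = 2)
  )
  conf <- validate_config(raw)
  expect_s3_class(conf$drug, "drug_params")
  expect_equal(conf$drug$cl_hep_int, 106)
  expect_equal(conf$physiology$cyp3a_induction_factor, 2)
  expect_s3_class(conf$params, "model_params")
})

test_that("validate_config rejects unknown and missing keys by name", {
  raw <- list(drug = list(name = "X", fu_maternal = 0.3, v_maternal = 50,
                          v_fetal = 5, typo_key = 1),
              absorption = list(route = "im", ka_fast = 1),
              placental = list(cl_int_pd = 45),
              physiology = list(gestational_week = 30, q_hepatic = 90,
                                q_placenta = 45))
  expect_error(validate_config(raw), "typo_key")
  raw$drug$typo_key <- NULL
  raw$physiology <- NULL
  expect_error(validate_config(raw), "physiology")
  raw2 <- list(bogus_section = list())
  expect_error(validate_config(raw2), "bogus_section")
})

test_that("config serialization round-trips losslessly", {
  params <- acs_params("BET", gw = 30)
  ab <- acs_absorption("BET")
  raw <- as_config_list(params)
  raw$absorption <- as_config_list(ab)
  conf <- validate_config(raw)
  expect_equal(conf$params, params)
  expect_equal(conf$absorption, ab)
  # and through an on-disk YAML file
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path, precision = 15)
  conf2 <- read_config(path)
  expect_equal(conf2$params, params)
})

test_that("shipped example configs load and mirror the presets", {
  for (f in c("bet_gw30.yaml", "dex_gw30.yaml")) {
    path <- system.file("extdata", f, package = "mfpbpk")
    conf <- read_config(path)
    expect_s3_class(conf$params, "model_params")
    drug <- conf$drug$name
    preset <- acs_params(drug, gw = 30)
    expect_equal(conf$drug$v_maternal, preset$drug$v_maternal)
    expect_equal(conf$drug$cl_hep_int, preset$drug$cl_hep_int)
    expect_equal(model_kpuu(conf$params), model_kpuu(preset), tolerance = 1e-3)
  }
})
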