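# Shared fixtures: a minimal synthetic drug with a direct clearance override
# (so closed-form one-compartment oracles apply) and i.v. regimens.

simple_params <- function(cl_total = 5, v_m = 50, v_f = 5,
                          fu_m = 0.4, fu_f = 0.4,
                          cl_int_pd = 1e6, cl_int_pgp = 0,
                          q_placenta = 45, cl_fetal = 0) {
  model_params(
    drug_params("TEST", fu_maternal = fu_m, fu_fetal = fu_f,
                v_maternal = v_m, v_fetal = v_f,
                cl_total_override = cl_total, cl_fetal = cl_fetal),
    placental_transfer(cl_int_pd, cl_int_pgp),
    maternal_physiology(30, q_hepatic = 90, q_placenta = q_placenta))
}

iv_regimen <- function(amount = 10, times = 0, label = "iv_test") {
  regimen(label, times, amount, absorption_params("iv_bolus"))
}

infusion_regimen <- function(amount, duration, label = "inf_test") {
  regimen(label, 0, amount,
          absorption_params("iv_infusion", infusion_duration = duration))
}

# unbound steady-state UV/MP ratio read from the end of a long constant
# infusion
steady_state_unbound_ratio <- function(params, hours = 400, dt = 0.5) {
  reg <- infusion_regimen(amount = 100 * hours, duration = hours)
  prof <- simulate_regimen(reg, params, grid = seq(0, hours, by = dt))
  i <- nrow(prof)
  (prof$uv_ng_ml[i] * params$drug$fu_fetal) /
    (prof$mp_ng_ml[i] * params$drug$fu_maternal)
}
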