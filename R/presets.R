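# Shipped parameter presets for dexamethasone (DEX) and betamethasone (BET).
#
# Printed kinetic constants (intrinsic hepatic clearances and their twofold
# CYP3A induction by pregnancy, i.m. absorption rate constants and lag
# times, placental flow limitation, Kp,uu values) come from the source
# clinical analyses; quantities those analyses do not print (unbound
# fractions, central volumes, hepatic blood flow, fetal volume) are declared
# approximations with typical literature magnitudes, and every one is
# overridable through the config interface. See the methods vignette.

.ACS_PRESETS <- list(
  DEX = list(
    fu_maternal = 0.32,          # weak plasma protein binding of DEX
    v_maternal = 75,             # ~1.0 L/kg x 75 kg
    v_fetal = 5,
    cl_hep_int_nonpreg = 53,     # doubled by pregnancy CYP3A induction -> 106
    kpuu = 0.48
  ),
  BET = list(
    fu_maternal = 0.36,
    v_maternal = 95,             # ~1.25 L/kg x 76 kg
    v_fetal = 5,
    cl_hep_int_nonpreg = 31,     # doubled by pregnancy -> 62 (i.v.)
    cl_hep_int_preg_im = c(caption = 22, text = 11.2),
    kpuu = 0.5
  )
)

.Q_HEPATIC_PREGNANT <- 97      # L/h, third trimester
.Q_HEPATIC_NONPREGNANT <- 87   # L/h
.Q_PLACENTA <- 45              # L/h, third trimester (flow-limiting)
.CL_INT_PD_LARGE <- 1e6        # L/h; passive diffusion is flow-limited

#' Preset absorption models
#'
#' Intramuscular absorption presets: DEX phosphate is released in a single
#' fast phase; the BET phosphate:acetate 1:1 mixture is released in two
#' phases (half the dose fast from the phosphate, half slow from the
#' acetate).
#'
#' @param drug `"DEX"` or `"BET"`.
#' @param variant absorption variant. For DEX, `"default"` (ka = 2.85/h,
#'   t_lag = 0.2 h) or `"fig"` (ka = 3/h, t_lag = 0.3 h) - two published
#'   optimizations of the same data. For BET, `"default"` (dual-phase,
#'   ka1 = 1.5/h, ka2 = 0.2/h, t_lag = 1.5 h) or `"phosphate"`
#'   (single-phase fast, for BET-P without the acetate ester, as in the WHO
#'   2 mg q12h regimen).
#' @return an [absorption_params()] object.
#' @export
acs_absorption <- function(drug = c("DEX", "BET"),
                           variant = c("default", "fig", "phosphate")) {
  drug <- match.arg(drug)
  variant <- match.arg(variant)
  if (drug == "DEX") {
    if (variant == "fig") {
      absorption_params("im", fraction_fast = 1, ka_fast = 3, ka_slow = 3,
                        t_lag = 0.3)
    } else {
      absorption_params("im", fraction_fast = 1, ka_fast = 2.85,
                        ka_slow = 2.85, t_lag = 0.2)
    }
  } else {
    if (variant == "phosphate") {
      absorption_params("im", fraction_fast = 1, ka_fast = 1.5, ka_slow = 1.5,
                        t_lag = 1.5)
    } else {
      absorption_params("im", fraction_fast = 0.5, ka_fast = 1.5,
                        ka_slow = 0.2, t_lag = 1.5)
    }
  }
}

#' Preset model parameters for the antenatal corticosteroids
#'
#' Returns a full [model_params()] bundle for DEX or BET at a given
#' gestational-week scenario. `gw` is a scenario label (30, 32 or 38); all
#' presets are third-trimester and share the same physiology (placental
#' blood flow 45 L/h; simulations span at most 72 h so no continuous
#' gestational-age functions are used).
#'
#' Scenarios:
#' * `"pregnant_im"` (default): the calibrated maternal model used for
#'   regimen design. For BET this uses the pregnancy i.m. hepatic intrinsic
#'   clearance re-estimated from maternal delivery data
#'   (`bet_clhep = "caption"`: 22 L/h; `"text"`: 11.2 L/h - two printed
#'   values of the same fit, shipped as alternatives).
#' * `"pregnant_iv"`: twofold CYP3A-induced intrinsic clearance
#'   (DEX 53 -> 106 L/h; BET 31 -> 62 L/h effective).
#' * `"nonpregnant"`: no induction, non-pregnant hepatic blood flow.
#'
#' @param drug `"DEX"` or `"BET"`.
#' @param gw gestational-week scenario label: 30, 32 or 38.
#' @param scenario see above.
#' @param kpuu unbound fetal:maternal partition coefficient used to set the
#'   placental efflux clearance; defaults to 0.48 (DEX) / 0.5 (BET).
#' @param bet_clhep which printed pregnancy i.m. BET intrinsic clearance to
#'   use (`"caption"` = 22 L/h, default; `"text"` = 11.2 L/h).
#' @return a [model_params()] object.
#' @export
acs_params <- function(drug = c("DEX", "BET"), gw = 30,
                       scenario = c("pregnant_im", "pregnant_iv", "nonpregnant"),
                       kpuu = NULL, bet_clhep = c("caption", "text")) {
  drug <- match.arg(drug)
  scenario <- match.arg(scenario)
  bet_clhep <- match.arg(bet_clhep)
  if (!gw %in% c(30, 32, 38)) {
    stop("field 'gw' must be one of the shipped scenario labels 30, 32, 38",
         call. = FALSE)
  }
  p <- .ACS_PRESETS[[drug]]
  if (is.null(kpuu)) kpuu <- p$kpuu

  pregnant <- scenario != "nonpregnant"
  if (drug == "BET" && scenario == "pregnant_im") {
    cl_hep_int <- p$cl_hep_int_preg_im[[bet_clhep]]
    induction <- 1   # directly re-estimated pregnancy value
  } else {
    cl_hep_int <- p$cl_hep_int_nonpreg
    induction <- if (pregnant) 2 else 1
  }
  phys <- maternal_physiology(
    gestational_week = if (pregnant) gw else 0,
    q_hepatic = if (pregnant) .Q_HEPATIC_PREGNANT else .Q_HEPATIC_NONPREGNANT,
    q_placenta = .Q_PLACENTA,
    cyp3a_induction_factor = induction
  )
  drugp <- drug_params(
    name = drug,
    fu_maternal = p$fu_maternal,
    v_maternal = p$v_maternal,
    v_fetal = p$v_fetal,
    cl_hep_int = cl_hep_int
  )
  clpd_eff <- effective_pd_clearance(.CL_INT_PD_LARGE, phys$q_placenta)
  plac <- placental_transfer(
    cl_int_pd = .CL_INT_PD_LARGE,
    cl_int_pgp = clpgp_from_kpuu(kpuu, clpd_eff)
  )
  model_params(drugp, plac, phys)
}
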