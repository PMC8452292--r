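# The reduced maternal-fetal PBPK engine.
#
# Four kinetic states (plus two cumulative-elimination bookkeeping states):
#   depot_fast, depot_slow  - i.m. depot amounts (mg)
#   a_maternal, a_fetal     - amounts in the maternal / fetal central
#                             compartments (mg)
# The placenta carries no stored amount: passive transfer is a
# perfusion-limited conduit (series combination of placental blood flow and
# the intrinsic passive-diffusion clearance) acting on unbound drug, and
# P-gp efflux is an additional fetal-to-maternal clearance on unbound fetal
# drug. At steady state this reproduces
#   fu_f C_f / (fu_m C_m) = CLpd_eff / (CLpd_eff + CL_int_Pgp),
# the unbound partition coefficient Kp,uu.

#' Kp,uu from placental clearances
#'
#' The steady-state unbound fetal:maternal partition coefficient implied by
#' the placental passive-diffusion and P-gp efflux clearances:
#' `Kp,uu = CL_pd / (CL_pd + CL_pgp)`.
#'
#' @param cl_int_pd passive-diffusion clearance (L/h), > 0.
#' @param cl_int_pgp P-gp efflux clearance (L/h), >= 0.
#' @return Kp,uu in (0, 1].
#' @examples
#' kpuu_from_clearances(45, 45)   # equal clearances -> 0.5
#' kpuu_from_clearances(45, 0)    # no efflux -> 1
#' @export
kpuu_from_clearances <- function(cl_int_pd, cl_int_pgp) {
  cl_int_pd <- .check_range(cl_int_pd, "cl_int_pd", 0, lower_open = TRUE)
  cl_int_pgp <- .check_range(cl_int_pgp, "cl_int_pgp", 0)
  cl_int_pd / (cl_int_pd + cl_int_pgp)
}

#' Efflux clearance implied by a Kp,uu
#'
#' Inverse of [kpuu_from_clearances()]: the P-gp efflux clearance that,
#' together with a given passive-diffusion clearance, yields the stated
#' Kp,uu.
#'
#' @param kpuu unbound partition coefficient, in (0, 1].
#' @param cl_int_pd passive-diffusion clearance (L/h), > 0.
#' @return efflux clearance (L/h), >= 0.
#' @examples
#' clpgp_from_kpuu(0.5, 45)   # 45
#' clpgp_from_kpuu(1.0, 45)   # 0: no efflux needed
#' @export
clpgp_from_kpuu <- function(kpuu, cl_int_pd) {
  kpuu <- .check_range(kpuu, "kpuu", 0, 1, lower_open = TRUE)
  cl_int_pd <- .check_range(cl_int_pd, "cl_int_pd", 0, lower_open = TRUE)
  cl_int_pd * (1 - kpuu) / kpuu
}

#' Well-stirred hepatic clearance
#'
#' Systemic hepatic clearance from intrinsic clearance via the well-stirred
#' liver model, `Q fu CLint' / (Q + fu CLint')`, where
#' `CLint' = induction_factor * cl_hep_int` accounts for the roughly twofold
#' induction of CYP3A activity by pregnancy at term.
#'
#' @param cl_hep_int hepatic intrinsic clearance (L/h), > 0.
#' @param fu_maternal unbound fraction in maternal plasma, > 0.
#' @param q_hepatic hepatic blood flow (L/h), > 0.
#' @param induction_factor multiplier on `cl_hep_int`, > 0.
#' @return systemic hepatic clearance (L/h), strictly less than `q_hepatic`.
#' @export
hepatic_clearance <- function(cl_hep_int, fu_maternal, q_hepatic,
                              induction_factor = 1) {
  cl_hep_int <- .check_range(cl_hep_int, "cl_hep_int", 0, lower_open = TRUE)
  fu_maternal <- .check_range(fu_maternal, "fu_maternal", 0, lower_open = TRUE)
  q_hepatic <- .check_range(q_hepatic, "q_hepatic", 0, lower_open = TRUE)
  induction_factor <- .check_range(induction_factor, "induction_factor", 0,
                                   lower_open = TRUE)
  fucl <- fu_maternal * induction_factor * cl_hep_int
  q_hepatic * fucl / (q_hepatic + fucl)
}

#' Perfusion-limited passive placental clearance
#'
#' Effective transplacental passive clearance as the series combination of
#' placental blood flow and the intrinsic passive-diffusion clearance,
#' `Q CL / (Q + CL)`. When the intrinsic clearance is large the effective
#' clearance approaches the placental blood flow (about 45 L/h in the third
#' trimester), i.e. transfer is flow-limited.
#'
#' @param cl_int_pd intrinsic passive-diffusion clearance (L/h), > 0.
#' @param q_placenta placental blood flow (L/h), > 0.
#' @return effective clearance (L/h), `<= min(q_placenta, cl_int_pd)`.
#' @export
effective_pd_clearance <- function(cl_int_pd, q_placenta) {
  cl_int_pd <- .check_range(cl_int_pd, "cl_int_pd", 0, lower_open = TRUE)
  q_placenta <- .check_range(q_placenta, "q_placenta", 0, lower_open = TRUE)
  q_placenta * cl_int_pd / (q_placenta + cl_int_pd)
}

#' Model-level (perfusion-limited) Kp,uu
#'
#' The steady-state unbound fetal:maternal partition coefficient the
#' simulator realizes: [kpuu_from_clearances()] evaluated with the
#' perfusion-limited effective passive clearance in place of the intrinsic
#' one. When the intrinsic passive clearance is far above placental blood
#' flow (the flow-limited regime), the effective passive clearance is
#' essentially the placental flow (~45 L/h).
#'
#' @param params a [model_params()] bundle.
#' @return Kp,uu in (0, 1], or `NA` when transplacental transfer is shut
#'   off (`cl_int_pd = 0`).
#' @export
model_kpuu <- function(params) {
  if (params$placental$cl_int_pd <= 0) return(NA_real_)
  kpuu_from_clearances(
    effective_pd_clearance(params$placental$cl_int_pd,
                           params$physiology$q_placenta),
    params$placental$cl_int_pgp)
}

#' Model state vector
#'
#' @param depot_fast,depot_slow i.m. depot amounts (mg).
#' @param a_maternal,a_fetal central-compartment amounts (mg).
#' @return named numeric vector (with zero cumulative-elimination slots).
#' @export
state_vector <- function(depot_fast = 0, depot_slow = 0,
                         a_maternal = 0, a_fetal = 0) {
  c(depot_fast = depot_fast, depot_slow = depot_slow,
    a_maternal = a_maternal, a_fetal = a_fetal,
    elim_maternal = 0, elim_fetal = 0)
}

# resolve the per-segment parameter vector the RHS consumes
.engine_parms <- function(absorption, params, in_rate = 0) {
  drug <- params$drug
  phys <- params$physiology
  cl_total <- if (!is.null(drug$cl_total_override)) {
    drug$cl_total_override
  } else {
    hep <- if (drug$cl_hep_int > 0) {
      hepatic_clearance(drug$cl_hep_int, drug$fu_maternal, phys$q_hepatic,
                        phys$cyp3a_induction_factor)
    } else 0
    hep + drug$cl_renal
  }
  c(ka_fast = absorption$ka_fast,
    ka_slow = absorption$ka_slow,
    cl_total = cl_total,
    clpd_eff = if (params$placental$cl_int_pd > 0) {
      effective_pd_clearance(params$placental$cl_int_pd, phys$q_placenta)
    } else 0,
    cl_pgp = params$placental$cl_int_pgp,
    fu_m = drug$fu_maternal,
    fu_f = drug$fu_fetal,
    v_m = drug$v_maternal,
    v_f = drug$v_fetal,
    cl_fetal = drug$cl_fetal,
    in_rate = in_rate)
}

#' Model right-hand side (reference implementation)
#'
#' The derivative of the state vector; the readable R mirror of the compiled
#' routine used by [simulate_regimen()]. Depot states feed the maternal
#' central compartment by first-order absorption; dose lag is realized by
#' filling the depots `t_lag` after each dose, so the depot equations hold
#' unconditionally.
#'
#' @param state named state vector, see [state_vector()].
#' @param t time (h); unused (the system is autonomous within a dosing
#'   segment) but kept for the standard signature.
#' @param params a [model_params()] bundle.
#' @param absorption an [absorption_params()] object (supplies ka's).
#' @param in_rate zero-order maternal input rate (mg/h), for infusions.
#' @return named derivative vector (mg/h).
#' @export
pbpk_rhs <- function(state, t, params, absorption, in_rate = 0) {
  p <- .engine_parms(absorption, params, in_rate)
  abs_fast <- p[["ka_fast"]] * state[["depot_fast"]]
  abs_slow <- p[["ka_slow"]] * state[["depot_slow"]]
  cm <- state[["a_maternal"]] / p[["v_m"]]
  cf <- state[["a_fetal"]] / p[["v_f"]]
  mat_to_fet <- p[["clpd_eff"]] * p[["fu_m"]] * cm
  fet_to_mat <- (p[["clpd_eff"]] + p[["cl_pgp"]]) * p[["fu_f"]] * cf
  c(depot_fast = -abs_fast,
    depot_slow = -abs_slow,
    a_maternal = abs_fast + abs_slow + p[["in_rate"]] -
      p[["cl_total"]] * cm - mat_to_fet + fet_to_mat,
    a_fetal = mat_to_fet - fet_to_mat - p[["cl_fetal"]] * cf,
    elim_maternal = p[["cl_total"]] * cm,
    elim_fetal = p[["cl_fetal"]] * cf)
}

# dose bookkeeping: instantaneous state increments and infusion intervals
.dose_schedule <- function(reg) {
  ab <- reg$absorption
  d <- reg$doses
  amt <- d$amount_mg * ab$bioavailability
  events <- data.frame(time = numeric(0), depot_fast = numeric(0),
                       depot_slow = numeric(0), a_maternal = numeric(0))
  infusions <- data.frame(start = numeric(0), end = numeric(0),
                          rate = numeric(0))
  if (ab$route == "im") {
    events <- data.frame(time = d$time_h + ab$t_lag,
                         depot_fast = amt * ab$fraction_fast,
                         depot_slow = amt * (1 - ab$fraction_fast),
                         a_maternal = 0)
  } else if (ab$route == "iv_bolus") {
    events <- data.frame(time = d$time_h, depot_fast = 0, depot_slow = 0,
                         a_maternal = amt)
  } else {
    infusions <- data.frame(start = d$time_h,
                            end = d$time_h + ab$infusion_duration,
                            rate = amt / ab$infusion_duration)
  }
  list(events = events, infusions = infusions)
}

#' Simulate a dosing regimen
#'
#' Integrates the reduced maternal-fetal model over an output grid with a
#' stiff-capable solver ([deSolve::lsoda()]). Doses enter as depot (i.m.),
#' maternal bolus (i.v.) or zero-order infusion inputs; integration is
#' segmented at dose/infusion boundaries so each event is applied exactly.
#'
#' @param reg a [regimen()].
#' @param params a [model_params()] bundle.
#' @param grid output time grid (h); defaults to `seq(0, tmax, by = dt)`.
#'   Must span all dose times.
#' @param tmax,dt grid end (h) and step (h) used when `grid` is `NULL`.
#'   `tmax` defaults to 48 h or the last dose time + 12 h, whichever is
#'   larger.
#' @param rtol,atol solver relative/absolute tolerances (mg).
#' @param engine `"compiled"` (C right-hand side, default) or `"R"`
#'   (reference implementation; identical results, slower).
#' @return a [concentration_profile()] (ng/ml) with attributes `states`
#'   (state matrix, mg, at grid times) and `input_cum` (cumulative
#'   bioavailable input, mg). See [mass_balance_error()].
#' @export
simulate_regimen <- function(reg, params, grid = NULL, tmax = NULL, dt = 0.05,
                             rtol = 1e-8, atol = 1e-12,
                             engine = c("compiled", "R")) {
  stopifnot(inherits(reg, "regimen"), inherits(params, "model_params"))
  engine <- match.arg(engine)
  if (is.null(grid)) {
    if (is.null(tmax)) tmax <- max(48, max(reg$doses$time_h) + 12)
    grid <- seq(0, tmax, by = dt)
  }
  grid <- as.numeric(grid)
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    stop("grid must be a strictly increasing vector of at least 2 times",
         call. = FALSE)
  }
  eps <- 1e-9
  if (min(reg$doses$time_h) < grid[1] - eps ||
      max(reg$doses$time_h) > grid[length(grid)] + eps) {
    stop("output grid must cover all dose times", call. = FALSE)
  }
  sched <- .dose_schedule(reg)
  ev <- sched$events
  inf <- sched$infusions
  tend <- grid[length(grid)]
  bounds <- c(grid[1], ev$time, inf$start, inf$end, tend)
  bounds <- sort(unique(round(bounds, 9)))
  bounds <- bounds[bounds >= grid[1] - eps & bounds <= tend + eps]

  base_parms <- .engine_parms(reg$absorption, params)
  state <- state_vector()
  res <- matrix(NA_real_, length(grid), 6,
                dimnames = list(NULL, names(state)))
  solver_call <- function(times, parms) {
    out <- tryCatch({
      if (engine == "compiled") {
        deSolve::lsoda(y = state, times = times, func = "pbpk_derivs",
                       parms = parms, dllname = "mfpbpk",
                       initfunc = "pbpk_init", rtol = rtol, atol = atol)
      } else {
        deSolve::lsoda(y = state, times = times,
                       func = function(t, y, p) {
                         names(y) <- names(state)
                         list(unname(pbpk_rhs(y, t, params, reg$absorption,
                                              in_rate = p[["in_rate"]])))
                       },
                       parms = parms, rtol = rtol, atol = atol)
      }
    }, error = function(e) {
      stop(sprintf(
        "ODE solver failed for regimen '%s' (drug %s, CL_total %.4g, Kp,uu %.4g): %s",
        reg$label, params$drug$name, parms[["cl_total"]],
        model_kpuu(params), conditionMessage(e)), call. = FALSE)
    })
    if (any(!is.finite(out[, -1]))) {
      stop(sprintf("ODE solver returned non-finite values for regimen '%s'",
                   reg$label), call. = FALSE)
    }
    out
  }

  for (i in seq_along(bounds)) {
    t0 <- bounds[i]
    hit <- which(abs(ev$time - t0) < eps)
    if (length(hit)) {
      state[1] <- state[1] + sum(ev$depot_fast[hit])
      state[2] <- state[2] + sum(ev$depot_slow[hit])
      state[3] <- state[3] + sum(ev$a_maternal[hit])
    }
    gi <- which(abs(grid - t0) < eps)
    if (length(gi)) res[gi, ] <- state
    if (i == length(bounds)) break
    t1 <- bounds[i + 1]
    inner <- which(grid > t0 + eps & grid < t1 - eps)
    times <- c(t0, grid[inner], t1)
    rate <- if (nrow(inf)) {
      sum(inf$rate[inf$start <= t0 + eps & inf$end >= t1 - eps])
    } else 0
    parms <- base_parms
    parms[["in_rate"]] <- rate
    sol <- solver_call(times, parms)
    if (length(inner)) res[inner, ] <- sol[1 + seq_along(inner), -1]
    state <- sol[nrow(sol), -1]
  }

  # cumulative bioavailable input at each grid time (bolus/depot + infusion)
  input_cum <- numeric(length(grid))
  for (j in seq_len(nrow(ev))) {
    amt <- ev$depot_fast[j] + ev$depot_slow[j] + ev$a_maternal[j]
    input_cum <- input_cum + amt * (grid >= ev$time[j] - eps)
  }
  for (j in seq_len(nrow(inf))) {
    input_cum <- input_cum +
      inf$rate[j] * pmax(0, pmin(grid, inf$end[j]) - inf$start[j])
  }

  mp <- pmax(0, res[, "a_maternal"]) / params$drug$v_maternal
  uv <- pmax(0, res[, "a_fetal"]) / params$drug$v_fetal
  # mg/L -> ng/ml: 1 mg = 1e6 ng, 1 L = 1e3 ml
  prof <- concentration_profile(grid, mp * 1e6 / 1e3, uv * 1e6 / 1e3)
  attr(prof, "states") <- res
  attr(prof, "input_cum") <- input_cum
  attr(prof, "regimen_label") <- reg$label
  prof
}

#' Mass-balance error of a simulated profile
#'
#' Maximum over the output grid of the absolute difference between the
#' cumulative bioavailable input and the sum of all compartment amounts plus
#' cumulative elimination, relative to the total administered input.
#'
#' @param profile a profile returned by [simulate_regimen()].
#' @return maximum relative mass-balance error (dimensionless).
#' @export
mass_balance_error <- function(profile) {
  states <- attr(profile, "states")
  input_cum <- attr(profile, "input_cum")
  if (is.null(states) || is.null(input_cum)) {
    stop("profile carries no mass-balance bookkeeping (not from simulate_regimen?)",
         call. = FALSE)
  }
  total <- rowSums(states)
  denom <- max(input_cum, .Machine$double.eps)
  max(abs(total - input_cum)) / denom
}
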