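# Domain types and validation. Every quantity is carried in fixed units:
# clearances and flows L/h, volumes L, times h, doses mg, concentrations ng/ml.

# default unbound-fraction ratio fu_maternal/fu_fetal; chosen so that a
# total-concentration UV/MP plateau of 0.59 maps to Kp,uu = 0.48
.FU_RATIO_DEFAULT <- 0.8136

.check_scalar <- function(x, field) {
  if (is.null(x) || length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop(sprintf("field '%s' must be a single numeric value (got: %s)",
                 field, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  as.numeric(x)
}

.check_range <- function(x, field, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  x <- .check_scalar(x, field)
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("field '%s' = %g is outside %s%g, %g%s",
                 field, x,
                 if (lower_open) "(" else "[", lower, upper,
                 if (upper_open) ")" else "]"),
         call. = FALSE)
  }
  x
}

.check_known_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown key%s in %s: %s",
                 if (length(extra) > 1) "s" else "", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Drug-specific kinetic parameters
#'
#' Bundles the drug-dependent constants of the maternal-fetal model: plasma
#' unbound fractions, hepatic intrinsic clearance (fed through the
#' well-stirred liver model), optional renal clearance, an optional direct
#' systemic clearance override, and the maternal/fetal central volumes of
#' distribution.
#'
#' @param name drug label, e.g. `"DEX"` or `"BET"`.
#' @param fu_maternal unbound fraction in maternal plasma, in (0, 1].
#' @param v_maternal maternal central volume of distribution (L), > 0.
#' @param v_fetal fetal central volume (L), > 0.
#' @param fu_fetal unbound fraction in fetal plasma, in (0, 1]. Defaults to
#'   `fu_maternal / 0.8136` (see [plateau_to_kpuu()] for where this ratio
#'   comes from).
#' @param cl_hep_int hepatic intrinsic clearance (L/h), >= 0.
#' @param cl_renal renal clearance (L/h), >= 0.
#' @param cl_total_override optional direct systemic clearance (L/h). When
#'   set it takes precedence over the well-stirred (`cl_hep_int`, `cl_renal`)
#'   route.
#' @param cl_fetal fetal elimination clearance (L/h), >= 0.
#' @return an object of class `drug_params`.
#' @seealso [maternal_physiology()], [placental_transfer()], [acs_params()]
#' @export
drug_params <- function(name, fu_maternal, v_maternal, v_fetal,
                        fu_fetal = NULL, cl_hep_int = 0, cl_renal = 0,
                        cl_total_override = NULL, cl_fetal = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  fu_maternal <- .check_range(fu_maternal, "fu_maternal", 0, 1, lower_open = TRUE)
  if (is.null(fu_fetal)) fu_fetal <- fu_maternal / .FU_RATIO_DEFAULT
  fu_fetal <- .check_range(fu_fetal, "fu_fetal", 0, 1, lower_open = TRUE)
  obj <- structure(list(
    name = name,
    fu_maternal = fu_maternal,
    fu_fetal = fu_fetal,
    cl_hep_int = .check_range(cl_hep_int, "cl_hep_int", 0),
    cl_renal = .check_range(cl_renal, "cl_renal", 0),
    cl_total_override = if (is.null(cl_total_override)) NULL else
      .check_range(cl_total_override, "cl_total_override", 0),
    v_maternal = .check_range(v_maternal, "v_maternal", 0, lower_open = TRUE),
    v_fetal = .check_range(v_fetal, "v_fetal", 0, lower_open = TRUE),
    cl_fetal = .check_range(cl_fetal, "cl_fetal", 0)
  ), class = "drug_params")
  obj
}

#' Absorption / dose-input parameters
#'
#' Describes how each dose of a regimen enters the maternal circulation.
#' Intramuscular dosing uses a dual first-order depot: a fraction
#' `fraction_fast` of the (bioavailable) dose is released at `ka_fast`
#' and the remainder at `ka_slow`, both after a common lag `t_lag`.
#' Single-phase absorption is the special case `fraction_fast = 1`.
#'
#' @param route one of `"im"`, `"iv_bolus"`, `"iv_infusion"`.
#' @param fraction_fast fraction of the dose entering the fast depot (0-1).
#' @param ka_fast,ka_slow first-order absorption rate constants (1/h);
#'   `ka_fast >= ka_slow > 0`.
#' @param t_lag absorption lag time (h), >= 0. Ignored for intravenous routes.
#' @param bioavailability absorbed fraction of the dose (0-1].
#' @param infusion_duration infusion duration (h) per dose; required when
#'   `route = "iv_infusion"`, ignored otherwise.
#' @return an object of class `absorption_params`.
#' @export
absorption_params <- function(route = c("im", "iv_bolus", "iv_infusion"),
                              fraction_fast = 1, ka_fast = 1, ka_slow = ka_fast,
                              t_lag = 0, bioavailability = 1,
                              infusion_duration = NULL) {
  route <- match.arg(route)
  fraction_fast <- .check_range(fraction_fast, "fraction_fast", 0, 1)
  ka_fast <- .check_range(ka_fast, "ka_fast", 0, lower_open = TRUE)
  ka_slow <- .check_range(ka_slow, "ka_slow", 0, lower_open = TRUE)
  if (ka_fast < ka_slow) {
    stop(sprintf("field 'ka_fast' = %g must be >= ka_slow = %g", ka_fast, ka_slow),
         call. = FALSE)
  }
  if (fraction_fast < 1 && identical(ka_fast, ka_slow)) {
    # dual-phase with identical rates collapses to single-phase; normalize
    fraction_fast <- 1
  }
  if (route == "iv_infusion") {
    infusion_duration <- .check_range(infusion_duration, "infusion_duration",
                                      0, lower_open = TRUE)
  } else {
    infusion_duration <- NULL
  }
  structure(list(
    route = route,
    fraction_fast = fraction_fast,
    ka_fast = ka_fast,
    ka_slow = ka_slow,
    t_lag = .check_range(t_lag, "t_lag", 0),
    bioavailability = .check_range(bioavailability, "bioavailability", 0, 1,
                                   lower_open = TRUE),
    infusion_duration = infusion_duration
  ), class = "absorption_params")
}

#' Placental transfer clearances
#'
#' Intrinsic placental clearances acting on unbound drug: bidirectional
#' passive diffusion (`cl_int_pd`) and unidirectional fetal-to-maternal
#' P-glycoprotein efflux (`cl_int_pgp`). Their ratio fixes the steady-state
#' unbound fetal:maternal partition coefficient, see [kpuu_from_clearances()].
#'
#' @param cl_int_pd intrinsic passive-diffusion clearance (L/h), >= 0
#'   (0 shuts off transplacental transfer entirely).
#' @param cl_int_pgp intrinsic P-gp efflux clearance (L/h), >= 0.
#' @return an object of class `placental_transfer` with a derived `kpuu`
#'   element (intrinsic-scale partition coefficient; `NA` when
#'   `cl_int_pd = 0`).
#' @export
placental_transfer <- function(cl_int_pd, cl_int_pgp = 0) {
  cl_int_pd <- .check_range(cl_int_pd, "cl_int_pd", 0)
  cl_int_pgp <- .check_range(cl_int_pgp, "cl_int_pgp", 0)
  structure(list(
    cl_int_pd = cl_int_pd,
    cl_int_pgp = cl_int_pgp,
    kpuu = if (cl_int_pd > 0) kpuu_from_clearances(cl_int_pd, cl_int_pgp)
           else NA_real_
  ), class = "placental_transfer")
}

#' Maternal physiology scenario
#'
#' The small set of physiological quantities the reduced model consumes.
#' `gestational_week` is a scenario label selecting a preset (all simulations
#' span at most 72 h, so no continuous gestational-age functions are used).
#' `cyp3a_induction_factor` multiplies the hepatic intrinsic clearance
#' (pregnancy induces CYP3A about twofold at term; 1 for non-pregnant).
#'
#' @param gestational_week gestational week label (e.g. 30).
#' @param q_hepatic hepatic blood flow (L/h), > 0.
#' @param q_placenta placental blood flow (L/h), > 0 (about 45 L/h in the
#'   third trimester).
#' @param cyp3a_induction_factor multiplier on `cl_hep_int`, >= 1.
#' @return an object of class `maternal_physiology`.
#' @export
maternal_physiology <- function(gestational_week, q_hepatic, q_placenta,
                                cyp3a_induction_factor = 1) {
  structure(list(
    gestational_week = .check_range(gestational_week, "gestational_week", 0),
    q_hepatic = .check_range(q_hepatic, "q_hepatic", 0, lower_open = TRUE),
    q_placenta = .check_range(q_placenta, "q_placenta", 0, lower_open = TRUE),
    cyp3a_induction_factor = .check_range(cyp3a_induction_factor,
                                          "cyp3a_induction_factor", 1)
  ), class = "maternal_physiology")
}

#' Dosing regimen
#'
#' An ordered schedule of doses plus the absorption model they share.
#'
#' @param label regimen name.
#' @param times dose times (h since simulation start), strictly increasing,
#'   >= 0.
#' @param amounts dose amounts (mg of the administered ester product), >= 0,
#'   recycled to `length(times)`.
#' @param absorption an [absorption_params()] object.
#' @return an object of class `regimen`; `$doses` is a data frame with
#'   columns `time_h` and `amount_mg`.
#' @export
regimen <- function(label, times, amounts, absorption) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(absorption, "absorption_params"))
  times <- vapply(seq_along(times), function(i)
    .check_range(times[i], sprintf("dose time [%d]", i), 0), numeric(1))
  if (length(times) < 1L) stop("a regimen needs at least one dose", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("dose times must be strictly increasing", call. = FALSE)
  }
  amounts <- rep_len(as.numeric(amounts), length(times))
  for (i in seq_along(amounts)) {
    .check_range(amounts[i], sprintf("dose amount [%d]", i), 0)
  }
  structure(list(
    label = label,
    doses = data.frame(time_h = times, amount_mg = amounts),
    absorption = absorption
  ), class = "regimen")
}

#' Bundle the model parameters for one drug/scenario
#'
#' @param drug a [drug_params()] object.
#' @param placental a [placental_transfer()] object.
#' @param physiology a [maternal_physiology()] object.
#' @return an object of class `model_params`.
#' @export
model_params <- function(drug, placental, physiology) {
  stopifnot(inherits(drug, "drug_params"),
            inherits(placental, "placental_transfer"),
            inherits(physiology, "maternal_physiology"))
  structure(list(drug = drug, placental = placental, physiology = physiology),
            class = "model_params")
}

#' Concentration-time profile
#'
#' @param times time grid (h), strictly increasing.
#' @param mp_conc maternal plasma concentrations (ng/ml), >= 0.
#' @param uv_conc fetal (umbilical-vein) plasma concentrations (ng/ml), >= 0.
#' @return a data frame of class `concentration_profile` with columns
#'   `time_h`, `mp_ng_ml`, `uv_ng_ml`.
#' @export
concentration_profile <- function(times, mp_conc, uv_conc) {
  n <- length(times)
  if (length(mp_conc) != n || length(uv_conc) != n) {
    stop("times, mp_conc and uv_conc must have equal length", call. = FALSE)
  }
  if (n > 1 && any(diff(times) <= 0)) {
    stop("profile times must be strictly increasing", call. = FALSE)
  }
  if (any(mp_conc < 0) || any(uv_conc < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  structure(data.frame(time_h = as.numeric(times),
                       mp_ng_ml = as.numeric(mp_conc),
                       uv_ng_ml = as.numeric(uv_conc)),
            class = c("concentration_profile", "data.frame"))
}

#' Paired maternal/umbilical observations (dyads)
#'
#' One maternal-fetal dyad contributes a single paired maternal-plasma /
#' umbilical-vein sample at a known time after the first dose. Records with
#' concentrations at or below the quantification limit are expected to be
#' excluded upstream; zero or negative values are rejected here.
#'
#' @param dyad_id subject labels.
#' @param time_post_dose_h sampling times (h after first dose), > 0.
#' @param mp_ng_ml,uv_ng_ml maternal and umbilical-vein plasma
#'   concentrations (ng/ml), > 0.
#' @return a data frame of class `observed_dyads`.
#' @export
observed_dyads <- function(dyad_id, time_post_dose_h, mp_ng_ml, uv_ng_ml) {
  n <- length(dyad_id)
  if (length(time_post_dose_h) != n || length(mp_ng_ml) != n ||
      length(uv_ng_ml) != n) {
    stop("all dyad columns must have equal length", call. = FALSE)
  }
  if (any(time_post_dose_h <= 0)) {
    stop("field 'time_post_dose_h' must be > 0 for every dyad", call. = FALSE)
  }
  if (any(mp_ng_ml <= 0) || any(uv_ng_ml <= 0)) {
    stop("dyad concentrations must be > 0 (exclude below-quantification records)",
         call. = FALSE)
  }
  structure(data.frame(dyad_id = as.character(dyad_id),
                       time_post_dose_h = as.numeric(time_post_dose_h),
                       mp_ng_ml = as.numeric(mp_ng_ml),
                       uv_ng_ml = as.numeric(uv_ng_ml)),
            class = c("observed_dyads", "data.frame"))
}

# cv_map keys the population sampler understands
.CV_KEYS <- c("cl", "v_maternal", "v_fetal", "ka_fast", "ka_slow",
              "cl_int_pd", "cl_int_pgp")

#' Population variability specification
#'
#' Log-normal inter-individual variability for Monte-Carlo simulation.
#' Each entry of `cv_map` is a coefficient of variation in percent; the
#' sampled parameter has its nominal value as median. The `cl` key scales
#' maternal elimination (`cl_hep_int`, `cl_renal` and `cl_total_override`
#' jointly with a single draw).
#'
#' @param n_subjects number of virtual subjects, >= 1.
#' @param cv_map named numeric vector/list of CVs in percent; allowed names:
#'   `cl`, `v_maternal`, `v_fetal`, `ka_fast`, `ka_slow`, `cl_int_pd`,
#'   `cl_int_pgp`.
#' @param seed integer RNG seed.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_subjects, cv_map = default_cv_map(), seed = 1L) {
  n_subjects <- .check_range(n_subjects, "n_subjects", 1)
  cv_map <- unlist(cv_map)
  .check_known_keys(cv_map, .CV_KEYS, "cv_map")
  for (k in names(cv_map)) .check_range(cv_map[[k]], paste0("cv_map$", k), 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 cv_map = cv_map,
                 seed = as.integer(.check_scalar(seed, "seed"))),
            class = "population_spec")
}

#' Default inter-individual variability magnitudes
#'
#' The paper-style percentile bands require a variability model that the
#' source figures do not print; these defaults are typical population-PK
#' magnitudes (35% on clearances and volumes, 50% on absorption rate
#' constants, 30% on placental clearances). Regimen comparisons use matched
#' seeds, so comparative results are insensitive to the exact CVs.
#'
#' @return named numeric vector of CVs in percent.
#' @export
default_cv_map <- function() {
  c(cl = 35, v_maternal = 35, v_fetal = 35,
    ka_fast = 50, ka_slow = 50,
    cl_int_pd = 30, cl_int_pgp = 30)
}

# ---- serialization ----------------------------------------------------------

#' Convert typed parameter objects to plain lists (for config round-trips)
#'
#' @param x a typed object.
#' @param ... unused.
#' @return a plain named list mirroring the constructor arguments.
#' @export
as_config_list <- function(x, ...) UseMethod("as_config_list")

#' @export
as_config_list.drug_params <- function(x, ...) {
  out <- unclass(x)
  out[vapply(out, is.null, logical(1))] <- NULL
  out
}

#' @export
as_config_list.absorption_params <- function(x, ...) {
  out <- unclass(x)
  out[vapply(out, is.null, logical(1))] <- NULL
  out
}

#' @export
as_config_list.placental_transfer <- function(x, ...) {
  list(cl_int_pd = x$cl_int_pd, cl_int_pgp = x$cl_int_pgp)
}

#' @export
as_config_list.maternal_physiology <- function(x, ...) unclass(x)

#' @export
as_config_list.model_params <- function(x, ...) {
  list(drug = as_config_list(x$drug),
       placental = as_config_list(x$placental),
       physiology = as_config_list(x$physiology))
}

.construct_from_list <- function(raw, constructor, allowed, where) {
  if (is.null(raw)) stop(sprintf("missing required section '%s'", where),
                         call. = FALSE)
  .check_known_keys(raw, allowed, where)
  do.call(constructor, raw)
}

#' Validate a raw configuration tree
#'
#' Turns a parsed configuration (nested named list, e.g. from YAML or JSON)
#' into validated typed objects. Unknown keys are rejected with a message
#' naming the key; range violations name the field, the value and the bound.
#'
#' @param raw named list with sections `drug`, `absorption`, `placental`,
#'   `physiology`.
#' @return a list with validated elements `drug`, `absorption`, `placental`,
#'   `physiology`, and a convenience `params` ([model_params()]).
#' @export
validate_config <- function(raw) {
  .check_known_keys(raw, c("drug", "absorption", "placental", "physiology"),
                    "config")
  drug <- .construct_from_list(raw$drug, drug_params,
                               names(formals(drug_params)), "drug")
  absorption <- .construct_from_list(raw$absorption, absorption_params,
                                     names(formals(absorption_params)),
                                     "absorption")
  praw <- raw$placental
  praw$kpuu <- NULL  # derived; tolerated on input for round-trips
  placental <- .construct_from_list(praw, placental_transfer,
                                    names(formals(placental_transfer)),
                                    "placental")
  physiology <- .construct_from_list(raw$physiology, maternal_physiology,
                                     names(formals(maternal_physiology)),
                                     "physiology")
  list(drug = drug, absorption = absorption, placental = placental,
       physiology = physiology,
       params = model_params(drug, placental, physiology))
}

#' Read and validate a configuration file
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return see [validate_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw)
}

# ---- print methods ----------------------------------------------------------

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("<drug_params> %s\n", x$name))
  cat(sprintf("  fu maternal/fetal: %.3g / %.3g\n", x$fu_maternal, x$fu_fetal))
  if (!is.null(x$cl_total_override)) {
    cat(sprintf("  CL total (override): %.3g L/h\n", x$cl_total_override))
  } else {
    cat(sprintf("  CL hep,int: %.3g L/h  CL renal: %.3g L/h\n",
                x$cl_hep_int, x$cl_renal))
  }
  cat(sprintf("  V maternal/fetal: %.3g / %.3g L  CL fetal: %.3g L/h\n",
              x$v_maternal, x$v_fetal, x$cl_fetal))
  invisible(x)
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %s (%s): %s mg at %s h\n", x$label,
              x$absorption$route,
              paste(x$doses$amount_mg, collapse = ", "),
              paste(x$doses$time_h, collapse = ", ")))
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  print(x$drug)
  cat(sprintf("  GW%g  Q_hep %.3g L/h  Q_placenta %.3g L/h  CYP3A x%.3g\n",
              x$physiology$gestational_week, x$physiology$q_hepatic,
              x$physiology$q_placenta, x$physiology$cyp3a_induction_factor))
  cat(sprintf("  placental CL_int PD %.3g L/h, P-gp %.3g L/h (Kp,uu %.3g)\n",
              x$placental$cl_int_pd, x$placental$cl_int_pgp, x$placental$kpuu))
  invisible(x)
}
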