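# Monte-Carlo inter-individual variability and percentile summaries.
#
# Each parameter listed in the population spec's cv_map receives an
# independent log-normal multiplier with median 1 and the stated coefficient
# of variation, so the sampled parameter's median equals its nominal value.
# The same seed always yields the same virtual population, which is what
# makes matched-seed regimen comparisons meaningful.

.lognormal_sdlog <- function(cv_percent) sqrt(log(1 + (cv_percent / 100)^2))

#' Sample a virtual population
#'
#' Draws per-subject parameter sets around nominal values. Each cv_map key
#' gets one log-normal multiplier per subject (median 1): `cl` scales
#' maternal elimination (`cl_hep_int`, `cl_renal`, `cl_total_override`
#' jointly), `v_maternal`/`v_fetal` the central volumes, `ka_fast`/`ka_slow`
#' the absorption rate constants, and `cl_int_pd`/`cl_int_pgp` the placental
#' clearances. Parameters without a cv_map entry are left untouched.
#'
#' Sampled sets are plain modified copies: cross-field invariants such as
#' `ka_fast >= ka_slow` are enforced on user-constructed objects, not on
#' Monte-Carlo draws (the model is well-defined either way).
#'
#' @param spec a [population_spec()].
#' @param params nominal [model_params()].
#' @param absorption nominal [absorption_params()] (from the regimen).
#' @return list of length `n_subjects`; each element has `params`,
#'   `absorption` and the `factors` applied. The full factor matrix is
#'   attached as attribute `factors`.
#' @export
sample_population <- function(spec, params, absorption) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(params, "model_params"),
            inherits(absorption, "absorption_params"))
  keys <- names(spec$cv_map)
  n <- spec$n_subjects
  fac <- withr::with_seed(spec$seed, {
    m <- vapply(keys, function(k) {
      sd <- .lognormal_sdlog(spec$cv_map[[k]])
      if (sd == 0) rep(1, n) else rlnorm(n, meanlog = 0, sdlog = sd)
    }, numeric(n))
    matrix(m, nrow = n, dimnames = list(NULL, keys))
  })
  subjects <- lapply(seq_len(n), function(i) {
    f <- fac[i, , drop = TRUE]
    p <- params
    a <- absorption
    if ("cl" %in% keys) {
      p$drug$cl_hep_int <- p$drug$cl_hep_int * f[["cl"]]
      p$drug$cl_renal <- p$drug$cl_renal * f[["cl"]]
      if (!is.null(p$drug$cl_total_override)) {
        p$drug$cl_total_override <- p$drug$cl_total_override * f[["cl"]]
      }
    }
    if ("v_maternal" %in% keys) p$drug$v_maternal <- p$drug$v_maternal * f[["v_maternal"]]
    if ("v_fetal" %in% keys) p$drug$v_fetal <- p$drug$v_fetal * f[["v_fetal"]]
    if ("cl_int_pd" %in% keys) p$placental$cl_int_pd <- p$placental$cl_int_pd * f[["cl_int_pd"]]
    if ("cl_int_pgp" %in% keys) p$placental$cl_int_pgp <- p$placental$cl_int_pgp * f[["cl_int_pgp"]]
    if ("ka_fast" %in% keys) a$ka_fast <- a$ka_fast * f[["ka_fast"]]
    if ("ka_slow" %in% keys) a$ka_slow <- a$ka_slow * f[["ka_slow"]]
    list(params = p, absorption = a, factors = f)
  })
  attr(subjects, "factors") <- fac
  subjects
}

#' Simulate a regimen across a virtual population
#'
#' Runs [simulate_regimen()] for every subject of a sampled population and
#' summarizes maternal and fetal concentrations pointwise across subjects:
#' mean and 5th/50th/95th percentile profiles (the dashed-band convention of
#' population-PK figures).
#'
#' @param reg a [regimen()].
#' @param params nominal [model_params()].
#' @param spec a [population_spec()].
#' @param grid output time grid (h); defaults as in [simulate_regimen()].
#' @param ... further arguments passed to [simulate_regimen()].
#' @return an object of class `population_profiles`: list with `times`,
#'   matrices `mp` and `uv` (time x subject, ng/ml), `summary` (a data frame
#'   with mean/p5/p50/p95 per matrix), and `n_subjects`.
#' @export
simulate_population <- function(reg, params, spec, grid = NULL, ...) {
  subjects <- sample_population(spec, params, reg$absorption)
  if (is.null(grid)) {
    tmax <- max(48, max(reg$doses$time_h) + 12)
    grid <- seq(0, tmax, by = 0.05)
  }
  n <- length(subjects)
  mp <- matrix(NA_real_, length(grid), n)
  uv <- matrix(NA_real_, length(grid), n)
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    reg_i <- reg
    reg_i$absorption <- s$absorption
    prof <- tryCatch(
      simulate_regimen(reg_i, s$params, grid = grid, ...),
      error = function(e) {
        stop(sprintf("subject %d: %s", i, conditionMessage(e)), call. = FALSE)
      })
    mp[, i] <- prof$mp_ng_ml
    uv[, i] <- prof$uv_ng_ml
  }
  qfun <- function(m) {
    data.frame(
      time_h = grid,
      mean = rowMeans(m),
      p5 = apply(m, 1, quantile, probs = 0.05, names = FALSE),
      p50 = apply(m, 1, quantile, probs = 0.50, names = FALSE),
      p95 = apply(m, 1, quantile, probs = 0.95, names = FALSE)
    )
  }
  structure(list(times = grid, mp = mp, uv = uv,
                 summary = list(mp = qfun(mp), uv = qfun(uv)),
                 n_subjects = n, regimen_label = reg$label,
                 seed = spec$seed),
            class = "population_profiles")
}

#' Extract one summary profile from a population simulation
#'
#' @param pop a `population_profiles` object from [simulate_population()].
#' @param which one of `"mean"`, `"p5"`, `"p50"`, `"p95"`.
#' @return a [concentration_profile()].
#' @export
population_profile <- function(pop, which = c("mean", "p5", "p50", "p95")) {
  which <- match.arg(which)
  concentration_profile(pop$times, pop$summary$mp[[which]],
                        pop$summary$uv[[which]])
}

#' @export
print.population_profiles <- function(x, ...) {
  cat(sprintf("<population_profiles> %s: %d subjects, %d time points, seed %d\n",
              x$regimen_label, x$n_subjects, length(x$times), x$seed))
  invisible(x)
}

#' Long-format export of per-subject population profiles
#'
#' @param pop a `population_profiles` object.
#' @return data frame with columns `subject_id`, `time_h`, `mp_ng_ml`,
#'   `uv_ng_ml`.
#' @export
population_long <- function(pop) {
  n <- pop$n_subjects
  data.frame(
    subject_id = rep(seq_len(n), each = length(pop$times)),
    time_h = rep(pop$times, n),
    mp_ng_ml = as.vector(pop$mp),
    uv_ng_ml = as.vector(pop$uv)
  )
}
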