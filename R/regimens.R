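# Built-in dosing-regimen registry and reference-vs-alternative comparison.

#' Built-in antenatal-corticosteroid regimens
#'
#' The clinical reference regimens and the alternative regimens examined in
#' the dosing-redesign analysis. Doses are mg of the administered ester
#' product:
#' * `DEX_ref`: 6 mg DEX phosphate i.m. every 12 h for 48 h (4 doses).
#' * `DEX_alt`: 12 mg every 24 h (2 doses) - maintains AUC, halves the
#'   dosing frequency.
#' * `BET_ref`: 12 mg BET phosphate:acetate 1:1 i.m. every 24 h (2 doses).
#' * `BET_alt1`: 2.4 mg every 24 h (20% of the reference total dose).
#' * `BET_alt2`: single 5.4 mg dose (22.5% of the reference total).
#' * `BET_alt3`: single 12 mg dose (50% of the reference total; the
#'   BETADOSE-trial regimen).
#' * `BET_WHO`: 2 mg BET phosphate (single-phase fast absorption) every
#'   12 h for 48 h (the WHO trial regimen).
#'
#' Each regimen carries its drug name as attribute `drug`.
#'
#' @return named list of [regimen()] objects.
#' @export
builtin_regimens <- function() {
  dex_ab <- acs_absorption("DEX")
  bet_ab <- acs_absorption("BET")
  betp_ab <- acs_absorption("BET", "phosphate")
  tag <- function(r, drug) { attr(r, "drug") <- drug; r }
  list(
    DEX_ref  = tag(regimen("DEX_ref", c(0, 12, 24, 36), 6, dex_ab), "DEX"),
    DEX_alt  = tag(regimen("DEX_alt", c(0, 24), 12, dex_ab), "DEX"),
    BET_ref  = tag(regimen("BET_ref", c(0, 24), 12, bet_ab), "BET"),
    BET_alt1 = tag(regimen("BET_alt1", c(0, 24), 2.4, bet_ab), "BET"),
    BET_alt2 = tag(regimen("BET_alt2", 0, 5.4, bet_ab), "BET"),
    BET_alt3 = tag(regimen("BET_alt3", 0, 12, bet_ab), "BET"),
    BET_WHO  = tag(regimen("BET_WHO", c(0, 12, 24, 36), 2, betp_ab), "BET")
  )
}

# restrict a series to a window, interpolating the edges
.window_series <- function(times, concs, t0, t1) {
  inside <- times > t0 & times < t1
  list(times = c(t0, times[inside], t1),
       concs = c(approx(times, concs, xout = t0)$y, concs[inside],
                 approx(times, concs, xout = t1)$y))
}

# TRUE if the series rises above `threshold` and never falls back below it
# before t1 (the "maintained above the therapeutic threshold" criterion)
.maintained_above <- function(times, concs, threshold, t0, t1) {
  w <- .window_series(times, concs, t0, t1)
  above <- w$concs > threshold
  if (!any(above)) return(FALSE)
  first <- which(above)[1]
  all(above[first:length(above)])
}

.doses_per_day <- function(reg) {
  days <- floor(reg$doses$time_h / 24)
  max(table(days))
}

.profile_metrics <- function(prof, window, threshold) {
  t0 <- window[1]; t1 <- window[2]
  fet <- .window_series(prof$time_h, prof$uv_ng_ml, t0, t1)
  c(maternal_auc = auc_trapezoid(prof$time_h, prof$mp_ng_ml, t0, t1),
    maternal_cmax = cmax_cmin(prof$time_h, prof$mp_ng_ml, t0, t1)$cmax,
    fetal_auc = auc_trapezoid(prof$time_h, prof$uv_ng_ml, t0, t1),
    fetal_cmin = .post_peak_min(prof$time_h, prof$uv_ng_ml, t0, t1),
    fetal_time_above = time_above(fet$times, fet$concs, threshold))
}

#' Compare a reference and an alternative dosing regimen
#'
#' Simulates both regimens with the same parameters - and, when a
#' population spec is given, the same virtual population (matched seeds), so
#' that percent changes isolate the regimen effect from sampling noise - and
#' reports exposure metrics over a stated window: maternal AUC and Cmax,
#' fetal AUC, fetal Cmin (post-first-peak trough; simulated profiles start
#' at zero so the absolute window minimum is uninformative) and fetal time
#' above the therapeutic threshold. Metrics are reported for the mean
#' profile and, with a population, for the pointwise 5th/95th percentile
#' profiles. `threshold_met` records whether the fetal 5th-percentile
#' concentration, once above the threshold, stays above it through the end
#' of the window (mean profile when no population is simulated).
#'
#' @param reference,alternative [regimen()] objects.
#' @param params [model_params()] shared by both arms.
#' @param pop_spec optional [population_spec()]; `NULL` for a deterministic
#'   (mean-subject) comparison.
#' @param window analysis window `c(t0, t1)` (h).
#' @param threshold fetal therapeutic threshold (ng/ml), > 0.
#' @param grid output grid; defaults to `seq(0, window[2], 0.05)` extended
#'   to cover all dose times.
#' @param ... passed to the simulator.
#' @return an object of class `regimen_comparison`: list with `table`
#'   (metric, profile, reference, alternative, pct_change), `threshold_met`
#'   (named logical), `doses_per_day`, `window`, `threshold`, `labels`.
#' @export
compare_regimens <- function(reference, alternative, params, pop_spec = NULL,
                             window = c(0, 48), threshold = 1, grid = NULL,
                             ...) {
  stopifnot(inherits(reference, "regimen"), inherits(alternative, "regimen"))
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be c(t0, t1) with t0 < t1", call. = FALSE)
  }
  threshold <- .check_range(threshold, "threshold", 0, lower_open = TRUE)
  if (is.null(grid)) {
    tmax <- max(window[2], reference$doses$time_h, alternative$doses$time_h)
    grid <- seq(0, tmax, by = 0.05)
  }
  get_profiles <- function(reg) {
    if (is.null(pop_spec)) {
      list(mean = simulate_regimen(reg, params, grid = grid, ...))
    } else {
      pop <- simulate_population(reg, params, pop_spec, grid = grid, ...)
      list(mean = population_profile(pop, "mean"),
           p5 = population_profile(pop, "p5"),
           p95 = population_profile(pop, "p95"))
    }
  }
  ref_p <- get_profiles(reference)
  alt_p <- get_profiles(alternative)

  rows <- list()
  for (prof_name in names(ref_p)) {
    mref <- .profile_metrics(ref_p[[prof_name]], window, threshold)
    malt <- .profile_metrics(alt_p[[prof_name]], window, threshold)
    pct <- ifelse(mref > 0, 100 * (malt - mref) / mref, NA_real_)
    rows[[prof_name]] <- data.frame(
      metric = names(mref), profile = prof_name,
      reference = unname(mref), alternative = unname(malt),
      pct_change = unname(pct), row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  row.names(tab) <- NULL

  guard <- if (is.null(pop_spec)) ref_p$mean else ref_p$p5
  guard_alt <- if (is.null(pop_spec)) alt_p$mean else alt_p$p5
  threshold_met <- c(
    reference = .maintained_above(guard$time_h, guard$uv_ng_ml, threshold,
                                  window[1], window[2]),
    alternative = .maintained_above(guard_alt$time_h, guard_alt$uv_ng_ml,
                                    threshold, window[1], window[2]))

  structure(list(
    table = tab,
    threshold_met = threshold_met,
    doses_per_day = c(reference = .doses_per_day(reference),
                      alternative = .doses_per_day(alternative)),
    window = window, threshold = threshold,
    labels = c(reference = reference$label, alternative = alternative$label),
    n_subjects = if (is.null(pop_spec)) 1L else pop_spec$n_subjects
  ), class = "regimen_comparison")
}

#' Look up one entry of a regimen comparison
#'
#' @param cmp a `regimen_comparison`.
#' @param metric one of `maternal_auc`, `maternal_cmax`, `fetal_auc`,
#'   `fetal_cmin`, `fetal_time_above`.
#' @param profile one of `mean`, `p5`, `p95`.
#' @param what `"pct_change"`, `"reference"` or `"alternative"`.
#' @return a single number.
#' @export
comparison_value <- function(cmp, metric, profile = "mean",
                             what = "pct_change") {
  row <- cmp$table$metric == metric & cmp$table$profile == profile
  if (!any(row)) {
    stop(sprintf("no entry for metric '%s', profile '%s'", metric, profile),
         call. = FALSE)
  }
  cmp$table[row, what][[1]]
}

#' @export
print.regimen_comparison <- function(x, ...) {
  cat(sprintf("<regimen_comparison> %s vs %s over [%g, %g] h (n = %d)\n",
              x$labels["reference"], x$labels["alternative"],
              x$window[1], x$window[2], x$n_subjects))
  tab <- x$table
  tab$reference <- signif(tab$reference, 4)
  tab$alternative <- signif(tab$alternative, 4)
  tab$pct_change <- round(tab$pct_change, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("fetal conc maintained > %g ng/ml: reference %s, alternative %s\n",
              x$threshold, x$threshold_met["reference"],
              x$threshold_met["alternative"]))
  cat(sprintf("doses per day: reference %d, alternative %d\n",
              x$doses_per_day["reference"], x$doses_per_day["alternative"]))
  invisible(x)
}
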