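# Synthetic clinical observations with the structure the calibration
# assumes: one paired maternal/umbilical sample per maternal-fetal dyad at a
# random delivery time after the first dose, with independent multiplicative
# log-normal residual error on each matrix. This emulates pooled
# single-sample delivery data; it does not emulate below-quantification
# censoring, shared subject-level error, or true inter-individual kinetic
# variability in the sampled mothers.

#' Generate synthetic maternal-fetal dyads
#'
#' Simulates the model once, draws each dyad's delivery time uniformly over
#' a sampling window, reads off maternal and umbilical-vein concentrations,
#' and perturbs each independently by log-normal error with the stated CV
#' (error has unit median, so `mean(log(obs/pred)) = 0` in expectation).
#' Delivery times falling before absorption onset (zero predicted
#' concentration; such samples would be below quantification and excluded
#' upstream) are redrawn within the window, deterministically under the
#' seed.
#'
#' @param n number of dyads.
#' @param reg the [regimen()] administered.
#' @param params [model_params()].
#' @param sampling_window `c(t_min, t_max)` (h after first dose);
#'   `t_min >= 1` (samples earlier than 60 min post dose are unusable
#'   because prodrug hydrolysis is only then complete).
#' @param noise_cv residual coefficient of variation (%), >= 0.
#' @param seed RNG seed.
#' @param dt simulation grid step (h).
#' @param ... passed to [simulate_regimen()].
#' @return an [observed_dyads()] data frame with attribute `true_profile`
#'   (the noise-free simulated profile).
#' @export
generate_dyads <- function(n, reg, params, sampling_window = c(1, 24),
                           noise_cv = 25, seed = 1L, dt = 0.05, ...) {
  n <- .check_range(n, "n", 1)
  if (length(sampling_window) != 2 ||
      sampling_window[1] >= sampling_window[2]) {
    stop("sampling_window must be c(t_min, t_max) with t_min < t_max",
         call. = FALSE)
  }
  if (sampling_window[1] < 1) {
    stop(sprintf("field 'sampling_window[1]' = %g must be >= 1 h post dose",
                 sampling_window[1]), call. = FALSE)
  }
  noise_cv <- .check_range(noise_cv, "noise_cv", 0)
  tmax <- max(sampling_window[2], reg$doses$time_h) + dt
  grid <- seq(0, ceiling(tmax / dt) * dt, by = dt)
  prof <- simulate_regimen(reg, params, grid = grid, ...)

  sdlog <- .lognormal_sdlog(noise_cv)
  pred_at <- function(tt) {
    list(mp = approx(prof$time_h, prof$mp_ng_ml, xout = tt)$y,
         uv = approx(prof$time_h, prof$uv_ng_ml, xout = tt)$y)
  }
  draws <- withr::with_seed(seed, {
    times <- runif(n, sampling_window[1], sampling_window[2])
    # delivery times where the model predicts zero concentration (before
    # absorption onset) would be below-quantification records, which the
    # dyad data model excludes; redraw them
    for (iter in seq_len(100)) {
      p <- pred_at(times)
      bad <- which(p$mp <= 0 | p$uv <= 0)
      if (!length(bad)) break
      times[bad] <- runif(length(bad), sampling_window[1], sampling_window[2])
    }
    list(times = times,
         err_mp = if (sdlog > 0) rlnorm(n, 0, sdlog) else rep(1, n),
         err_uv = if (sdlog > 0) rlnorm(n, 0, sdlog) else rep(1, n))
  })
  p <- pred_at(draws$times)
  mp <- p$mp * draws$err_mp
  uv <- p$uv * draws$err_uv
  if (any(mp <= 0) || any(uv <= 0)) {
    stop("sampling window has zero predicted concentration throughout",
         call. = FALSE)
  }
  out <- observed_dyads(sprintf("dyad%03d", seq_len(n)), draws$times, mp, uv)
  attr(out, "true_profile") <- prof
  out
}

#' Generate a noisy dense concentration profile
#'
#' [simulate_regimen()] output with independent multiplicative log-normal
#' noise on each maternal and fetal grid value (a fixture generator for NCA
#' and fitting tests). `noise_cv = 0` reproduces the simulator output
#' exactly.
#'
#' @param reg a [regimen()].
#' @param params [model_params()].
#' @param grid output grid (h).
#' @param noise_cv residual CV (%), >= 0.
#' @param seed RNG seed.
#' @param ... passed to [simulate_regimen()].
#' @return a [concentration_profile()] with attribute `true_profile`.
#' @export
generate_dense_profile <- function(reg, params, grid = NULL, noise_cv = 0,
                                   seed = 1L, ...) {
  noise_cv <- .check_range(noise_cv, "noise_cv", 0)
  prof <- simulate_regimen(reg, params, grid = grid, ...)
  if (noise_cv == 0) return(prof)
  sdlog <- .lognormal_sdlog(noise_cv)
  m <- length(prof$time_h)
  err <- withr::with_seed(seed, list(mp = rlnorm(m, 0, sdlog),
                                     uv = rlnorm(m, 0, sdlog)))
  out <- concentration_profile(prof$time_h, prof$mp_ng_ml * err$mp,
                               prof$uv_ng_ml * err$uv)
  attr(out, "true_profile") <- prof
  out
}
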