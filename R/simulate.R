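# run expr with a temporary RNG state; never leaks global seed changes
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Latent monolayer model for the simulator
#'
#' Phenomenological ground truth for a leaky, cation-selective (claudin-2
#' rich) monolayer: the selectivity ratio beta = P_Na/P_Cl and the
#' transepithelial conductance G relax exponentially within each epoch,
#'
#'   beta(t) = beta_inf + (beta_start - beta_inf) exp(-(t - t0) / tau),
#'
#' continuous across epoch boundaries (`beta_start` of an epoch is the value
#' the previous epoch reached at its end). A constant epoch is `tau = Inf`.
#' This is the minimal monotone model consistent with a gradual
#' selectivity decline under a standing apical-hyposmotic gradient and
#' prompt recovery when the gradient is removed; no mechanistic claim is
#' attached to the parameters.
#'
#' @param condition A [condition_preset()] providing the bath schedule.
#' @param beta0 Initial P_Na/P_Cl at t = 0.
#' @param g0 Initial conductance in S cm^-2.
#' @param epochs Data frame with columns `t0` (epoch start, minutes;
#'   first row must be 0), `beta_inf`, `tau_beta` (minutes), `g_inf`,
#'   `tau_g`. Default: one constant epoch.
#' @return Object of class `monolayer_model`.
#' @export
monolayer_model <- function(condition, beta0, g0, epochs = NULL) {
  stopifnot(inherits(condition, "condition_preset"),
            beta0 > 0, g0 > 0)
  if (is.null(epochs))
    epochs <- data.frame(t0 = 0, beta_inf = beta0, tau_beta = Inf,
                         g_inf = g0, tau_g = Inf)
  stopifnot(all(c("t0", "beta_inf", "tau_beta", "g_inf", "tau_g") %in%
                  names(epochs)),
            epochs$t0[1] == 0, !is.unsorted(epochs$t0, strictly = TRUE),
            all(epochs$tau_beta > 0), all(epochs$tau_g > 0),
            all(epochs$beta_inf > 0), all(epochs$g_inf > 0))
  structure(list(condition = condition, beta0 = beta0, g0 = g0,
                 epochs = epochs),
            class = "monolayer_model")
}

# one state variable through the epoch chain
.relax <- function(t, t0s, inf, tau, x0) {
  n <- length(t0s)
  # state at each epoch start (continuity)
  start_val <- numeric(n)
  start_val[1] <- x0
  if (n > 1) for (k in 2:n) {
    dt <- t0s[k] - t0s[k - 1]
    start_val[k] <- inf[k - 1] +
      (start_val[k - 1] - inf[k - 1]) * exp(-dt / tau[k - 1])
  }
  vapply(t, function(ti) {
    k <- findInterval(ti, t0s)
    if (k < 1) stop("time ", ti, " min precedes the first model epoch")
    inf[k] + (start_val[k] - inf[k]) * exp(-(ti - t0s[k]) / tau[k])
  }, numeric(1))
}

#' Latent ground-truth state of a monolayer model
#'
#' @param model A [monolayer_model()].
#' @param time Vector of times in minutes.
#' @return Data frame `time`, `beta`, `g`.
#' @export
latent_state <- function(model, time) {
  stopifnot(inherits(model, "monolayer_model"))
  ep <- model$epochs
  data.frame(
    time = time,
    beta = .relax(time, ep$t0, ep$beta_inf, ep$tau_beta, model$beta0),
    g = .relax(time, ep$t0, ep$g_inf, ep$tau_g, model$g0))
}

#' Volt-ohm-meter noise and blank-filter model
#'
#' @param sigma_v Gaussian noise SD on each potential reading, mV.
#' @param sigma_r Gaussian noise SD on each resistance reading, ohm cm^2.
#' @param blank_r Blank-filter series resistance, ohm cm^2.
#' @param blank_v_offset Blank potential offset (junction-potential
#'   surrogate), mV.
#' @param blank_v_drift Linear drift of the blank potential, mV/min.
#' @param seed Integer seed for the run.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_v = 0.2, sigma_r = 2, blank_r = 10,
                        blank_v_offset = 0.5, blank_v_drift = 0, seed = 1L) {
  stopifnot(sigma_v >= 0, sigma_r >= 0)
  structure(list(sigma_v = sigma_v, sigma_r = sigma_r, blank_r = blank_r,
                 blank_v_offset = blank_v_offset,
                 blank_v_drift = blank_v_drift, seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate one electrophysiological run
#'
#' For each grid time the latent (beta, G) is mapped through the forward
#' model: dilution potential via [ghk_forward_potential()] under the bath
#' pair in force, epithelial resistance 1/G. The sample reading adds the
#' blank filter's series resistance and potential offset plus Gaussian
#' meter noise; the blank series carries the same blank contributions and
#' noise, so [blank_correct()] recovers the epithelial ground truth up to
#' noise. Fully reproducible from `noise$seed`.
#'
#' @param model A [monolayer_model()].
#' @param noise A [noise_model()].
#' @param grid Strictly increasing measurement times in minutes.
#' @param ctx A [physical_context()].
#' @return List with `sample` and `blank` ([measurement_series()]), `truth`
#'   (data frame `time`, `beta`, `g`, `v`, `ter`, `p_na`, `p_cl`), and
#'   `schedule` (the bath schedule used).
#' @export
simulate_run <- function(model, noise, grid = seq(0, 120, by = 5),
                         ctx = physical_context()) {
  stopifnot(inherits(model, "monolayer_model"),
            inherits(noise, "noise_model"))
  if (is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be strictly increasing")
  schedule <- condition_schedule(model$condition)
  st <- latent_state(model, grid)
  v <- vapply(seq_along(grid), function(i)
    ghk_forward_potential(st$beta[i], baths_at(schedule, grid[i]), ctx),
    numeric(1))
  ter <- 1 / st$g
  kk <- lapply(seq_along(grid), function(i)
    kk_split_permeabilities(ter[i], st$beta[i],
                            baths_at(schedule, grid[i]), ctx))
  truth <- data.frame(time = grid, beta = st$beta, g = st$g, v = v,
                      ter = ter,
                      p_na = vapply(kk, `[[`, numeric(1), "p_na"),
                      p_cl = vapply(kk, `[[`, numeric(1), "p_cl"))
  n <- length(grid)
  blank_v <- noise$blank_v_offset + noise$blank_v_drift * grid
  .with_seed(noise$seed, {
    sample <- measurement_series(
      grid,
      ter + noise$blank_r + rnorm(n, 0, noise$sigma_r),
      v + blank_v + rnorm(n, 0, noise$sigma_v))
    blank <- measurement_series(
      grid,
      noise$blank_r + rnorm(n, 0, noise$sigma_r),
      blank_v + rnorm(n, 0, noise$sigma_v))
    list(sample = sample, blank = blank, truth = truth, schedule = schedule)
  })
}

#' Analyse a simulated run with the measurement pipeline
#'
#' Convenience wrapper: [blank_correct()] then
#' [compute_permeability_series()] against the run's own bath schedule.
#'
#' @param sim Output of [simulate_run()].
#' @param ctx A [physical_context()].
#' @param variant KK concentration-mean variant.
#' @return Permeability series data frame.
#' @export
analyze_run <- function(sim, ctx = physical_context(), variant = "logmean") {
  corrected <- blank_correct(sim$sample, sim$blank)
  compute_permeability_series(corrected, sim$schedule, ctx, variant)
}

# solve (x_start, x_inf) of x(t) = x_inf + (x_start - x_inf) e^{-t/tau}
# from two anchors (t1, v1), (t2, v2); times relative to epoch start
.solve_two_anchor <- function(t1, v1, t2, v2, tau) {
  e1 <- exp(-t1 / tau); e2 <- exp(-t2 / tau)
  a <- matrix(c(e1, e2, 1 - e1, 1 - e2), 2, 2)
  sol <- solve(a, c(v1, v2))
  list(start = sol[1], inf = sol[2])
}

#' Library of illustrative monolayer presets
#'
#' Named ground-truth models spanning the qualitative behaviours of the
#' study system:
#' \describe{
#'   \item{wt_iso}{wild-type monolayer under the apical-isosmotic condition:
#'     constant beta ~9, constant G.}
#'   \item{wt_hypo}{wild type under the apical-hyposmotic gradient: beta
#'     relaxes 9 -> 3 with tau = 30 min, G constant (so P_Na falls and P_Cl
#'     rises over 2 h).}
#'   \item{wt_reversibility}{the gradient-removal protocol: epoch parameters
#'     are solved so the latent trajectory passes through the reported
#'     selectivity triple (22.41 at 5 min, 3.40 at 120 min, 16.55 at
#'     125 min) and P_Na anchors (46.20, 33.46, 27.13 x 1e-6 cm/s); recovery
#'     time constant 1 min ("prompt").}
#'   \item{ko}{claudin-2-deficient monolayer: low conductance,
#'     non-selective (beta = 1), gradient-insensitive.}
#'   \item{rescue}{claudin-2 re-expression: wt_hypo-like response.}
#' }
#' Parameter values are illustrative anchors, not fits; the measurement grid
#' and noise magnitudes are free choices of the simulation.
#'
#' @param ctx A [physical_context()] (used to convert P_Na anchors to
#'   conductances).
#' @return Named list of [monolayer_model()]s.
#' @export
preset_library <- function(ctx = physical_context()) {
  pre <- condition_presets()
  g_of <- function(p_na, beta, baths) kk_conductance(p_na, beta, baths, ctx)

  iso_baths <- pre$apical_isosmotic$baths
  hypo_baths <- pre$apical_hyposmotic$baths

  wt_iso <- monolayer_model(pre$apical_isosmotic, beta0 = 9.32,
                            g0 = g_of(35e-6, 9.32, iso_baths))

  g_hypo <- g_of(40e-6, 9, hypo_baths)
  wt_hypo <- monolayer_model(
    pre$apical_hyposmotic, beta0 = 9, g0 = g_hypo,
    epochs = data.frame(t0 = 0, beta_inf = 3, tau_beta = 30,
                        g_inf = g_hypo, tau_g = Inf))

  # reversibility: relaxation epoch anchored at (5, 120) min, recovery epoch
  # at 125 min with tau_rec = 1 min
  tau1 <- 30; tau_rec <- 1
  b1 <- .solve_two_anchor(5, 22.41, 120, 3.40, tau1)
  b120 <- 3.40
  b_rec_inf <- (16.55 - b120 * exp(-5 / tau_rec)) / (1 - exp(-5 / tau_rec))
  g5 <- g_of(46.20e-6, 22.41, hypo_baths)
  g120 <- g_of(33.46e-6, 3.40, hypo_baths)
  g1 <- .solve_two_anchor(5, g5, 120, g120, tau1)
  g125 <- g_of(27.13e-6, 16.55,
               baths_at(condition_schedule(pre$reversibility), 125))
  g_rec_inf <- (g125 - g120 * exp(-5 / tau_rec)) / (1 - exp(-5 / tau_rec))
  wt_reversibility <- monolayer_model(
    pre$reversibility, beta0 = b1$start, g0 = g1$start,
    epochs = data.frame(
      t0 = c(0, 120),
      beta_inf = c(b1$inf, b_rec_inf), tau_beta = c(tau1, tau_rec),
      g_inf = c(g1$inf, g_rec_inf), tau_g = c(tau1, tau_rec)))

  ko <- monolayer_model(pre$apical_hyposmotic, beta0 = 1,
                        g0 = g_of(5e-6, 1, hypo_baths))

  g_res <- g_of(35e-6, 9, hypo_baths)
  rescue <- monolayer_model(
    pre$apical_hyposmotic, beta0 = 9, g0 = g_res,
    epochs = data.frame(t0 = 0, beta_inf = 3, tau_beta = 30,
                        g_inf = g_res, tau_g = Inf))

  list(wt_iso = wt_iso, wt_hypo = wt_hypo,
       wt_reversibility = wt_reversibility, ko = ko, rescue = rescue)
}

#' Fit an exponential relaxation to a recovered selectivity series
#'
#' Nonlinear least squares of
#' beta(t) = beta_inf + (beta0 - beta_inf) exp(-t / tau) to the `beta`
#' column of a permeability series; used for ground-truth parameter
#' recovery from simulated runs.
#'
#' @param series Data frame with columns `time`, `beta` (NA rows dropped).
#' @param start Optional named start values `beta0`, `beta_inf`, `tau`.
#' @return Named numeric `c(beta0, beta_inf, tau)`.
#' @export
fit_relaxation <- function(series, start = NULL) {
  d <- series[stats::complete.cases(series[, c("time", "beta")]), ]
  if (nrow(d) < 4) stop("need at least 4 beta records to fit a relaxation")
  if (is.null(start))
    start <- list(beta0 = d$beta[which.min(d$time)],
                  beta_inf = d$beta[which.max(d$time)],
                  tau = diff(range(d$time)) / 4)
  fit <- stats::nls(beta ~ beta_inf + (beta0 - beta_inf) * exp(-time / tau),
                    data = d, start = start,
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE))
  stats::coef(fit)[c("beta0", "beta_inf", "tau")]
}

#' Fit the selectivity relaxation in dilution-potential space
#'
#' Maximum-likelihood counterpart of [fit_relaxation()]: the exponential
#' beta(t) model is pushed through the forward GHK relation and fitted by
#' least squares directly to the blank-corrected dilution potentials, where
#' the meter noise is additive homoscedastic Gaussian. This avoids the
#' variance inflation and convexity bias of first inverting each noisy
#' potential to beta (the inversion is poorly conditioned at high
#' selectivity, where dV/dbeta is small). Replicate series may simply be
#' stacked in `corrected`.
#'
#' @param corrected Data frame with columns `time` and `dilution_potential`
#'   (mV), e.g. one or several stacked [blank_correct()] outputs.
#' @param baths The [bath_pair()] in force (a single relaxation epoch is
#'   assumed, so one pair).
#' @param ctx A [physical_context()].
#' @param start Optional start values `beta0`, `beta_inf`, `tau`.
#' @return Named numeric `c(beta0, beta_inf, tau)`.
#' @export
fit_relaxation_potential <- function(corrected, baths,
                                     ctx = physical_context(),
                                     start = NULL) {
  d <- corrected[stats::complete.cases(
    corrected[, c("time", "dilution_potential")]), ]
  if (nrow(d) < 4) stop("need at least 4 records to fit a relaxation")
  ions <- bath_ions(baths)
  vt_mv <- 1000 * thermal_voltage(ctx)
  if (is.null(start)) {
    b_ends <- ghk_invert_beta(
      c(d$dilution_potential[which.min(d$time)],
        d$dilution_potential[which.max(d$time)]), baths, ctx)
    start <- list(beta0 = max(b_ends[1], 0.01),
                  beta_inf = max(b_ends[2], 0.01),
                  tau = diff(range(d$time)) / 4)
  }
  fit <- stats::nls(
    dilution_potential ~ vt_mv * log(
      ((beta_inf + (beta0 - beta_inf) * exp(-time / tau)) * ions[["na_b"]] +
         ions[["cl_a"]]) /
        ((beta_inf + (beta0 - beta_inf) * exp(-time / tau)) * ions[["na_a"]] +
           ions[["cl_b"]])),
    data = d, start = start,
    control = stats::nls.control(maxiter = 300, warnOnly = TRUE))
  stats::coef(fit)[c("beta0", "beta_inf", "tau")]
}
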