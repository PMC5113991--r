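test_that("latent relaxation is piecewise exponential and continuous", {
  pre <- condition_presets()$reversibility
  model <- monolayer_model(
    pre, beta0 = 9, g0 = 0.01,
    epochs = data.frame(t0 = c(0, 120), beta_inf = c(3, 8),
                        tau_beta = c(30, 1), g_inf = 0.01, tau_g = Inf))
  st <- latent_state(model, c(0, 30, 120))
  expect_equal(st$beta[1], 9)
  expect_equal(st$beta[2], 3 + 6 * exp(-1), tolerance = 1e-12)
  b120 <- 3 + 6 * exp(-4)
  expect_equal(st$beta[3], b120, tolerance = 1e-12)
  # continuity at the epoch boundary
  eps <- latent_state(model, c(120 - 1e-9, 120 + 1e-9))
  expect_equal(eps$beta[1], eps$beta[2], tolerance = 1e-6)
  # under a constant epoch (tau = Inf) the state never moves
  const <- monolayer_model(pre, beta0 = 5, g0 = 0.02)
  expect_true(all(latent_state(const, seq(0, 240, 30))$beta == 5))
  expect_error(latent_state(model, -1), "epoch")
})

test_that("simulated series are bit-identical under a fixed seed", {
  pl <- preset_library()
  nm <- noise_model(seed = 123)
  s1 <- simulate_run(pl$wt_hypo, nm)
  s2 <- simulate_run(pl$wt_hypo, nm)
  expect_identical(s1, s2)
  s3 <- simulate_run(pl$wt_hypo, noise_model(seed = 124))
  expect_false(identical(s1$sample, s3$sample))
})

test_that("wt_iso stays flat: the 115-min deltas vanish within noise", {
  pl <- preset_library()
  res <- analyze_run(simulate_run(pl$wt_iso, noise_model(seed = 2),
                                  grid = seq(0, 120, 5)))
  d <- delta_115min(res)
  # truth delta is 0; bound by propagated noise on P (a few percent)
  expect_lt(abs(d$delta_p_na) / res$p_na[res$time == 5], 0.15)
})

test_that("the knockout model is gradient-insensitive", {
  pl <- preset_library()
  st <- latent_state(pl$ko, seq(0, 120, 5))
  expect_lt(diff(range(st$beta)) / mean(st$beta), 0.10)
  expect_lt(pl$ko$g0, pl$wt_hypo$g0)  # low conductance without claudin-2
})

test_that("mean recovered selectivity converges to the model plateau over
           replicates", {
  pl <- preset_library()
  n <- 4
  b120 <- vapply(seq_len(n), function(i) {
    sim <- simulate_run(pl$wt_hypo, noise_model(sigma_v = 0.2, seed = 100 + i),
                        grid = seq(100, 120, 5))
    res <- analyze_run(sim)
    res$beta[res$time == 120]
  }, numeric(1))
  truth <- latent_state(pl$wt_hypo, 120)$beta
  sem <- sd(b120) / sqrt(n)
  expect_lt(abs(mean(b120) - truth), 3 * max(sem, 1e-3))
})

test_that("full-loop parameter recovery: fitted (beta0, beta_inf) track the
           generator", {
  pl <- preset_library()
  grid <- seq(0, 120, 5)
  baths <- pl$wt_hypo$condition$baths
  fits <- vapply(1:5, function(rep) {
    stacked <- do.call(rbind, lapply(1:4, function(i) {
      sim <- simulate_run(pl$wt_hypo,
                         noise_model(sigma_v = 0.2, seed = 1000 * rep + i),
                         grid = grid)
      blank_correct(sim$sample, sim$blank)
    }))
    fit_relaxation_potential(stacked, baths)
  }, numeric(3))
  # each repeat within the noise envelope; the ensemble mean much tighter
  expect_true(all(abs(fits["beta0", ] - 9) / 9 < 0.15))
  expect_true(all(abs(fits["beta_inf", ] - 3) / 3 < 0.15))
  expect_lt(abs(mean(fits["beta0", ]) - 9) / 9, 0.05)
  expect_lt(abs(mean(fits["beta_inf", ]) - 3) / 3, 0.05)

  # the zero-noise fit recovers the generator exactly
  quiet <- noise_model(sigma_v = 0, sigma_r = 0, blank_r = 0,
                       blank_v_offset = 0)
  cor <- blank_correct(simulate_run(pl$wt_hypo, quiet, grid = grid)$sample,
                       simulate_run(pl$wt_hypo, quiet, grid = grid)$blank)
  # nls reports non-convergence on exactly-zero residuals; coefficients are
  # still exact
  fit0 <- suppressWarnings(fit_relaxation_potential(cor, baths))
  expect_equal(unname(fit0), c(9, 3, 30), tolerance = 1e-6)
})
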