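test_that("preset osmotic classes match their condition names", {
  pre <- condition_presets()
  expected <- c(apical_isosmotic = "iso",
                apical_hyposmotic = "apical_hypo",
                basal_isosmotic = "iso",
                basal_hyposmotic = "apical_hyper",
                basal_hyperosmotic = "apical_hypo",
                basal_hyperosmotic_balanced = "iso",
                apical_hyperosmotic = "apical_hyper",
                apical_hyperosmotic_balanced = "iso",
                reversibility = "apical_hypo")
  for (nm in names(expected))
    expect_identical(osmotic_class(pre[[nm]]), unname(expected[nm]),
                     label = nm)
  # mannitol presets classify identically
  prem <- condition_presets("mannitol")
  expect_identical(osmotic_class(prem$apical_isosmotic), "iso")
})

test_that("the reversibility switch removes the osmotic gradient but keeps
           the NaCl gradient", {
  pre <- condition_presets()$reversibility
  sched <- condition_schedule(pre)
  before <- baths_at(sched, 119); after <- baths_at(sched, 121)
  expect_identical(bath_ions(before), bath_ions(after))
  expect_identical(osmotic_class(after), "iso")
  expect_identical(osmotic_class(before), "apical_hypo")
})

test_that("delta over the 5-120 min window follows the stated subtraction
           order", {
  const <- data.frame(time = seq(0, 120, 5), p_na = 4e-5, p_cl = 5e-6)
  d <- delta_115min(const)
  expect_equal(d$delta_p_na, 0)
  expect_equal(d$delta_p_cl, 0)

  # relaxing selectivity at constant conductance: P_Na falls, P_Cl rises
  pl <- preset_library()
  quiet <- noise_model(sigma_v = 0, sigma_r = 0, blank_r = 0,
                       blank_v_offset = 0)
  res <- analyze_run(simulate_run(pl$wt_hypo, quiet,
                                  grid = seq(0, 120, 5)))
  d <- delta_115min(res)
  expect_gt(d$delta_p_na, 0)
  expect_lt(d$delta_p_cl, 0)
})

test_that("anchors accept nearest records within the tolerance", {
  s <- data.frame(time = c(4.8, 60, 120.3), p_na = c(4, 3, 2),
                  p_cl = c(1, 1, 1))
  d <- delta_115min(s)
  expect_equal(d$t_early, 4.8)
  expect_equal(d$t_late, 120.3)
  expect_equal(d$delta_p_na, 2)
  expect_error(delta_115min(data.frame(time = c(20, 60), p_na = 1:2,
                                       p_cl = 1:2)), "anchor")
})

test_that("delta is antisymmetric under time reversal of the series", {
  s <- data.frame(time = seq(5, 120, 5))
  s$p_na <- 4e-5 * exp(-s$time / 50)
  s$p_cl <- 5e-6 * exp(s$time / 200)
  fwd <- delta_115min(s)
  rev <- s; rev$time <- 125 - s$time
  bwd <- delta_115min(rev)
  expect_equal(bwd$delta_p_na, -fwd$delta_p_na)
  expect_equal(bwd$delta_p_cl, -fwd$delta_p_cl)
})

test_that("recovery metrics reproduce a constant series and the exponential
           recovery plateau", {
  const <- data.frame(time = seq(0, 130, 5), beta = 7)
  rm <- recovery_metrics(const)
  expect_equal(unlist(rm), c(beta_pre = 7, beta_at_switch = 7,
                             beta_post5min = 7))

  # tau_rec = 1 min: five minutes after the switch the recovery is within
  # 2% of its plateau (closed form: 1 - exp(-5) residual)
  pre <- condition_presets()$reversibility
  model <- monolayer_model(
    pre, beta0 = 9, g0 = 0.01,
    epochs = data.frame(t0 = c(0, 120), beta_inf = c(3, 9),
                        tau_beta = c(30, 1), g_inf = 0.01, tau_g = Inf))
  st <- latent_state(model, c(120, 125))
  plateau <- 9
  expect_lt(abs(st$beta[2] - plateau) / plateau, 0.02)
  quiet <- noise_model(sigma_v = 0, sigma_r = 0, blank_r = 0,
                       blank_v_offset = 0)
  res <- analyze_run(simulate_run(model, quiet, grid = seq(0, 130, 5)))
  rm <- recovery_metrics(res)
  expect_lt(abs(rm$beta_post5min - plateau) / plateau, 0.02)
  expect_error(recovery_metrics(res[res$time < 120, ]), "anchor")
})

test_that("the reversibility preset reproduces the reported selectivity
           triple through the full pipeline", {
  pl <- preset_library()
  quiet <- noise_model(sigma_v = 0, sigma_r = 0, blank_r = 0,
                       blank_v_offset = 0)
  res <- analyze_run(simulate_run(pl$wt_reversibility, quiet,
                                  grid = c(5, 60, 120, 125)))
  rm <- recovery_metrics(res)
  expect_equal(rm$beta_pre, 22.41, tolerance = 1e-6)
  expect_equal(rm$beta_at_switch, 3.40, tolerance = 1e-6)
  expect_equal(rm$beta_post5min, 16.55, tolerance = 1e-6)
  # and the P_Na anchors
  expect_equal(res$p_na[res$time == 5] * 1e6, 46.20, tolerance = 1e-6)
  expect_equal(res$p_na[res$time == 120] * 1e6, 33.46, tolerance = 1e-6)
  expect_equal(res$p_na[res$time == 125] * 1e6, 27.13, tolerance = 1e-6)
})
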