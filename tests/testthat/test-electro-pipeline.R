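test_that("blank correction subtracts paired readings", {
  sample <- measurement_series(5, 90, 12)
  blank <- measurement_series(5, 30, -2)
  cor <- blank_correct(sample, blank)
  expect_equal(cor$ter, 60)
  expect_equal(cor$dilution_potential, 14)
  expect_false(cor$flagged)
})

test_that("identical sample and blank yield only flagged records", {
  s <- measurement_series(c(0, 5, 10), c(30, 31, 32), c(1, 1.2, 0.9))
  expect_warning(cor <- blank_correct(s, s), "non-positive")
  expect_true(all(cor$flagged))
  expect_true(all(cor$ter == 0))
})

test_that("unpairable time points raise an error naming the orphans", {
  sample <- measurement_series(c(5, 10), c(90, 91), c(12, 12))
  blank <- measurement_series(5, 30, -2)
  expect_error(blank_correct(sample, blank), "10")
  # within tolerance pairing works
  blank2 <- measurement_series(c(5.3, 9.6), c(30, 30), c(-2, -2))
  expect_equal(blank_correct(sample, blank2)$ter, c(60, 61))
})

test_that("pipeline inverts the forward model exactly without noise", {
  pl <- preset_library()
  quiet <- noise_model(sigma_v = 0, sigma_r = 0, blank_r = 0,
                       blank_v_offset = 0)
  sim <- simulate_run(pl$wt_hypo, quiet, grid = seq(0, 120, by = 15))
  res <- analyze_run(sim)
  expect_equal(res$beta, sim$truth$beta, tolerance = 1e-9)
  expect_equal(res$p_na, sim$truth$p_na, tolerance = 1e-9)
  expect_equal(res$p_cl, sim$truth$p_cl, tolerance = 1e-9)
})

test_that("blank correction removes simulated blank artifacts to noise level", {
  pl <- preset_library()
  noisy <- noise_model(sigma_v = 0.2, sigma_r = 2, blank_r = 25,
                       blank_v_offset = 1.5, blank_v_drift = 0.01,
                       seed = 42)
  sim <- simulate_run(pl$wt_hypo, noisy, grid = seq(0, 120, by = 5))
  cor <- blank_correct(sim$sample, sim$blank)
  # corrected readings match artifact-free ground truth within 5 sigma of
  # the difference noise (sqrt(2) * sigma per channel)
  expect_true(all(abs(cor$ter - sim$truth$ter) < 5 * sqrt(2) * 2))
  expect_true(all(abs(cor$dilution_potential - sim$truth$v) <
                    5 * sqrt(2) * 0.2))
})

test_that("recovered selectivity stays in a 3-sigma envelope of truth", {
  pl <- preset_library()
  sim <- simulate_run(pl$wt_hypo,
                      noise_model(sigma_v = 0.2, sigma_r = 0, blank_r = 10,
                                  seed = 7),
                      grid = seq(0, 120, by = 5))
  res <- analyze_run(sim)
  # propagate potential noise through the inversion: d(beta)/dV at truth
  baths <- baths_at(sim$schedule, 0)
  dbeta_dv <- vapply(seq_len(nrow(res)), function(i) {
    b <- sim$truth$beta[i]
    (ghk_invert_beta(sim$truth$v[i] + 1e-4, baths) -
       ghk_invert_beta(sim$truth$v[i] - 1e-4, baths)) / 2e-4
  }, numeric(1))
  sigma_beta <- abs(dbeta_dv) * sqrt(2) * 0.2
  expect_true(all(abs(res$beta - sim$truth$beta) < 3.5 * sigma_beta))
})

test_that("flagged records propagate as NA, never silently dropped", {
  corrected <- data.frame(time = c(5, 10, 15), ter = c(60, -1, 62),
                          dilution_potential = c(10, 11, 10.5),
                          flagged = c(FALSE, TRUE, FALSE))
  res <- compute_permeability_series(corrected, nacl_baths(70, 140))
  expect_equal(nrow(res), 3)
  expect_true(is.na(res$beta[2]) && is.na(res$p_na[2]))
  expect_false(anyNA(res$beta[c(1, 3)]))
})

test_that("a schedule gap is reported with the uncovered time", {
  corrected <- data.frame(time = 5, ter = 60, dilution_potential = 10)
  schedule <- list(list(time = 10, baths = nacl_baths(70, 140)))
  expect_error(compute_permeability_series(corrected, schedule), "5")
})

test_that("bath bookkeeping alone creates no discontinuity at a switch", {
  # constant latent beta across a solution replacement that leaves NaCl
  # unchanged: the analysed series must be smooth through the switch
  pre <- condition_presets()$reversibility
  model <- monolayer_model(pre, beta0 = 5, g0 = 0.01)
  quiet <- noise_model(sigma_v = 0, sigma_r = 0, blank_r = 0,
                       blank_v_offset = 0)
  sim <- simulate_run(model, quiet, grid = c(110, 115, 120, 125, 130))
  res <- analyze_run(sim)
  expect_equal(res$beta, rep(5, 5), tolerance = 1e-9)
})
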