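prot24 <- acquisition_protocol(n_angles = 24)

test_that("window scatter estimate scales the estimation window by k", {
  s <- simulate_acquisition(small_phantom(), prot24, seed = 2)
  expect_true(all(window_scatter_estimate(s, "w118", k = 0) == 0))
  est <- window_scatter_estimate(s, "w118", k = 1.15, smoothing_fwhm_mm = 0)
  expect_equal(est, 1.15 * s$counts$w118, tolerance = 1e-14)
  # smoothing redistributes but conserves the total estimate
  est_sm <- window_scatter_estimate(s, "w118", k = 1.15, smoothing_fwhm_mm = 20)
  expect_false(isTRUE(all.equal(est_sm, est)))
  expect_equal(sum(est_sm), 1.15 * sum(s$counts$w118), tolerance = 1e-9)
  expect_true(all(est_sm >= 0))
  expect_error(window_scatter_estimate(s, "w999"), "not in projection set")
})

test_that("MLEM conserves counts on noiseless unattenuated data", {
  # uniform cylinder, mu = 0, no scatter, 1 subset, no PSF
  d <- c(32, 32, 16)
  act <- array(0, d)
  x <- ((1:32) - 16.5); r2 <- outer(x^2, x^2, "+")
  for (z in 5:12) act[, , z] <- (r2 <= 10^2) * 1e5
  av <- voxel_volume(act, c(4.8, 4.8, 4.8), units = "Bq/ml")
  mu0 <- voxel_volume(array(0, d), c(4.8, 4.8, 4.8))
  stk <- attenuated_forward_project(av, mu0, prot24, psf_fwhm_mm = 0,
                                    sensitivity = 1e-5)
  cfg <- recon_config(n_iterations = 10, n_subsets = 1, psf_fwhm_mm = 0,
                      sensitivity = 1e-5,
                      init_volume = array(1, d))
  rec <- osem_reconstruct(stk, 0, mu0, prot24, cfg)
  expect_equal(sum(rec$values$data), sum(act), tolerance = 0.005)
  expect_true(all(rec$values$data >= 0))
})

test_that("the true solution is a fixed point of the EM update", {
  ph <- small_phantom()
  s <- simulate_acquisition(no_tc(ph), prot24, noise = FALSE)
  true_scatter <- s$components$w81$ho_downscatter
  cfg <- recon_config(n_iterations = 1, n_subsets = 1,
                      init_volume = ph$ho_activity$data)
  cfg <- duospect:::resolve_sensitivity(s, cfg, "ho", "w81")
  # measured counts are exactly forward(truth) + true scatter (no noise)
  rec <- osem_reconstruct(s$expected$w81, true_scatter, ph$mu_81, prot24, cfg)
  rel <- abs(rec$values$data - ph$ho_activity$data) /
    max(ph$ho_activity$data)
  expect_lt(max(rel), 1e-6)
})

test_that("MLEM log-likelihood is monotone non-decreasing on noiseless data", {
  ph <- small_phantom()
  s <- simulate_acquisition(no_tc(ph), prot24, noise = FALSE)
  cfg <- recon_config(n_iterations = 8, n_subsets = 1, track_loglik = TRUE)
  cfg <- duospect:::resolve_sensitivity(s, cfg, "ho", "w81")
  rec <- osem_reconstruct(s$expected$w81,
                          window_scatter_estimate(s, "w118", 1.15, 20),
                          ph$mu_81, prot24, cfg)
  ll <- rec$convergence$loglik
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
})

test_that("OSEM with 8 subsets matches MLEM at matched update count", {
  ph <- small_phantom()
  s <- simulate_acquisition(no_tc(ph), prot24, noise = FALSE)
  scatter <- window_scatter_estimate(s, "w118", 1.15, 20)
  cfg8 <- duospect:::resolve_sensitivity(s, recon_config(n_iterations = 10,
                                                         n_subsets = 8),
                                         "ho", "w81")
  cfg1 <- duospect:::resolve_sensitivity(s, recon_config(n_iterations = 80,
                                                         n_subsets = 1),
                                         "ho", "w81")
  r8 <- osem_reconstruct(s$expected$w81, scatter, ph$mu_81, prot24, cfg8)
  r1 <- osem_reconstruct(s$expected$w81, scatter, ph$mu_81, prot24, cfg1)
  liver <- organ_mask(ph, "liver")
  expect_equal(mean(r8$values$data[liver]), mean(r1$values$data[liver]),
               tolerance = 0.02)
})

test_that("degenerate reconstruction inputs are handled", {
  d <- c(8, 8, 4)
  mu0 <- voxel_volume(array(0, d), c(4.8, 4.8, 4.8))
  prot <- acquisition_protocol(n_angles = 4)
  zeros <- array(0, c(8, 4, 4))
  cfg <- recon_config(sensitivity = 1)
  expect_warning(rec <- osem_reconstruct(zeros, 0, mu0, prot, cfg),
                 "all-zero")
  expect_true(all(rec$values$data == 0))
  neg <- zeros; neg[1] <- -1
  expect_error(osem_reconstruct(neg, 0, mu0, prot, cfg), "negative counts")
  expect_error(osem_reconstruct(zeros, -1, mu0, prot, cfg), "non-negative")
})

test_that("dual-isotope data with no Tc reconstruct identically to Ho-only", {
  ph <- small_phantom()
  s_ho <- simulate_acquisition(no_tc(ph), prot24, seed = 5)
  s_di <- simulate_acquisition(no_tc(ph), prot24, seed = 5)
  r_ho <- reconstruct_ho(s_ho, ph$mu_81, prot24)
  r_di <- reconstruct_ho(s_di, ph$mu_81, prot24)
  expect_identical(r_ho$values$data, r_di$values$data)
})

test_that("downscatter correction moves the DI image toward the Ho-only one", {
  ph <- small_phantom()
  healthy <- organ_mask(ph, "healthy")
  for (seed in 1:3) {
    s_ho <- simulate_acquisition(no_tc(ph), prot24, seed = seed)
    s_di <- simulate_acquisition(ph, prot24, seed = seed)
    r_ho <- reconstruct_ho(s_ho, ph$mu_81, prot24)
    r_c <- reconstruct_ho(s_di, ph$mu_81, prot24)
    r_u <- reconstruct_ho(s_di, ph$mu_81, prot24,
                          recon_config(correction = FALSE))
    m_ho <- mean(r_ho$values$data[healthy])
    expect_lt(abs(mean(r_c$values$data[healthy]) - m_ho),
              abs(mean(r_u$values$data[healthy]) - m_ho))
  }
})

test_that("high-count reconstruction recovers liver activity within 10%", {
  ph <- std_phantom()
  rec <- std_ho_recon()
  liver <- organ_mask(ph, "liver")
  expect_equal(mean(rec$values$data[liver]),
               mean(ph$ho_activity$data[liver]), tolerance = 0.10)
})

test_that("Tc reconstruction recovers amount and support of the colloid", {
  ph <- std_phantom()
  rtc <- std_tc_recon()
  # total within 15% of the simulated 50 MBq
  expect_equal(total_activity_mbq(rtc$values), 50, tolerance = 0.15)
  # >= 90% of reconstructed Tc activity inside the healthy-liver mask
  # after thresholding away the noise floor
  v <- rtc$values$data
  v[v < 0.05 * max(v)] <- 0
  healthy <- organ_mask(ph, "healthy")
  expect_gte(sum(v[healthy]) / sum(v), 0.90)
  # with no Ho present, toggling the correction changes nothing
  ph_tc <- small_phantom()
  ph_tc$ho_activity$data[] <- 0
  s <- simulate_acquisition(ph_tc, prot24, seed = 6)
  r_on <- reconstruct_tc(s, ph_tc$mu_140, prot24)
  r_off <- reconstruct_tc(s, ph_tc$mu_140, prot24,
                          recon_config(correction = FALSE))
  expect_identical(r_on$values$data, r_off$values$data)
})

test_that("Gaussian post-filter is conservative and sigma = 0 is identity", {
  rec <- std_ho_recon()
  expect_identical(gaussian_postfilter(rec, 0), rec)
  sm <- gaussian_postfilter(rec, 4.2)
  expect_equal(sum(sm$values$data), sum(rec$values$data), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(sm$values$data, rec$values$data)))
})
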