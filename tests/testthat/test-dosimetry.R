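sp48 <- c(4.8, 4.8, 4.8)

uniform_vol <- function(value, d = c(8, 8, 4), units = "") {
  voxel_volume(array(value, d), sp48, units = units)
}

test_that("the dose equation reproduces its analytic values", {
  act <- uniform_vol(1e6, units = "Bq/ml")     # 1 MBq/ml
  expect_equal(unique(as.numeric(dose_map(act, uniform_vol(1.0))$data)), 15.87)
  expect_equal(unique(as.numeric(dose_map(act, uniform_vol(1.06))$data)),
               15.87 / 1.06)
  expect_equal(unique(as.numeric(dose_map(act, uniform_vol(0.3))$data)),
               15.87 / 0.3)
  expect_equal(round(15.87 / 0.3, 1), 52.9)
  expect_true(all(dose_map(uniform_vol(0), uniform_vol(1))$data == 0))
  expect_error(dose_map(act, uniform_vol(0)), "zero density")
})

test_that("dose is linear in activity and inverse in density", {
  set.seed(3)
  a <- voxel_volume(array(runif(256) * 1e6, c(8, 8, 4)), sp48, units = "Bq/ml")
  d1 <- dose_map(a, uniform_vol(1.0))
  a2 <- a; a2$data <- 2 * a$data
  expect_equal(dose_map(a2, uniform_vol(1.0))$data, 2 * d1$data)
  expect_equal(dose_map(a, uniform_vol(2.0))$data, d1$data / 2)
})

test_that("energy bookkeeping closes: body-integrated energy equals
           15.87 mJ per administered MBq", {
  ph <- small_phantom()
  admin <- 1000
  td <- true_dose_map(ph, admin)
  # energy [J] = dose [Gy] * mass [kg]
  mass_kg <- ph$density$data * voxel_size_ml(ph$labels) / 1000
  expect_equal(sum(td$data * mass_kg), 15.87e-3 * admin, tolerance = 1e-9)
})

test_that("rescaling fixes the integral and is idempotent", {
  rec <- uniform_vol(2, units = "Bq/ml")
  scaled <- rescale_to_administered(rec, 250)
  expect_equal(total_activity_mbq(scaled), 250, tolerance = 1e-12)
  # doubling the input halves nothing after rescale (shape-only)
  rec2 <- uniform_vol(4, units = "Bq/ml")
  expect_equal(rescale_to_administered(rec2, 250)$data, scaled$data)
  expect_equal(rescale_to_administered(scaled, 250)$data, scaled$data)
  expect_error(rescale_to_administered(uniform_vol(0), 250), "zero total")
  expect_error(rescale_to_administered(rec, 0), "> 0")
})

test_that("ellipsoid VOIs voxelise to their analytic volume", {
  grid <- voxel_volume(array(0, c(48, 48, 48)), c(2, 2, 2))
  r <- 20
  voi <- make_ellipsoid_voi(c(47, 47, 47), rep(r, 3), grid)
  analytic_ml <- 4 / 3 * pi * r^3 / 1000
  shell_ml <- 4 * pi * r^2 * 2 / 1000  # one-voxel shell
  expect_lt(abs(voi$volume_ml - analytic_ml), shell_ml)
  expect_equal(make_ellipsoid_voi(c(47, 47, 47), c(0, 0, 0), grid)$volume_ml, 0)
})

test_that("Tc thresholding recovers the healthy liver (Dice >= 0.85)", {
  ph <- std_phantom()
  seg <- segment_healthy_from_tc(std_tc_recon())
  expect_gte(dice(seg$mask, organ_mask(ph, "healthy")), 0.85)
  # threshold above the maximum -> empty mask with a warning
  expect_warning(empty <- segment_healthy_from_tc(std_tc_recon(),
                                                  threshold_fraction = 1.5),
                 "empty")
  expect_equal(empty$volume_ml, 0)
})

test_that("tumour segmentation on the Ho image recovers the lesion", {
  ph <- std_phantom()
  healthy <- segment_healthy_from_tc(std_tc_recon())
  seg <- segment_tumor_from_ho(std_ho_recon(), healthy)
  expect_gte(dice(seg$mask, organ_mask(ph, "tumor")), 0.7)
  # a phantom without any tumour organ yields an empty tumour VOI
  organs0 <- Filter(function(o) o$name != "tumor", small_organs())
  ph0 <- build_phantom(small_spec(organs = organs0))
  flat <- segment_tumor_from_ho(ph0$ho_activity,
                                organ_mask(ph0, "healthy"),
                                threshold_fraction = 0.4)
  expect_equal(flat$volume_ml, 0)
})

test_that("lung delineation shrinks strictly under the 2 cm erosion", {
  ph <- std_phantom()
  raw <- lung_mask(ph$mu_81, shrink_cm = 0, mu_soft = 0.18)
  shrunk <- lung_mask(ph$mu_81, shrink_cm = 2, mu_soft = 0.18)
  expect_gt(raw$volume_ml, shrunk$volume_ml)
  expect_gt(shrunk$volume_ml, 0)
  expect_true(all(shrunk$mask <= raw$mask))  # erosion is a subset
  expect_equal(dice(raw$mask, organ_mask(ph, "lung")), 1)
  expect_warning(lung_mask(ph$mu_81, shrink_cm = 50, mu_soft = 0.18), "empty")
})

test_that("the 25 ml minimum-volume rule is a sharp boundary", {
  vox_ml <- prod(sp48) / 1000
  n_under <- floor(24.9 / vox_ml)
  n_over <- ceiling(25.0 / vox_ml)
  d <- c(40, 40, 10)
  m_under <- array(FALSE, d); m_under[seq_len(n_under)] <- TRUE
  m_over <- array(FALSE, d); m_over[seq_len(n_over)] <- TRUE
  expect_false(enforce_min_volume(voi_mask(m_under, "A", sp48))$accepted)
  expect_true(enforce_min_volume(voi_mask(m_over, "B", sp48))$accepted)
  empty <- voi_mask(array(FALSE, d), "C", sp48)
  rej <- enforce_min_volume(empty)
  expect_false(rej$accepted)
  expect_match(rej$reason, "below minimum")
})

test_that("mean VOI dose averages exactly and rejects empty VOIs", {
  d <- c(8, 8, 4)
  dose <- uniform_vol(10, d, units = "Gy")
  m <- array(FALSE, d); m[1:10] <- TRUE
  expect_equal(mean_voi_dose(dose, voi_mask(m, "X", sp48)), 10)
  checker <- array(rep(c(0, 20), length.out = prod(d)), d)
  expect_equal(mean_voi_dose(voxel_volume(checker, sp48),
                             voi_mask(array(TRUE, d), "Y", sp48)), 10)
  expect_error(mean_voi_dose(dose, voi_mask(array(FALSE, d), "Z", sp48)),
               "empty VOI")
})

test_that("dose_report returns one tidy row per VOI with the volume rule", {
  d <- c(40, 40, 10)
  dose <- uniform_vol(5, d, units = "Gy")
  big <- array(FALSE, d); big[seq_len(300)] <- TRUE
  tiny <- array(FALSE, d); tiny[1:10] <- TRUE
  rep <- dose_report(dose, list(voi_mask(big, "BIG", sp48),
                                voi_mask(tiny, "TINY", sp48)),
                     administered_mbq = 250)
  expect_s3_class(rep, "tbl_df")
  expect_equal(rep$accepted, c(TRUE, FALSE))
  expect_equal(rep$mean_dose_gy, c(5, NA_real_))
  expect_equal(unique(rep$administered_mbq), 250)
})
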