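test_that("pairwise subtraction and repetition averaging follow the FAIR convention", {
  d <- tibble::tibble(
    ti_ms = 2000,
    condition = rep(c("selective", "nonselective"), each = 2),
    repetition = c(1, 2, 1, 2),
    signal = c(10, 12, 8, 9)
  )
  out <- compute_delta_m(d)
  expect_equal(out$dm, 2.5)
  expect_equal(out$mc, 8.5)
  expect_equal(out$ti, 2)
  # opposite sign convention flips dm only
  out2 <- compute_delta_m(d, sign = "nonselective_minus_selective")
  expect_equal(out2$dm, -2.5)
  expect_equal(out2$mc, 8.5)
})

test_that("identical conditions give an identically zero difference signal", {
  d <- tidyr::expand_grid(ti_ms = c(200, 1000), repetition = 1:5,
                          condition = c("selective", "nonselective")) |>
    dplyr::mutate(signal = 3 + ti_ms / 1000)
  expect_equal(compute_delta_m(d)$dm, c(0, 0))
})

test_that("mismatched repetition counts are a structural error", {
  d <- tibble::tibble(
    ti_ms = 200,
    condition = c("selective", "selective", "nonselective"),
    repetition = c(1, 2, 1),
    signal = c(1, 2, 3)
  )
  expect_error(compute_delta_m(d), class = "bcsfbasl_structure_error")
})

test_that("duplicate schedule entries stay independent observations", {
  s <- simulate_subject_series(
    "bcsfb", params = list(m0 = 100, t1_csf = 3.31, water_delivery = 0.55,
                           ventricular_volume = 1.02),
    snr_dm = Inf, snr_mc = Inf)
  out <- compute_delta_m(s)
  expect_equal(nrow(out), 8)
  expect_equal(sum(out$ti == 0.2), 2)
})

test_that("voxel volume follows the acquisition geometry", {
  expect_equal(voxel_volume_from_geometry(c(20, 20), c(32, 32), 2.4),
               0.9375)
  expect_equal(12 * voxel_volume_from_geometry(c(20, 20), c(32, 32), 2.4),
               11.25)
  expect_equal(voxel_volume_from_geometry(c(20, 16), c(200, 160), 0.4),
               0.004)
  expect_equal(voxel_volume_from_geometry(c(1, 1), c(1, 1), 1), 1)
  expect_error(voxel_volume_from_geometry(c(0, 20), c(32, 32), 2.4),
               "positive")
})

test_that("ventricular volume counts voxels, is additive and order-invariant", {
  set.seed(5)
  slices <- lapply(1:6, function(i) matrix(runif(50) < 0.2, 10, 5))
  k <- sum(vapply(slices, sum, numeric(1)))
  expect_equal(ventricular_volume(slices), k * 0.004)
  expect_equal(ventricular_volume(rev(slices)), k * 0.004)
  per_slice <- vapply(slices, function(s) ventricular_volume(list(s)),
                      numeric(1))
  expect_equal(sum(per_slice), ventricular_volume(slices))
  expect_warning(v0 <- ventricular_volume(array(FALSE, c(4, 4, 2))),
                 "Empty")
  expect_equal(v0, 0)
})

test_that("M0 correction rescales by the volume ratio", {
  expect_equal(m0_corr(1000, 1.60, 11.25), 1000 * 1.60 / 11.25)
  expect_equal(m0_corr(123, 11.25, 11.25), 123)
  expect_equal(m0_corr(10, 2.4, 11.25), 2 * m0_corr(10, 1.2, 11.25))
  # invariant under joint rescaling of both volumes
  expect_equal(m0_corr(10, 1.5, 11.25), m0_corr(10, 3.0, 22.5))
  expect_error(m0_corr(10, 1.5, 0), "positive")
})

test_that("ventriculomegaly screen flags leave-one-out outliers only", {
  rec <- tibble::tibble(
    subject_id = sprintf("S%d", 1:4),
    genotype = "control", age_weeks = 8,
    ventricular_volume = c(1.0, 1.1, 0.9, 4.2)
  )
  out <- flag_ventriculomegaly(rec, multiplier = 3)
  expect_equal(out$excluded, c(FALSE, FALSE, FALSE, TRUE))
  expect_match(out$exclusion_reason[4], "ventriculomegaly")

  rec_eq <- dplyr::mutate(rec, ventricular_volume = 1.5)
  expect_false(any(flag_ventriculomegaly(rec_eq)$excluded))

  # the observed case: one subject at ~4x its group mean
  rec4 <- tibble::tibble(genotype = "3xTg", age_weeks = 32,
                         ventricular_volume = c(rep(1.8, 9), 7.2))
  expect_true(flag_ventriculomegaly(rec4)$excluded[10])

  singleton <- tibble::tibble(genotype = c("a", "a", "b"), age_weeks = 8,
                              ventricular_volume = c(1, 1.1, 100))
  expect_warning(out_s <- flag_ventriculomegaly(singleton), "Singleton")
  expect_false(any(out_s$excluded))
})

test_that("noise-free subject quantification recovers generating values", {
  asl <- make_clean_subject()
  rec <- quantify_subject(asl, ventricular_volume = 1.02)
  expect_equal(rec$cbf_cortex, 185, tolerance = 1e-3)
  expect_equal(rec$t1_cortex, 1.8, tolerance = 1e-5)
  expect_equal(rec$t1_csf, 3.31, tolerance = 1e-5)
  expect_equal(rec$m0_csf, 100, tolerance = 1e-5)
  expect_equal(rec$m0_corr, 100 * 1.02 / 11.25, tolerance = 1e-5)
  expect_equal(rec$water_delivery, 0.55, tolerance = 1e-3)
})

test_that("a subject without BCSFB data degrades gracefully", {
  asl <- make_clean_subject() |>
    dplyr::filter(protocol == "standard")
  rec <- quantify_subject(asl, ventricular_volume = 1.02)
  expect_equal(rec$cbf_cortex, 185, tolerance = 1e-3)
  expect_true(is.na(rec$water_delivery))
  expect_match(rec$flags, "bcsfb")
})

test_that("series round-trip through CSV preserves the quantification", {
  asl <- make_clean_subject() |>
    dplyr::mutate(subject_id = "S001", .before = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_asl_series(asl, path)
  back <- read_asl_series(path)
  rec <- quantify_subject(back, ventricular_volume = 1.02)
  expect_equal(rec$water_delivery, 0.55, tolerance = 1e-3)
})
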