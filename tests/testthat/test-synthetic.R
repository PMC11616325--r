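test_that("generators are pure functions of their seed", {
  p <- list(m0 = 100, t1_csf = 3.31, water_delivery = 0.55,
            ventricular_volume = 1.02)
  s1 <- simulate_subject_series("bcsfb", p, seed = 4)
  s2 <- simulate_subject_series("bcsfb", p, seed = 4)
  expect_identical(s1, s2)
  expect_false(identical(
    s1$signal, simulate_subject_series("bcsfb", p, seed = 5)$signal))

  ph1 <- simulate_micro_volume(seed = 6)
  ph2 <- simulate_micro_volume(seed = 6)
  expect_identical(ph1$volume, ph2$volume)
})

test_that("infinite SNR reproduces the forward curves exactly", {
  p <- list(m0 = 100, t1_csf = 3.31, water_delivery = 0.55,
            ventricular_volume = 1.02)
  s <- simulate_subject_series("bcsfb", p, snr_dm = Inf, snr_mc = Inf)
  out <- compute_delta_m(s)
  ti <- asl_protocol("bcsfb")$ti_s
  m0c <- m0_corr(100, 1.02)
  expect_equal(out$dm,
               bcsfb_signal(ti, 0.55, m0c, 1.02, 3.31,
                            transit_time = kinetic_defaults()$transit_time_bcsfb),
               tolerance = 1e-12)
  expect_equal(out$mc, ir_signal(ti, 100, 3.31), tolerance = 1e-12)
})

test_that("per-TI SNR of the averaged series matches the requested level", {
  set.seed(107)
  p <- list(m0 = 100, t1_tissue = 1.8, cbf = 185)
  reps <- replicate(400, {
    s <- simulate_subject_series("standard", p, snr_dm = 10, snr_mc = 100)
    compute_delta_m(s)$dm
  })
  ti <- asl_protocol("standard")$ti_s
  clean <- buxton_tissue_signal(
    ti, 185, 100, 1.8,
    transit_time = kinetic_defaults()$transit_time_tissue)
  noise_sd <- apply(reps - clean, 1, sd)
  # by construction the averaged difference carries sd = peak/SNR at each TI
  expect_equal(mean(noise_sd) / (max(clean) / 10), 1, tolerance = 0.15)
  # empirical mean over many repetitions converges on the clean curve
  expect_equal(rowMeans(reps), clean, tolerance = 0.05 * max(clean))
})

test_that("default cohort has the study's group structure", {
  co <- simulate_cohort(seed = 11)
  expect_equal(nrow(co), 71)
  sizes <- co |> dplyr::count(genotype, age_weeks)
  expect_equal(sizes$n[sizes$genotype == "control"], c(10, 7, 7, 7))
  expect_equal(sizes$n[sizes$genotype == "3xTg"], rep(10, 4))
  expect_equal(dplyr::n_distinct(co$subject_id), 71)

  spec1 <- default_cohort_spec()
  spec1$n <- rep(1L, 8)
  expect_equal(nrow(simulate_cohort(spec1, seed = 12)), 8)
})

test_that("drawn parameters converge on the specified cell means", {
  spec <- default_cohort_spec()[1, ]
  spec$n <- 10000L
  co <- simulate_cohort(spec, seed = 13, params_only = TRUE)
  # draws are normal truncated at zero, so the large-n mean is the
  # truncated-normal mean mu + sd phi(a)/(1 - Phi(a)), a = -mu/sd
  tn_mean <- function(mu, sd) {
    a <- -mu / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
  }
  expect_equal(mean(co$true_water_delivery),
               tn_mean(spec$water_delivery_mean, spec$water_delivery_sd),
               tolerance = 0.01)
  expect_equal(mean(co$true_t1_csf),
               tn_mean(spec$t1_csf_mean, spec$t1_csf_sd), tolerance = 0.01)
  expect_equal(mean(co$true_cbf_cortex),
               tn_mean(spec$cbf_cortex_mean, spec$cbf_cortex_sd),
               tolerance = 0.01)
})

test_that("ventricle masks realise the requested volume to within one voxel", {
  for (v in c(0.3, 1.02, 1.6, 2.5)) {
    mask <- simulate_ventricle_mask(v)
    expect_lt(abs(ventricular_volume(mask) - v), 0.004 + 1e-12)
  }
  mask <- simulate_ventricle_mask(1.02)
  expect_equal(sum(mask), 255)
  expect_equal(dim(mask), c(200, 160, 6))
})

test_that("cohort generation is snapped to the anatomical voxel grid", {
  spec <- default_cohort_spec()[c(1, 5), ]
  spec$n <- c(3L, 3L)
  co <- simulate_cohort(spec, seed = 17)
  vox <- anatomical_geometry()$voxel_volume_mm3
  expect_equal(co$ventricular_volume, co$vent_voxels * vox)
  for (i in seq_len(nrow(co))) {
    m <- simulate_ventricle_mask(co$ventricular_volume[i])
    expect_equal(sum(m), co$vent_voxels[i])
  }
})

test_that("micro phantom without CP is pure Rayleigh inside the mask", {
  ph <- simulate_micro_volume(cp_volume_ul = 0, sigma = 2.5, seed = 19)
  fit <- fit_rayleigh(ph$volume[ph$mask])
  expect_lt(abs(fit$sigma / 2.5 - 1), 0.02)
  expect_error(simulate_micro_volume(cp_volume_ul = 10), "exceeds")
})

test_that("end-to-end cohort recovery: fitted group means track generating means", {
  co <- simulate_cohort(seed = 23)
  rec <- quantify_cohort(co)
  expect_equal(nrow(rec), 71)
  chk <- rec |>
    dplyr::filter(!excluded) |>
    dplyr::group_by(genotype, age_weeks) |>
    dplyr::summarise(
      wd_hat = mean(water_delivery), wd_true = mean(true_water_delivery),
      wd_sem = sd(water_delivery) / sqrt(dplyr::n()),
      cbf_hat = mean(cbf_cortex), cbf_true = mean(true_cbf_cortex),
      cbf_sem = sd(cbf_cortex) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  expect_true(all(abs(chk$wd_hat - chk$wd_true) <= 2 * chk$wd_sem))
  expect_true(all(abs(chk$cbf_hat - chk$cbf_true) <= 2 * chk$cbf_sem))
})

test_that("quantified synthetic cohort reproduces the headline group effect", {
  co <- simulate_cohort(seed = 29)
  rec <- quantify_cohort(co)
  summ <- summarise_cohort(rec, "water_delivery") |>
    tidyr::pivot_wider(names_from = genotype,
                       values_from = c(n, mean, sem))
  excess <- summ$`mean_3xTg` / summ$mean_control - 1
  expect_true(all(excess > 0.3))
  cmp <- compare_groups(rec)
  wd <- dplyr::filter(cmp, variable == "water_delivery")
  # the genotype effect is detectable at every age; after FDR over the
  # whole MRI family (which is mostly null here) most ages survive
  expect_true(all(wd$p_raw < 0.05))
  expect_gte(sum(wd$reject), 3)
})
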