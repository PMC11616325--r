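#' Default cohort specification
#'
#' Group-level generative parameters for the synthetic cohort, one row per
#' (genotype, age) cell. MRI means and SEMs are the study's group summary
#' values (total BCSFB water delivery, T1 of CSF, ventricular volume, and
#' CBF in cortex/hippocampus/midbrain); generative SDs are reconstructed as
#' SEM * sqrt(n). Tissue T1 is set to 1.8 s (typical cortical value at
#' 9.4 T) in every cell. Y-maze parameters at 20 and 32 weeks follow the
#' reported entries and %SA summaries; at 8 and 14 weeks (not reported) the
#' 3xTg cells are given control-like values, since behavioural deficits
#' emerge only from 20 weeks.
#'
#' @return A tibble with columns `genotype`, `age_weeks`, `n` and
#'   `<param>_mean` / `<param>_sd` pairs for `water_delivery` (uL/min),
#'   `t1_csf` (s), `ventricular_volume` (mm^3), `cbf_cortex`,
#'   `cbf_hippocampus`, `cbf_midbrain` (mL/100 g/min), `t1_tissue` (s),
#'   `n_entries` and `sa` (percent).
#' @export
default_cohort_spec <- function() {
  spec <- tibble::tibble(
    genotype = rep(c("control", "3xTg"), each = 4),
    age_weeks = rep(c(8, 14, 20, 32), 2),
    n = c(10, 7, 7, 7, 10, 10, 10, 10),
    water_delivery_mean = c(0.55, 0.80, 0.81, 0.74, 1.13, 1.34, 1.39, 1.32),
    water_delivery_sem  = c(0.09, 0.07, 0.06, 0.11, 0.10, 0.04, 0.09, 0.09),
    t1_csf_mean = c(3.31, 3.38, 3.81, 3.73, 3.64, 3.65, 3.89, 3.81),
    t1_csf_sem  = c(0.13, 0.17, 0.04, 0.19, 0.03, 0.08, 0.04, 0.04),
    ventricular_volume_mean = c(1.02, 1.52, 1.83, 1.89,
                                1.60, 1.59, 1.82, 1.72),
    ventricular_volume_sem  = c(0.19, 0.21, 0.09, 0.29,
                                0.11, 0.10, 0.04, 0.12),
    cbf_cortex_mean = c(185, 181, 197, 167, 208, 206, 217, 235),
    cbf_cortex_sem  = c(11, 6, 9, 17, 5, 5, 6, 11),
    cbf_hippocampus_mean = c(246, 235, 252, 222, 255, 259, 267, 257),
    cbf_hippocampus_sem  = c(6, 3, 5, 17, 6, 6, 8, 10),
    cbf_midbrain_mean = c(258, 231, 234, 205, 263, 247, 251, 222),
    cbf_midbrain_sem  = c(6, 6, 7, 16, 4, 6, 4, 5),
    t1_tissue_mean = 1.8,
    t1_tissue_sem = 0.02,
    n_entries_mean = c(40, 40, 41, 28, 40, 38, 22, 16),
    n_entries_sem  = c(8, 8, 8, 4, 8, 8, 7, 6),
    sa_mean = c(60, 60, 61, 63, 60, 58, 45, 53),
    sa_sem  = c(8, 8, 8, 6, 8, 8, 14, 8)
  )
  # generative SD reconstructed from the printed SEM and cell size
  for (v in c("water_delivery", "t1_csf", "ventricular_volume",
              "cbf_cortex", "cbf_hippocampus", "cbf_midbrain",
              "t1_tissue", "n_entries", "sa")) {
    spec[[paste0(v, "_sd")]] <- spec[[paste0(v, "_sem")]] * sqrt(spec$n)
  }
  spec
}

# truncated-at-zero normal draw (resampling): keeps small-SD cells physical
rtnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate one subject's paired FAIR-ASL series
#'
#' Generates the raw long-format table of slice-selective and non-selective
#' ROI signals for one protocol, per TI and repetition. The non-selective
#' (control) signal is the inversion-recovery curve plus Gaussian noise;
#' the selective signal is the same control realisation plus the forward
#' kinetic difference signal plus Gaussian noise. Noise levels are
#' expressed as per-TI SNR of the repetition-averaged series: `snr_mc`
#' relative to M0 (so `snr_mc = 100` is 1% of M0), `snr_dm` relative to the
#' peak of the clean difference curve. `Inf` disables noise.
#'
#' @param protocol An [asl_protocol()] or protocol name.
#' @param params Named list of generating parameters. For `standard`:
#'   `m0`, `t1_tissue`, `cbf`, optional `transit_time`. For `bcsfb`: `m0`
#'   (CSF ROI M0), `t1_csf`, `water_delivery`, `ventricular_volume`,
#'   optional `transit_time`.
#' @param snr_dm,snr_mc Per-TI SNR of the averaged difference and control
#'   series.
#' @param constants Kinetic constants ([kinetic_defaults()]).
#' @param roi ROI label stamped on the output rows.
#' @param seed Optional integer seed.
#' @return Long tibble with columns `protocol`, `roi`, `acquisition`,
#'   `ti_ms`, `condition`, `repetition`, `signal`.
#' @export
simulate_subject_series <- function(protocol, params, snr_dm = 10,
                                    snr_mc = 100,
                                    constants = kinetic_defaults(),
                                    roi = NULL, seed = NULL) {
  if (is.character(protocol)) protocol <- asl_protocol(protocol)
  if (!inherits(protocol, "asl_protocol")) abort("Invalid protocol.")
  run <- function() {
    ti <- protocol$ti_s
    n_acq <- length(ti)
    reps <- protocol$repetitions
    mc_clean <- ir_signal(ti, params$m0,
                          if (protocol$name == "standard")
                            params$t1_tissue else params$t1_csf)
    if (protocol$name == "standard") {
      tt <- params$transit_time %||% constants$transit_time_tissue
      dm_clean <- buxton_tissue_signal(
        ti, cbf = params$cbf, m0_tissue = params$m0,
        t1_tissue = params$t1_tissue, t1_blood = constants$t1_blood,
        lambda = constants$lambda, alpha = constants$alpha,
        transit_time = tt, tissue_density = constants$tissue_density)
      roi <- roi %||% "cortex"
    } else {
      tt <- params$transit_time %||% constants$transit_time_bcsfb
      m0c <- m0_corr(params$m0, params$ventricular_volume,
                     protocol$roi_volume_mm3)
      dm_clean <- bcsfb_signal(
        ti, water_delivery = params$water_delivery, m0_corr = m0c,
        ventricular_volume = params$ventricular_volume,
        t1_csf = params$t1_csf, t1_blood = constants$t1_blood,
        alpha = constants$alpha, transit_time = tt)
      roi <- roi %||% "ventricles"
    }
    # per-repetition noise scaled so the repetition-averaged series has the
    # requested per-TI SNR
    sd_mc <- if (is.finite(snr_mc)) params$m0 / snr_mc * sqrt(reps) else 0
    sd_dm <- if (is.finite(snr_dm))
      max(abs(dm_clean)) / snr_dm * sqrt(reps) else 0
    grid <- tidyr::expand_grid(acquisition = seq_len(n_acq),
                               repetition = seq_len(reps))
    ns <- mc_clean[grid$acquisition] + rnorm(nrow(grid), 0, sd_mc)
    sel <- ns + dm_clean[grid$acquisition] + rnorm(nrow(grid), 0, sd_dm)
    dplyr::bind_rows(
      grid |> dplyr::mutate(condition = "nonselective", signal = ns),
      grid |> dplyr::mutate(condition = "selective", signal = sel)
    ) |>
      dplyr::mutate(protocol = protocol$name, roi = roi,
                    ti_ms = ti[.data$acquisition] * 1000) |>
      dplyr::select("protocol", "roi", "acquisition", "ti_ms",
                    "condition", "repetition", "signal") |>
      dplyr::arrange(.data$acquisition, .data$repetition, .data$condition)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a full cohort
#'
#' Draws subject-wise generating parameters from the per-cell distributions
#' of a cohort specification (normal, truncated at zero), then generates
#' per-subject standard-ASL series for the three tissue ROIs, a BCSFB-ASL
#' series for the ventricular ROI, and a Y-maze entry sequence. The default
#' specification yields 71 subjects in the study's group structure
#' (control n = 10, 7, 7, 7 and 3xTg n = 10 per age).
#'
#' @param spec Cohort specification, see [default_cohort_spec()].
#' @param seed Integer seed; the whole cohort is a pure function of
#'   `(spec, seed)`.
#' @param snr_dm,snr_mc Noise levels passed to
#'   [simulate_subject_series()].
#' @param m0 Equilibrium magnetization used for every simulated ROI
#'   (arbitrary units).
#' @param constants Kinetic constants.
#' @param params_only If `TRUE`, return only the drawn subject parameters
#'   (no ASL series or entry sequences) — useful for studying the parameter
#'   distributions at large n.
#' @return A manifest tibble with one row per subject: `subject_id`,
#'   `genotype`, `age_weeks`, the drawn true parameters (`true_*`),
#'   `ventricular_volume` (the drawn anatomical volume, mm^3),
#'   `vent_voxels` (its anatomical-grid voxel count), list-columns `asl`
#'   (long ASL table) and `entries` (arm-entry vector).
#' @export
simulate_cohort <- function(spec = default_cohort_spec(), seed = 1,
                            snr_dm = 10, snr_mc = 100, m0 = 100,
                            constants = kinetic_defaults(),
                            params_only = FALSE) {
  withr::with_seed(seed, {
    vox <- anatomical_geometry()$voxel_volume_mm3
    subjects <- spec |>
      dplyr::rowwise() |>
      dplyr::reframe(
        genotype = rep(.data$genotype, .data$n),
        age_weeks = rep(.data$age_weeks, .data$n),
        true_water_delivery = rtnorm_pos(.data$n, .data$water_delivery_mean,
                                         .data$water_delivery_sd),
        true_t1_csf = rtnorm_pos(.data$n, .data$t1_csf_mean,
                                 .data$t1_csf_sd),
        true_ventricular_volume = rtnorm_pos(
          .data$n, .data$ventricular_volume_mean,
          .data$ventricular_volume_sd),
        true_cbf_cortex = rtnorm_pos(.data$n, .data$cbf_cortex_mean,
                                     .data$cbf_cortex_sd),
        true_cbf_hippocampus = rtnorm_pos(.data$n,
                                          .data$cbf_hippocampus_mean,
                                          .data$cbf_hippocampus_sd),
        true_cbf_midbrain = rtnorm_pos(.data$n, .data$cbf_midbrain_mean,
                                       .data$cbf_midbrain_sd),
        true_t1_tissue = rtnorm_pos(.data$n, .data$t1_tissue_mean,
                                    .data$t1_tissue_sd),
        true_n_entries = pmax(3L, round(rtnorm_pos(
          .data$n, .data$n_entries_mean, .data$n_entries_sd))),
        true_sa = pmin(100, rtnorm_pos(.data$n, .data$sa_mean, .data$sa_sd))
      ) |>
      dplyr::mutate(subject_id = sprintf("S%03d", dplyr::row_number()),
                    .before = 1)

    # snap the drawn volume to the anatomical voxel grid so that a mask
    # realising it reproduces the volume to within one voxel
    subjects$vent_voxels <- pmax(1L, as.integer(round(
      subjects$true_ventricular_volume / vox)))
    subjects$ventricular_volume <- subjects$vent_voxels * vox

    if (!params_only) {
      subjects$asl <- purrr::pmap(subjects, function(...) {
        s <- list(...)
        tissue <- purrr::map2_dfr(
          c("cortex", "hippocampus", "midbrain"),
          list(s$true_cbf_cortex, s$true_cbf_hippocampus,
               s$true_cbf_midbrain),
          function(rname, rcbf) {
            simulate_subject_series(
              "standard",
              params = list(m0 = m0, t1_tissue = s$true_t1_tissue,
                            cbf = rcbf),
              snr_dm = snr_dm, snr_mc = snr_mc, constants = constants,
              roi = rname)
          })
        bcsfb <- simulate_subject_series(
          "bcsfb",
          params = list(m0 = m0, t1_csf = s$true_t1_csf,
                        water_delivery = s$true_water_delivery,
                        ventricular_volume = s$ventricular_volume),
          snr_dm = snr_dm, snr_mc = snr_mc, constants = constants)
        dplyr::bind_rows(tissue, bcsfb)
      })
      subjects$entries <- purrr::map2(
        subjects$true_n_entries, subjects$true_sa,
        ~ simulate_entries(.x, p_alternate_for_sa(.y)))
    }
    subjects
  })
}

#' Simulate a ventricular segmentation mask
#'
#' Builds a compact (quasi-ellipsoidal) binary mask on the anatomical grid
#' whose voxel count realises the requested volume exactly (to the nearest
#' voxel): the `round(volume / voxel_volume)` grid voxels closest to the
#' stack centre under anisotropy-corrected distance are selected.
#'
#' @param volume_mm3 Target ventricular volume.
#' @param geometry Anatomical grid geometry, see [anatomical_geometry()].
#' @return A logical array `matrix x slices`.
#' @export
simulate_ventricle_mask <- function(volume_mm3,
                                    geometry = anatomical_geometry()) {
  vox <- geometry$voxel_volume_mm3
  k <- max(1L, as.integer(round(volume_mm3 / vox)))
  dims <- c(geometry$matrix_size, geometry$n_slices)
  if (k > prod(dims)) abort("Requested volume exceeds the grid.")
  sp <- c(geometry$fov_mm / geometry$matrix_size,
          geometry$slice_thickness_mm)
  ctr <- (dims + 1) / 2
  d2 <- outer(((seq_len(dims[1]) - ctr[1]) * sp[1])^2,
              ((seq_len(dims[2]) - ctr[2]) * sp[2])^2, "+")
  d3 <- outer(as.vector(d2), ((seq_len(dims[3]) - ctr[3]) * sp[3])^2, "+")
  mask <- array(FALSE, dims)
  mask[order(d3)[seq_len(k)]] <- TRUE
  mask
}

#' Simulate an ex-vivo micro-MRI volume with embedded choroid plexus
#'
#' Generates a high-resolution magnitude volume: Rayleigh-distributed noise
#' everywhere (free fluid / background), an ellipsoidal ventricle mask, and
#' a connected bright cluster of the requested volume inside the mask whose
#' intensity follows a Rician distribution with amplitude
#' `contrast_over_sigma * sigma` — the bright-CP-on-noise structure that
#' [cp_volume()] segments.
#'
#' @param cp_volume_ul Ground-truth CP volume, uL.
#' @param contrast_over_sigma CP amplitude in units of the Rayleigh scale.
#' @param sigma Rayleigh scale of the noise.
#' @param voxel_size_mm Isotropic voxel edge, mm (default 0.05 mm, i.e.
#'   1.25e-4 uL voxels).
#' @param dims Grid dimensions.
#' @param mask_semiaxes Ellipsoid semi-axes of the ventricle mask, voxels.
#' @param seed Optional integer seed.
#' @return List with `volume` (array), `mask` (logical array),
#'   `voxel_volume_ul`, `n_cp_voxels`, `cp_volume_ul`.
#' @export
simulate_micro_volume <- function(cp_volume_ul = 0.0782,
                                  contrast_over_sigma = 8, sigma = 1,
                                  voxel_size_mm = 0.05,
                                  dims = c(48, 48, 48),
                                  mask_semiaxes = c(14, 14, 11),
                                  seed = NULL) {
  run <- function() {
    vox_ul <- voxel_size_mm^3
    ctr <- (dims + 1) / 2
    ex <- outer(((seq_len(dims[1]) - ctr[1]) / mask_semiaxes[1])^2,
                ((seq_len(dims[2]) - ctr[2]) / mask_semiaxes[2])^2, "+")
    e3 <- outer(as.vector(ex),
                ((seq_len(dims[3]) - ctr[3]) / mask_semiaxes[3])^2, "+")
    mask <- array(e3 <= 1, dims)
    k <- as.integer(round(cp_volume_ul / vox_ul))
    if (k > sum(mask))
      abort("CP volume exceeds the ventricle mask volume.")
    # compact connected cluster: k mask voxels nearest an interior point
    anchor <- ctr + c(mask_semiaxes[1] / 3, 0, 0)
    idx <- which(mask, arr.ind = TRUE)
    dcp <- (idx[, 1] - anchor[1])^2 + (idx[, 2] - anchor[2])^2 +
      (idx[, 3] - anchor[3])^2
    cp_idx <- idx[order(dcp)[seq_len(k)], , drop = FALSE]
    n_tot <- prod(dims)
    vol <- array(sigma * sqrt(rnorm(n_tot)^2 + rnorm(n_tot)^2), dims)
    if (k > 0) {
      a <- contrast_over_sigma * sigma
      vol[cp_idx] <- sqrt((a + rnorm(k, 0, sigma))^2 +
                            rnorm(k, 0, sigma)^2)
    }
    list(volume = vol, mask = mask, voxel_volume_ul = vox_ul,
         n_cp_voxels = k, cp_volume_ul = k * vox_ul)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
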