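#' Pairwise perfusion-weighted difference and control series
#'
#' Collapses raw repeated FAIR acquisitions into the repetition-averaged
#' \eqn{[TI, \Delta M]} and \eqn{[TI, M_c]} datasets used for fitting. For
#' each acquisition the slice-selective and non-selective images are paired
#' by repetition index and subtracted; repeated measures at each inflow time
#' are then averaged. The control signal \eqn{M_c} is the repetition mean of
#' the non-selective condition.
#'
#' @param data Long-format data frame with columns `ti_ms`, `condition`
#'   (`"selective"` or `"nonselective"`), `repetition` and `signal`. An
#'   optional `acquisition` column distinguishes repeated schedule entries at
#'   the same TI (the BCSFB schedule acquires TI = 200 ms twice); without it,
#'   rows are grouped by TI alone.
#' @param sign Subtraction convention. The default,
#'   `"selective_minus_nonselective"`, makes the perfusion-weighted signal of
#'   the forward models positive.
#' @return A tibble with one row per acquisition: `ti` (seconds), `n_rep`,
#'   `mc` and `dm`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   ti_ms = 2000, condition = rep(c("selective", "nonselective"), each = 2),
#'   repetition = c(1, 2, 1, 2), signal = c(10, 12, 8, 9)
#' )
#' compute_delta_m(d) # dm = 2.5, mc = 8.5
compute_delta_m <- function(data,
                            sign = c("selective_minus_nonselective",
                                     "nonselective_minus_selective")) {
  sign <- match.arg(sign)
  required <- c("ti_ms", "condition", "repetition", "signal")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  if (!all(data$condition %in% c("selective", "nonselective")))
    abort("`condition` must be 'selective' or 'nonselective'.")
  if (!("acquisition" %in% names(data))) {
    data <- data |>
      dplyr::mutate(acquisition = dplyr::dense_rank(.data$ti_ms))
  }

  wide <- data |>
    dplyr::select("acquisition", "ti_ms", "condition", "repetition",
                  "signal") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "signal")
  if (anyNA(wide$selective) || anyNA(wide$nonselective))
    abort("Unequal repetition counts between conditions at some TI.",
          class = "bcsfbasl_structure_error")

  s <- if (sign == "selective_minus_nonselective") 1 else -1
  wide |>
    dplyr::group_by(.data$acquisition, .data$ti_ms) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      mc = mean(.data$nonselective),
      dm = s * mean(.data$selective - .data$nonselective),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$acquisition) |>
    dplyr::transmute(ti = .data$ti_ms / 1000, n_rep = .data$n_rep,
                     mc = .data$mc, dm = .data$dm)
}

#' Voxel volume from acquisition geometry
#'
#' @param fov_mm Field of view, length-2 numeric (x, y) in mm.
#' @param matrix_size Acquisition matrix, length-2 (nx, ny).
#' @param slice_thickness_mm Slice thickness, mm.
#' @return Voxel volume in mm^3.
#' @export
#' @examples
#' voxel_volume_from_geometry(c(20, 20), c(32, 32), 2.4) # 0.9375
voxel_volume_from_geometry <- function(fov_mm, matrix_size,
                                       slice_thickness_mm) {
  if (length(fov_mm) != 2L || length(matrix_size) != 2L)
    abort("`fov_mm` and `matrix_size` must have length 2.")
  if (any(fov_mm <= 0) || any(matrix_size <= 0) || slice_thickness_mm <= 0)
    abort("All geometry dimensions must be positive.")
  (fov_mm[1] / matrix_size[1]) * (fov_mm[2] / matrix_size[2]) *
    slice_thickness_mm
}

#' Ventricular volume from a segmentation mask
#'
#' Total lateral-ventricular volume as segmented-voxel count times voxel
#' volume. The mask may be a logical/numeric array of any dimensionality
#' (slices stacked along the last dimension), a list of per-slice matrices,
#' or a path to a NIfTI mask file (read with RNifti).
#'
#' @param mask Segmentation mask (non-zero = ventricle).
#' @param voxel_volume Voxel volume in mm^3; defaults to the anatomical
#'   reference-scan geometry (0.004 mm^3).
#' @return Volume in mm^3.
#' @export
ventricular_volume <- function(mask,
                               voxel_volume = anatomical_geometry()$voxel_volume_mm3) {
  if (is.character(mask)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      abort("Reading NIfTI masks requires the RNifti package.")
    mask <- RNifti::readNifti(mask)
  }
  if (is.list(mask)) mask <- unlist(mask, use.names = FALSE)
  if (voxel_volume <= 0) abort("`voxel_volume` must be positive.")
  n <- sum(mask != 0)
  if (n == 0) warn("Empty ventricle mask; volume is 0.")
  n * voxel_volume
}

#' Volume-normalised CSF equilibrium magnetization
#'
#' The M0 estimated from the low-resolution ventricular ROI is heavily
#' partial-volumed, so it is rescaled by the ratio of the true ventricular
#' volume (from anatomical imaging) to the ROI volume:
#' \deqn{M_{0,corr} = M_{0,CSF} \times
#'   \frac{V_{vent}}{V_{ROI}}}
#'
#' @param m0_csf CSF equilibrium magnetization from the inversion-recovery
#'   fit of the ventricular ROI.
#' @param ventricular_volume Total lateral-ventricular volume, mm^3.
#' @param roi_volume Ventricular ROI volume, mm^3 (11.25 mm^3 for the
#'   default 12-voxel BCSFB ROI).
#' @return Corrected equilibrium magnetization.
#' @export
m0_corr <- function(m0_csf, ventricular_volume,
                    roi_volume = asl_protocol("bcsfb")$roi_volume_mm3) {
  if (ventricular_volume <= 0 || roi_volume <= 0)
    abort("Volumes must be positive.")
  m0_csf * ventricular_volume / roi_volume
}

#' Flag ventriculomegaly outliers
#'
#' Flags subjects whose ventricular volume exceeds `multiplier` times the
#' mean of their (genotype, age) group, the group mean being computed with
#' the candidate excluded (leave-one-out), as a screen for hydrocephalus.
#' Flagged subjects are excluded from downstream group statistics.
#'
#' @param records Data frame with columns `ventricular_volume` and the
#'   grouping variables.
#' @param multiplier Exclusion threshold as a multiple of the leave-one-out
#'   group mean (default 3).
#' @param group_vars Character vector of grouping columns.
#' @return `records` with logical `excluded` and character
#'   `exclusion_reason` columns added (existing exclusions are preserved).
#' @export
flag_ventriculomegaly <- function(records, multiplier = 3,
                                  group_vars = c("genotype", "age_weeks")) {
  if (nrow(records) < 2L)
    abort("Need at least 2 subjects to screen for ventriculomegaly.")
  if (!("excluded" %in% names(records))) records$excluded <- FALSE
  if (!("exclusion_reason" %in% names(records)))
    records$exclusion_reason <- NA_character_

  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
    dplyr::group_modify(function(g, key) {
      n <- nrow(g)
      if (n < 2L) {
        warn("Singleton group: ventriculomegaly screen skipped.")
        return(g)
      }
      v <- g$ventricular_volume
      loo_mean <- (sum(v) - v) / (n - 1)
      hit <- v > multiplier * loo_mean
      g$excluded <- g$excluded | hit
      g$exclusion_reason <- dplyr::if_else(
        hit & is.na(g$exclusion_reason),
        sprintf("ventriculomegaly: volume %.3g > %g x group mean %.3g",
                v, multiplier, loo_mean),
        g$exclusion_reason
      )
      g
    }) |>
    dplyr::ungroup()
}

#' Quantify one subject end to end
#'
#' Runs the full per-subject quantification chain: pairwise subtraction and
#' repetition averaging ([compute_delta_m()]), inversion-recovery fitting of
#' the control data per protocol ([fit_inversion_recovery()]), ventricular
#' M0 normalisation ([m0_corr()]), single-compartment CBF fitting per tissue
#' ROI ([fit_cbf()]) and two-compartment water-delivery fitting for the
#' ventricular ROI ([fit_bcsfb()]). Stage failures are recorded on the
#' returned record (as `NA` values plus a flag) rather than raised, so a
#' cohort run never stops at one bad subject.
#'
#' @param asl_data Long data frame with columns `protocol`
#'   (`"standard"`/`"bcsfb"`), `roi`, `ti_ms`, optional `acquisition`,
#'   `condition`, `repetition`, `signal`.
#' @param ventricular_volume Subject's anatomical ventricular volume, mm^3.
#' @param roi_volume Ventricular ROI volume, mm^3.
#' @param constants Kinetic constants, see [kinetic_defaults()].
#' @param fit_transit Whether transit delay is fitted (default) or fixed
#'   at 0.
#' @return A one-row tibble with per-ROI `cbf_*` and `t1_*` estimates,
#'   `m0_csf`, `t1_csf`, `m0_corr`, `water_delivery`, `ventricular_volume`,
#'   a `fits` list-column holding every `kinetic_fit`, and a `flags`
#'   character column.
#' @export
quantify_subject <- function(asl_data, ventricular_volume,
                             roi_volume = asl_protocol("bcsfb")$roi_volume_mm3,
                             constants = kinetic_defaults(),
                             fit_transit = TRUE) {
  flags <- character()
  fits <- list()
  out <- list(ventricular_volume = ventricular_volume)

  tissue_rois <- asl_data |>
    dplyr::filter(.data$protocol == "standard") |>
    dplyr::pull("roi") |>
    unique()
  for (roi in tissue_rois) {
    res <- tryCatch({
      series <- compute_delta_m(
        dplyr::filter(asl_data, .data$protocol == "standard",
                      .data$roi == !!roi))
      ir <- fit_inversion_recovery(series)
      cb <- fit_cbf(series |> dplyr::select("ti", "dm"),
                    m0_tissue = coef(ir)[["m0"]],
                    t1_tissue = coef(ir)[["t1"]],
                    t1_blood = constants$t1_blood,
                    lambda = constants$lambda, alpha = constants$alpha,
                    tissue_density = constants$tissue_density,
                    fit_transit = fit_transit)
      list(ir = ir, cbf = cb)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      flags <- c(flags, paste0("standard/", roi, ": ", conditionMessage(res)))
      out[[paste0("cbf_", roi)]] <- NA_real_
      out[[paste0("t1_", roi)]] <- NA_real_
    } else {
      out[[paste0("cbf_", roi)]] <- coef(res$cbf)[["cbf"]]
      out[[paste0("t1_", roi)]] <- coef(res$ir)[["t1"]]
      fits[[paste0("ir_", roi)]] <- res$ir
      fits[[paste0("cbf_", roi)]] <- res$cbf
    }
  }

  bcsfb_data <- dplyr::filter(asl_data, .data$protocol == "bcsfb")
  out$m0_csf <- out$t1_csf <- out$m0_corr <- out$water_delivery <- NA_real_
  if (nrow(bcsfb_data) == 0L) {
    flags <- c(flags, "bcsfb: series missing")
  } else {
    res <- tryCatch({
      series <- compute_delta_m(bcsfb_data)
      ir <- fit_inversion_recovery(series)
      m0c <- m0_corr(coef(ir)[["m0"]], ventricular_volume, roi_volume)
      wf <- fit_bcsfb(series |> dplyr::select("ti", "dm"),
                      m0_corr = m0c,
                      ventricular_volume = ventricular_volume,
                      t1_csf = coef(ir)[["t1"]],
                      t1_blood = constants$t1_blood,
                      alpha = constants$alpha, fit_transit = fit_transit)
      list(ir = ir, wf = wf, m0c = m0c)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      flags <- c(flags, paste0("bcsfb: ", conditionMessage(res)))
    } else {
      out$m0_csf <- coef(res$ir)[["m0"]]
      out$t1_csf <- coef(res$ir)[["t1"]]
      out$m0_corr <- res$m0c
      out$water_delivery <- coef(res$wf)[["water_delivery"]]
      fits$ir_ventricles <- res$ir
      fits$bcsfb <- res$wf
    }
  }

  tibble::as_tibble(out) |>
    dplyr::mutate(fits = list(fits),
                  flags = paste(flags, collapse = "; "))
}

#' Quantify a whole cohort
#'
#' Maps [quantify_subject()] over a cohort manifest (as produced by
#' [simulate_cohort()] or assembled from file), scores the Y-maze entry
#' sequences, and applies the ventriculomegaly exclusion screen.
#'
#' @param cohort Tibble with columns `subject_id`, `genotype`, `age_weeks`,
#'   `ventricular_volume`, a list-column `asl` of per-subject ASL tables and
#'   optionally a list-column `entries` of Y-maze arm-entry vectors.
#' @inheritParams quantify_subject
#' @param exclusion_multiplier Ventriculomegaly threshold, see
#'   [flag_ventriculomegaly()].
#' @return A tibble of subject records: group labels, fitted parameters,
#'   behaviour scores and exclusion flags.
#' @export
quantify_cohort <- function(cohort,
                            constants = kinetic_defaults(),
                            fit_transit = TRUE,
                            exclusion_multiplier = 3) {
  records <- cohort |>
    dplyr::mutate(
      record = purrr::map2(.data$asl, .data$ventricular_volume,
                           ~ quantify_subject(.x, .y, constants = constants,
                                              fit_transit = fit_transit))
    ) |>
    dplyr::select(-"asl") |>
    tidyr::unnest("record", names_repair = "minimal")
  # manifest carries the generating volume; keep the single column
  records <- records[, !duplicated(names(records))]

  if ("entries" %in% names(cohort)) {
    beh <- purrr::map(cohort$entries, sa_score)
    records$n_entries <- purrr::map_int(beh, ~ .x$n_entries)
    records$sa_score <- purrr::map_dbl(beh, ~ .x$sa_score)
    records$entries <- NULL
  }
  flag_ventriculomegaly(records, multiplier = exclusion_multiplier)
}

#' Group summary table (mean +/- SEM)
#'
#' Per-(genotype, age) means and standard errors of the quantified
#' variables, mirroring the layout of a cohort summary table. Excluded
#' subjects are dropped first.
#'
#' @param records Subject records from [quantify_cohort()].
#' @param variables Variables to summarise; defaults to every numeric
#'   quantified column present.
#' @return A long tibble with `genotype`, `age_weeks`, `variable`, `n`,
#'   `mean`, `sem`.
#' @export
summarise_cohort <- function(records, variables = NULL) {
  if (is.null(variables)) {
    variables <- intersect(
      c("water_delivery", "t1_csf", "ventricular_volume",
        grep("^(cbf|t1)_", names(records), value = TRUE),
        "n_entries", "sa_score"),
      names(records))
  }
  records |>
    dplyr::filter(!.data$excluded) |>
    dplyr::select(dplyr::all_of(c("genotype", "age_weeks", variables))) |>
    tidyr::pivot_longer(dplyr::all_of(variables), names_to = "variable") |>
    dplyr::group_by(.data$genotype, .data$age_weeks, .data$variable) |>
    dplyr::summarise(
      n = sum(is.finite(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sem = sd(.data$value, na.rm = TRUE) / sqrt(.data$n),
      .groups = "drop"
    )
}
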