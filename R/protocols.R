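#' FAIR-ASL acquisition protocols
#'
#' Returns the acquisition geometry and timing of the two multi-TI FAIR-ASL
#' protocols used throughout the package: the standard tissue-perfusion
#' protocol (short echo time, TE = 20 ms) and the BCSFB protocol, which uses
#' an ultra-long echo time (TE = 220 ms) so that only long-T2 ventricular CSF
#' contributes signal. The duplicate 200 ms entry in the BCSFB inversion-time
#' schedule is a genuine repeated acquisition and is retained as an
#' independent observation.
#'
#' @param name `"standard"` or `"bcsfb"`.
#'
#' @return A list of class `asl_protocol` with elements:
#'   * `name` — protocol label
#'   * `ti_s` — inversion-time schedule in seconds (ordered, may repeat)
#'   * `te_s` — echo time in seconds
#'   * `repetitions` — label/control pairs acquired per TI
#'   * `fov_mm`, `matrix_size`, `slice_thickness_mm` — imaging geometry
#'   * `voxel_volume_mm3` — in-plane voxel area times slice thickness
#'   * `roi_voxels` — for the BCSFB protocol, the default ventricular ROI
#'     size (two 3 x 2 voxel boxes, 12 voxels); `NA` otherwise
#'   * `roi_volume_mm3` — `roi_voxels * voxel_volume_mm3`
#' @export
#' @examples
#' asl_protocol("bcsfb")$roi_volume_mm3 # 11.25 mm^3
asl_protocol <- function(name = c("standard", "bcsfb")) {
  name <- match.arg(name)
  if (name == "standard") {
    p <- list(
      name = "standard",
      ti_s = c(200, 500, 1000, 1500, 2000, 3000, 4000) / 1000,
      te_s = 0.020,
      repetitions = 5L,
      fov_mm = c(20, 20),
      matrix_size = c(40L, 56L),
      slice_thickness_mm = 1.0,
      roi_voxels = NA_integer_
    )
  } else {
    p <- list(
      name = "bcsfb",
      ti_s = c(200, 200, 750, 1500, 2750, 4000, 5000, 6000) / 1000,
      te_s = 0.220,
      repetitions = 10L,
      fov_mm = c(20, 20),
      matrix_size = c(32L, 32L),
      slice_thickness_mm = 2.4,
      roi_voxels = 12L
    )
  }
  p$voxel_volume_mm3 <- voxel_volume_from_geometry(
    p$fov_mm, p$matrix_size, p$slice_thickness_mm
  )
  p$roi_volume_mm3 <- if (is.na(p$roi_voxels)) NA_real_ else
    p$roi_voxels * p$voxel_volume_mm3
  structure(p, class = "asl_protocol")
}

#' Anatomical reference-scan geometry
#'
#' Geometry of the coronal T2-weighted anatomical stack on which the lateral
#' ventricles are segmented: FOV 20 x 16 mm, matrix 200 x 160, six 0.4 mm
#' slices, giving 0.004 mm^3 voxels.
#'
#' @return A list with `fov_mm`, `matrix_size`, `slice_thickness_mm`,
#'   `n_slices` and `voxel_volume_mm3`.
#' @export
anatomical_geometry <- function() {
  g <- list(
    fov_mm = c(20, 16),
    matrix_size = c(200L, 160L),
    slice_thickness_mm = 0.4,
    n_slices = 6L
  )
  g$voxel_volume_mm3 <- voxel_volume_from_geometry(
    g$fov_mm, g$matrix_size, g$slice_thickness_mm
  )
  g
}

#' Default kinetic-model constants
#'
#' Physiological constants required by the kinetic models but not estimated
#' from the data. None of these is hard-coded in the model functions; every
#' fitting and simulation routine takes them as arguments defaulting to this
#' list.
#'
#' @details
#' * `t1_blood` — longitudinal relaxation time of arterial blood at 9.4 T,
#'   2.4 s (typical mouse value).
#' * `lambda` — blood-brain partition coefficient of water, 0.9 mL/g.
#' * `alpha` — inversion (labelling) efficiency, 1.0.
#' * `tissue_density` — brain tissue density, 1.0 g/mL, used to convert CBF
#'   from mL/100 g/min to a rate in 1/s.
#' * `transit_time_tissue`, `transit_time_bcsfb` — default arterial transit
#'   delays (s) used by the synthetic-data generator; fitting routines treat
#'   transit time as a free bounded parameter by default.
#'
#' @return Named list of constants.
#' @export
kinetic_defaults <- function() {
  list(
    t1_blood = 2.4,
    lambda = 0.9,
    alpha = 1.0,
    tissue_density = 1.0,
    transit_time_tissue = 0.2,
    transit_time_bcsfb = 0.3
  )
}
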