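#' Group scatter with mean and SEM by age
#'
#' Individual-subject values with overlaid group mean +/- SEM per
#' (genotype, age) cell — the conventional display for cross-sectional
#' cohort parameters such as water delivery, CBF, T1 or %SA.
#'
#' @param records Subject records (excluded subjects are dropped).
#' @param variable Column to plot (string).
#' @param ylab Optional y-axis label; defaults to the variable name.
#' @return A ggplot object.
#' @export
plot_group_summary <- function(records, variable, ylab = variable) {
  if ("excluded" %in% names(records))
    records <- dplyr::filter(records, !.data$excluded)
  summ <- records |>
    dplyr::group_by(.data$genotype, .data$age_weeks) |>
    dplyr::summarise(
      mean = mean(.data[[variable]], na.rm = TRUE),
      sem = sd(.data[[variable]], na.rm = TRUE) /
        sqrt(sum(is.finite(.data[[variable]]))),
      .groups = "drop"
    )
  ggplot2::ggplot(records,
                  ggplot2::aes(x = factor(.data$age_weeks),
                               colour = .data$genotype)) +
    ggplot2::geom_jitter(ggplot2::aes(y = .data[[variable]]),
                         width = 0.12, alpha = 0.5, size = 1.5,
                         position = ggplot2::position_jitterdodge(
                           jitter.width = 0.15, dodge.width = 0.5)) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.5), size = 0.6) +
    ggplot2::labs(x = "Age (weeks)", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Group-averaged kinetic curves
#'
#' Averages the repetition-averaged difference signal across subjects per
#' group and plots the group kinetic curves against inversion time.
#'
#' @param cohort Cohort manifest with an `asl` list-column (see
#'   [simulate_cohort()]).
#' @param protocol Which protocol's series to average.
#' @param roi ROI to plot.
#' @return A ggplot object.
#' @export
plot_group_kinetics <- function(cohort, protocol = "bcsfb",
                                roi = if (protocol == "bcsfb")
                                  "ventricles" else "cortex") {
  curves <- cohort |>
    dplyr::mutate(curve = purrr::map(.data$asl, function(a) {
      compute_delta_m(dplyr::filter(a, .data$protocol == !!protocol,
                                    .data$roi == !!roi))
    })) |>
    dplyr::select("subject_id", "genotype", "age_weeks", "curve") |>
    tidyr::unnest("curve") |>
    dplyr::group_by(.data$genotype, .data$age_weeks, .data$ti) |>
    dplyr::summarise(dm = mean(.data$dm), .groups = "drop")
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$ti, y = .data$dm,
                               colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ age_weeks, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Inversion time (s)",
                  y = expression(Delta * M~"(mean)"), colour = NULL) +
    ggplot2::theme_minimal()
}
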