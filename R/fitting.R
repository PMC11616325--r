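#' @title Bounded least-squares kinetic fitting
#' @description Internal engine shared by the three fitters: bounded
#'   Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]) with a
#'   deterministic default start and an optional seeded multi-start grid.
#' @noRd
fit_ls <- function(resid_fn, init, lower, upper, n_starts = 1L, seed = NULL) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                     gtol = 0, maxiter = 500)
  starts <- list(init)
  if (n_starts > 1L) {
    if (!is.null(seed)) {
      starts <- c(starts, withr::with_seed(seed, random_starts(
        n_starts - 1L, lower, upper, init)))
    } else {
      starts <- c(starts, random_starts(n_starts - 1L, lower, upper, init))
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("Least-squares optimisation failed from every start.")
  best
}

random_starts <- function(k, lower, upper, init) {
  lo <- pmax(lower, init / 10)
  hi <- pmin(upper, init * 10 + 1)
  lapply(seq_len(k), function(i) {
    s <- lo + runif(length(init)) * (hi - lo)
    names(s) <- names(init)
    s
  })
}

new_kinetic_fit <- function(model, params, free, std_error, fit, data,
                            bounds, flags = character(), seed = NULL) {
  structure(
    list(
      model = model,
      params = params,
      free = free,
      std_error = std_error,
      residual_norm = if (is.null(fit)) 0 else sqrt(fit$deviance),
      converged = if (is.null(fit)) TRUE else fit$info %in% 1:4,
      n_iter = if (is.null(fit)) 0L else fit$niter,
      data = data,
      bounds = bounds,
      flags = flags,
      seed = seed
    ),
    class = "kinetic_fit"
  )
}

# Standard errors from the local Gauss-Newton approximation J'J.
ls_std_errors <- function(fit, n_obs) {
  p <- length(fit$par)
  dfree <- n_obs - p
  se <- rep(NA_real_, p)
  if (dfree > 0 && !is.null(fit$hessian)) {
    cv <- tryCatch(solve(fit$hessian) * fit$deviance / dfree,
                   error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  setNames(se, names(fit$par))
}

#' Fit the inversion-recovery curve
#'
#' Estimates the equilibrium magnetization M0 and longitudinal relaxation
#' time T1 from a control-condition series \eqn{[TI, M_c]} by least-squares
#' fitting of [ir_signal()]. Used on short-TE (tissue) data to obtain M0 and
#' T1 of tissue, and on ultra-long-TE (BCSFB) data to obtain M0 of
#' ventricular CSF and T1 of CSF.
#'
#' @param data Data frame with columns `ti` (seconds) and `mc` (signal).
#' @param init Optional named vector `c(m0 = , t1 = )` of starting values;
#'   by default M0 starts at the largest absolute signal and T1 at the
#'   zero-crossing TI divided by log(2).
#' @param lower,upper Named bounds on `m0` and `t1`.
#' @return A `kinetic_fit` object; see [tidy.kinetic_fit()] and
#'   [glance.kinetic_fit()].
#' @export
#' @examples
#' ti <- c(0.2, 0.2, 0.75, 1.5, 2.75, 4, 5, 6)
#' d <- tibble::tibble(ti = ti, mc = ir_signal(ti, m0 = 1, t1 = 3.31))
#' coef(fit_inversion_recovery(d))
fit_inversion_recovery <- function(data, init = NULL,
                                   lower = c(m0 = 1e-12, t1 = 0.05),
                                   upper = c(m0 = Inf, t1 = 20)) {
  ti <- data$ti
  mc <- data$mc
  if (length(unique(ti)) < 3L)
    abort("Inversion-recovery fitting needs at least 3 distinct TI values.",
          class = "bcsfbasl_insufficient_data")
  if (!all(is.finite(mc))) abort("`mc` values must be finite.")
  if (any(ti <= 0)) abort("`ti` values must be strictly positive.")
  if (is.null(init)) {
    m0_init <- max(abs(mc))
    ord <- order(ti)
    pos <- ti[ord][mc[ord] > 0]
    ti0 <- if (length(pos)) pos[1] else median(ti)
    init <- c(m0 = m0_init, t1 = max(ti0 / log(2), lower[["t1"]] * 2))
  }
  resid_fn <- function(p) mc - p[["m0"]] * (1 - 2 * exp(-ti / p[["t1"]]))
  fit <- fit_ls(resid_fn, init, lower, upper)
  params <- c(m0 = fit$par[["m0"]], t1 = fit$par[["t1"]])
  dat <- tibble::tibble(
    ti = ti, observed = mc,
    fitted = ir_signal(ti, params[["m0"]], params[["t1"]])
  )
  new_kinetic_fit("inversion_recovery", params, free = c("m0", "t1"),
                  std_error = ls_std_errors(fit, length(ti)), fit = fit,
                  data = dat, bounds = list(lower = lower, upper = upper))
}

#' Fit tissue CBF with the single-compartment Buxton model
#'
#' Least-squares fit of [buxton_tissue_signal()] to a perfusion-weighted
#' series \eqn{[TI, \Delta M]}. M0 and T1 of tissue come from the
#' inversion-recovery fit of the same ROI and enter as fixed inputs; CBF and
#' (by default) the arterial transit delay are free.
#'
#' @param data Data frame with columns `ti` (seconds) and `dm` (signal).
#' @param m0_tissue,t1_tissue Fixed subject-wise values from
#'   [fit_inversion_recovery()].
#' @inheritParams buxton_tissue_signal
#' @param fit_transit If `TRUE` (default) the transit delay is a free
#'   parameter in `transit_bounds`; if `FALSE` it is fixed at `transit_time`.
#' @param transit_time Fixed transit delay (s), used when
#'   `fit_transit = FALSE`.
#' @param transit_bounds Bounds (s) on the fitted transit delay.
#' @param cbf_bounds Bounds on CBF, mL/100 g/min.
#' @param init Named starting values for the free parameters.
#' @return A `kinetic_fit` with `cbf` in mL/100 g/min.
#' @export
fit_cbf <- function(data, m0_tissue, t1_tissue,
                    t1_blood = kinetic_defaults()$t1_blood,
                    lambda = kinetic_defaults()$lambda,
                    alpha = kinetic_defaults()$alpha,
                    tissue_density = kinetic_defaults()$tissue_density,
                    fit_transit = TRUE, transit_time = 0,
                    transit_bounds = c(0, 0.5),
                    cbf_bounds = c(0, 2000),
                    init = c(cbf = 100, transit_time = 0.1)) {
  ti <- data$ti
  dm <- data$dm
  if (length(unique(ti)) < 3L)
    abort("CBF fitting needs at least 3 distinct TI values.",
          class = "bcsfbasl_insufficient_data")
  flags <- character()
  if (all(dm == 0)) {
    warn("All-zero perfusion-weighted signal; returning CBF = 0.")
    params <- c(cbf = 0, transit_time = transit_time)
    dat <- tibble::tibble(ti = ti, observed = dm, fitted = 0)
    return(new_kinetic_fit("buxton_tissue", params,
                           free = c("cbf", if (fit_transit) "transit_time"),
                           std_error = c(cbf = NA_real_, transit_time = NA_real_),
                           fit = NULL, data = dat,
                           bounds = list(cbf = cbf_bounds,
                                         transit_time = transit_bounds),
                           flags = "all_zero_dm"))
  }
  model <- function(p) {
    tt <- if (fit_transit) p[["transit_time"]] else transit_time
    buxton_tissue_signal(ti, cbf = p[["cbf"]], m0_tissue = m0_tissue,
                         t1_tissue = t1_tissue, t1_blood = t1_blood,
                         lambda = lambda, alpha = alpha,
                         transit_time = tt, tissue_density = tissue_density)
  }
  free <- if (fit_transit) c("cbf", "transit_time") else "cbf"
  lower <- c(cbf = cbf_bounds[1], transit_time = transit_bounds[1])[free]
  upper <- c(cbf = cbf_bounds[2], transit_time = transit_bounds[2])[free]
  fit <- fit_ls(function(p) dm - model(p), init[free], lower, upper)
  params <- c(fit$par,
              if (!fit_transit) c(transit_time = transit_time))
  dat <- tibble::tibble(ti = ti, observed = dm, fitted = model(fit$par))
  out <- new_kinetic_fit("buxton_tissue", params, free = free,
                         std_error = ls_std_errors(fit, length(ti)),
                         fit = fit, data = dat,
                         bounds = list(cbf = cbf_bounds,
                                       transit_time = transit_bounds),
                         flags = flags)
  if (!out$converged) warn("CBF fit did not converge cleanly.")
  out
}

#' Fit BCSFB-mediated water delivery with the two-compartment model
#'
#' Least-squares fit of [bcsfb_signal()] to an ultra-long-TE
#' perfusion-weighted series. T1 of CSF and the volume-normalised M0 come
#' from the inversion-recovery fit of the control data ([m0_corr()]); the
#' total water delivery W (and by default the transit delay) are free. W is
#' reported in uL/min summed across the lateral ventricles.
#'
#' @param data Data frame with columns `ti` (seconds) and `dm` (signal).
#' @param m0_corr Fixed volume-normalised CSF equilibrium magnetization.
#' @param ventricular_volume Fixed total ventricular volume, mm^3.
#' @param t1_csf Fixed CSF T1 (s) from the inversion-recovery fit.
#' @inheritParams fit_cbf
#' @param wd_bounds Bounds on water delivery, uL/min.
#' @return A `kinetic_fit` with `water_delivery` in uL/min.
#' @export
fit_bcsfb <- function(data, m0_corr, ventricular_volume, t1_csf,
                      t1_blood = kinetic_defaults()$t1_blood,
                      alpha = kinetic_defaults()$alpha,
                      fit_transit = TRUE, transit_time = 0,
                      transit_bounds = c(0, 1),
                      wd_bounds = c(0, 20),
                      init = c(water_delivery = 0.5, transit_time = 0.2)) {
  ti <- data$ti
  dm <- data$dm
  if (length(unique(ti)) < 3L)
    abort("BCSFB fitting needs at least 3 distinct TI values.",
          class = "bcsfbasl_insufficient_data")
  if (all(dm == 0)) {
    warn("All-zero perfusion-weighted signal; returning water delivery = 0.")
    params <- c(water_delivery = 0, transit_time = transit_time)
    dat <- tibble::tibble(ti = ti, observed = dm, fitted = 0)
    return(new_kinetic_fit("bcsfb", params,
                           free = c("water_delivery",
                                    if (fit_transit) "transit_time"),
                           std_error = c(water_delivery = NA_real_,
                                         transit_time = NA_real_),
                           fit = NULL, data = dat,
                           bounds = list(water_delivery = wd_bounds,
                                         transit_time = transit_bounds),
                           flags = "all_zero_dm"))
  }
  model <- function(p) {
    tt <- if (fit_transit) p[["transit_time"]] else transit_time
    bcsfb_signal(ti, water_delivery = p[["water_delivery"]],
                 m0_corr = m0_corr,
                 ventricular_volume = ventricular_volume, t1_csf = t1_csf,
                 t1_blood = t1_blood, alpha = alpha, transit_time = tt)
  }
  free <- if (fit_transit) c("water_delivery", "transit_time") else
    "water_delivery"
  lower <- c(water_delivery = wd_bounds[1],
             transit_time = transit_bounds[1])[free]
  upper <- c(water_delivery = wd_bounds[2],
             transit_time = transit_bounds[2])[free]
  fit <- fit_ls(function(p) dm - model(p), init[free], lower, upper)
  params <- c(fit$par,
              if (!fit_transit) c(transit_time = transit_time))
  dat <- tibble::tibble(ti = ti, observed = dm, fitted = model(fit$par))
  out <- new_kinetic_fit("bcsfb", params, free = free,
                         std_error = ls_std_errors(fit, length(ti)),
                         fit = fit, data = dat,
                         bounds = list(water_delivery = wd_bounds,
                                       transit_time = transit_bounds),
                         flags = character())
  if (!out$converged) warn("BCSFB fit did not converge cleanly.")
  out
}

#' @export
coef.kinetic_fit <- function(object, ...) object$params

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit:", x$model, ">\n")
  est <- format(signif(x$params, 6))
  for (nm in names(x$params)) {
    tag <- if (nm %in% x$free) "" else " (fixed)"
    cat("  ", nm, " = ", est[[nm]], tag, "\n", sep = "")
  }
  cat("  residual norm:", signif(x$residual_norm, 4),
      "| converged:", x$converged, "|", x$n_iter, "iterations\n")
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error` and whether the parameter was `free` in the fit.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$params),
    estimate = unname(x$params),
    std.error = unname(x$std_error[names(x$params)]),
    free = names(x$params) %in% x$free
  )
}

#' One-row fit summary
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the model label, residual norm, convergence
#'   flag, iteration count, observation count and residual degrees of
#'   freedom.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    residual_norm = x$residual_norm,
    converged = x$converged,
    n_iter = x$n_iter,
    nobs = nrow(x$data),
    df.residual = nrow(x$data) - length(x$free)
  )
}

#' Plot a kinetic fit
#'
#' Observed signal against inversion time with the fitted model curve
#' overlaid, in the style of per-subject ASL kinetic-curve panels.
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  grid <- tibble::tibble(ti = seq(min(object$data$ti) * 0.5,
                                  max(object$data$ti), length.out = 200))
  p <- object$params
  grid$fitted <- switch(
    object$model,
    inversion_recovery = ir_signal(grid$ti, p[["m0"]], p[["t1"]]),
    stats::approx(object$data$ti, object$data$fitted, xout = grid$ti,
                  rule = 2)$y
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ti)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "Inversion time (s)", y = "Signal",
                  title = paste("Kinetic fit:", object$model)) +
    ggplot2::theme_minimal()
}
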