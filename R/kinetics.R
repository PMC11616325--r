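#' Inversion-recovery signal
#'
#' Longitudinal magnetization of the control (non-selective) FAIR condition
#' following a global inversion pulse:
#' \deqn{M_c(TI) = M_0 (1 - 2 e^{-TI/T_1})}
#'
#' @param ti Inversion time(s), seconds; non-negative.
#' @param m0 Equilibrium magnetization, arbitrary signal units; positive.
#' @param t1 Longitudinal relaxation time, seconds; positive.
#' @return Signal value(s), same length as `ti`.
#' @export
#' @examples
#' ir_signal(log(2) * 1.8, m0 = 100, t1 = 1.8) # null crossing: 0
ir_signal <- function(ti, m0, t1) {
  if (!is.numeric(m0) || length(m0) != 1L || !is.finite(m0) || m0 <= 0)
    abort("`m0` must be a single positive number.")
  if (!is.numeric(t1) || length(t1) != 1L || !is.finite(t1) || t1 <= 0)
    abort("`t1` must be a single positive number.")
  if (any(ti < 0)) abort("`ti` must be non-negative.")
  m0 * (1 - 2 * exp(-ti / t1))
}

# Shared two-exponential kernel of both Buxton-type delivery models:
# label delivered from t' = dt onward decays at r1_in (blood) before arrival
# and at r1_out (destination compartment) afterwards. `amp` carries 2, alpha,
# equilibrium magnetization and the delivery rate. Equal-rate branch switches
# at |r1_in - r1_out| < 1e-9 1/s to avoid catastrophic cancellation.
buxton_kernel <- function(ti, amp, r1_in, r1_out, transit_time) {
  out <- numeric(length(ti))
  on <- ti >= transit_time
  if (!any(on)) return(out)
  t_on <- ti[on]
  dr <- r1_in - r1_out
  if (abs(dr) < 1e-9) {
    out[on] <- amp * (t_on - transit_time) * exp(-r1_in * t_on)
  } else {
    out[on] <- amp * exp(-r1_out * t_on) *
      (exp(-dr * transit_time) - exp(-dr * t_on)) / dr
  }
  out
}

#' Single-compartment Buxton tissue perfusion signal
#'
#' Perfusion-weighted difference signal \eqn{\Delta M(TI)} of the general
#' Buxton kinetic model for a FAIR experiment with a global labelling pulse.
#' Because the whole animal is labelled, the bolus is modelled as unbounded
#' (duration exceeding the longest inversion time), so the signal is the
#' convolution of an exponentially decaying arterial input (rate
#' \eqn{R_{1b} = 1/T_{1b}}) with tissue clearance at the apparent rate
#' \eqn{R_{1app} = 1/T_{1,tissue} + f/\lambda}, switched on at the arterial
#' transit delay:
#' \deqn{\Delta M(TI) = 2 \alpha \frac{M_0}{\lambda} f\,
#'   e^{-R_{1app} TI}\,
#'   \frac{e^{-(R_{1b}-R_{1app})\Delta t} - e^{-(R_{1b}-R_{1app})TI}}
#'        {R_{1b}-R_{1app}}, \quad TI \ge \Delta t}
#' and 0 before arrival. `cbf` is given in the conventional
#' mL/100 g/min and converted internally to a rate
#' \eqn{f = \mathrm{cbf}\,\rho/6000} in 1/s.
#'
#' @param ti Inversion time(s), seconds.
#' @param cbf Cerebral blood flow, mL/100 g/min; non-negative.
#' @param m0_tissue Tissue equilibrium magnetization (signal units).
#' @param t1_tissue Tissue T1, seconds.
#' @param t1_blood Arterial blood T1, seconds.
#' @param lambda Blood-brain partition coefficient, mL/g.
#' @param alpha Inversion efficiency in (0, 1].
#' @param transit_time Arterial transit delay, seconds.
#' @param tissue_density Tissue density, g/mL.
#' @return \eqn{\Delta M} value(s).
#' @export
buxton_tissue_signal <- function(ti, cbf, m0_tissue, t1_tissue,
                                 t1_blood = kinetic_defaults()$t1_blood,
                                 lambda = kinetic_defaults()$lambda,
                                 alpha = kinetic_defaults()$alpha,
                                 transit_time = 0,
                                 tissue_density = kinetic_defaults()$tissue_density) {
  check_positive(m0_tissue = m0_tissue, t1_tissue = t1_tissue,
                 t1_blood = t1_blood, lambda = lambda, alpha = alpha,
                 tissue_density = tissue_density)
  if (cbf < 0) abort("`cbf` must be non-negative.")
  if (transit_time < 0) abort("`transit_time` must be non-negative.")
  if (alpha > 1) abort("`alpha` must not exceed 1.")
  if (any(ti < 0)) abort("`ti` must be non-negative.")
  f <- cbf * tissue_density / 6000 # 1/s
  r1app <- 1 / t1_tissue + f / lambda
  amp <- 2 * alpha * (m0_tissue / lambda) * f
  buxton_kernel(ti, amp, r1_in = 1 / t1_blood, r1_out = r1app,
                transit_time = transit_time)
}

#' Two-compartment BCSFB water-delivery signal
#'
#' Ultra-long-TE FAIR difference signal from labelled arterial water
#' delivered across the blood-CSF barrier into ventricular CSF. Labelled
#' water relaxes with blood T1 before exchange and with CSF T1 after; there
#' is no outflow term on the time scale of the experiment:
#' \deqn{\Delta M(TI) = 2 \alpha M_{0,corr}\, w\,
#'   e^{-R_{1csf} TI}\,
#'   \frac{e^{-(R_{1b}-R_{1csf})\Delta t} - e^{-(R_{1b}-R_{1csf})TI}}
#'        {R_{1b}-R_{1csf}}, \quad TI \ge \Delta t}
#' with the fractional delivery rate \eqn{w} (1/s) obtained from the total
#' water delivery \eqn{W} (uL/min, summed over the lateral ventricles) as
#' \eqn{w = (W/60)/V_{vent}} using 1 uL = 1 mm^3.
#'
#' @param ti Inversion time(s), seconds.
#' @param water_delivery Total labelled-water delivery W, uL/min;
#'   non-negative.
#' @param m0_corr Volume-normalised CSF equilibrium magnetization (see
#'   [m0_corr()]).
#' @param ventricular_volume Total lateral-ventricular volume, mm^3.
#' @param t1_csf CSF T1, seconds.
#' @inheritParams buxton_tissue_signal
#' @return \eqn{\Delta M} value(s).
#' @export
bcsfb_signal <- function(ti, water_delivery, m0_corr, ventricular_volume,
                         t1_csf,
                         t1_blood = kinetic_defaults()$t1_blood,
                         alpha = kinetic_defaults()$alpha,
                         transit_time = 0) {
  check_positive(m0_corr = m0_corr, ventricular_volume = ventricular_volume,
                 t1_csf = t1_csf, t1_blood = t1_blood, alpha = alpha)
  if (water_delivery < 0) abort("`water_delivery` must be non-negative.")
  if (transit_time < 0) abort("`transit_time` must be non-negative.")
  if (alpha > 1) abort("`alpha` must not exceed 1.")
  if (any(ti < 0)) abort("`ti` must be non-negative.")
  w <- (water_delivery / 60) / ventricular_volume # 1/s
  amp <- 2 * alpha * m0_corr * w
  buxton_kernel(ti, amp, r1_in = 1 / t1_blood, r1_out = 1 / t1_csf,
                transit_time = transit_time)
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      abort(paste0("`", nm, "` must be a single positive number."))
  }
  invisible(TRUE)
}
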