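# Independent oracles used across the suite. These re-derive expected values
# by brute force / quadrature / enumeration, never through the package's own
# closed forms.

# Numerical quadrature of the delivery-decay convolution that defines both
# kinetic models: label delivered from `dt` onward, decaying at rate r1_in
# before arrival and r1_out after.
quad_kernel <- function(ti, amp, r1_in, r1_out, dt) {
  vapply(ti, function(t1) {
    if (t1 <= dt) return(0)
    amp * integrate(function(tp) exp(-r1_in * tp) * exp(-r1_out * (t1 - tp)),
                    lower = dt, upper = t1,
                    rel.tol = 1e-12, abs.tol = 0)$value
  }, numeric(1))
}

quad_tissue <- function(ti, cbf, m0, t1_tissue, t1_blood = 2.4,
                        lambda = 0.9, alpha = 1, dt = 0, density = 1) {
  f <- cbf * density / 6000
  r1app <- 1 / t1_tissue + f / lambda
  quad_kernel(ti, 2 * alpha * (m0 / lambda) * f, 1 / t1_blood, r1app, dt)
}

quad_bcsfb <- function(ti, wd, m0_corr, vvent, t1_csf, t1_blood = 2.4,
                       alpha = 1, dt = 0) {
  w <- (wd / 60) / vvent
  quad_kernel(ti, 2 * alpha * m0_corr * w, 1 / t1_blood, 1 / t1_csf, dt)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (tie-free data); matches the symmetric two-sided convention.
mw_enum_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  pl <- mean(u_all <= u_obs)
  pg <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pg))
}

# Step-up BH from the definition, independent of p.adjust.
bh_def <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  k <- which(ranked <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  adj <- rev(cummin(rev(ranked * m / seq_len(m))))
  adj <- pmin(adj, 1)
  list(adjusted = adj[order(o)], reject = reject)
}

# Type III SS by explicit full/reduced model refits with sum-to-zero
# contrasts.
type3_ss_refit <- function(y, g, a) {
  g <- factor(g); a <- factor(a)
  mm <- model.matrix(~ g * a,
                     contrasts.arg = list(g = "contr.sum", a = "contr.sum"))
  rss <- function(cols) {
    fit <- lm.fit(mm[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  cols_g <- grep("^g\\d+$", colnames(mm))
  cols_a <- grep("^a\\d+$", colnames(mm))
  cols_ga <- grep(":", colnames(mm), fixed = TRUE)
  full <- rss(seq_len(ncol(mm)))
  list(
    genotype = rss(setdiff(seq_len(ncol(mm)), cols_g)) - full,
    age = rss(setdiff(seq_len(ncol(mm)), cols_a)) - full,
    interaction = rss(setdiff(seq_len(ncol(mm)), cols_ga)) - full,
    residual = full
  )
}

# Long-run %SA of the entry generator from its transition matrix over the
# state "are the last two entries distinct", enumerated explicitly.
sa_chain_expectation <- function(p) {
  # states: 1 = last two same, 2 = last two distinct
  P <- matrix(c(1 - p, p,
                (1 - p) / 2, p + (1 - p) / 2),
              nrow = 2, byrow = TRUE)
  pi <- Re(eigen(t(P))$vectors[, 1])
  pi <- pi / sum(pi)
  100 * pi[2] * p
}

# One clean BCSFB/standard raw-series pair for round-trip tests.
make_clean_subject <- function(m0 = 100, t1_tissue = 1.8, cbf = 185,
                               t1_csf = 3.31, wd = 0.55, vvent = 1.02) {
  dplyr::bind_rows(
    simulate_subject_series(
      "standard", params = list(m0 = m0, t1_tissue = t1_tissue, cbf = cbf),
      snr_dm = Inf, snr_mc = Inf, roi = "cortex"),
    simulate_subject_series(
      "bcsfb", params = list(m0 = m0, t1_csf = t1_csf,
                             water_delivery = wd,
                             ventricular_volume = vvent),
      snr_dm = Inf, snr_mc = Inf)
  )
}
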