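#' Fit a Rayleigh noise model to ventricular intensities
#'
#' Magnitude MR background noise follows a Rayleigh distribution. Inside a
#' ventricle mask the intensity histogram is a Rayleigh noise body (free
#' fluid) plus a bright choroid-plexus mode, so the scale is estimated
#' robustly: intensities above the `trim_quantile` empirical quantile are
#' discarded and the Rayleigh scale is obtained by maximum likelihood for
#' the truncated distribution (the truncation point enters the likelihood,
#' so the estimate is unbiased for pure noise despite the trimming). One
#' refinement pass re-trims at the fitted model's `trim_quantile` quantile
#' and re-estimates. The segmentation threshold is set at the upper
#' `tail_prob` quantile of the fitted noise distribution,
#' \eqn{\sigma\sqrt{-2\ln(\mathrm{tail\_prob})}}.
#'
#' @param intensities Positive voxel intensities (>= 50 values).
#' @param tail_prob Upper-tail probability defining the threshold
#'   (default 0.001).
#' @param trim_quantile Quantile above which intensities are excluded from
#'   the noise fit (default 0.9).
#' @param refine Number of refinement passes (default 1).
#' @return An object of class `rayleigh_fit`: list with `sigma`,
#'   `threshold`, `tail_prob`, `trim_quantile`, `n`, `n_used`.
#' @export
fit_rayleigh <- function(intensities, tail_prob = 0.001,
                         trim_quantile = 0.9, refine = 1L) {
  x <- as.numeric(intensities)
  if (length(x) < 50L)
    abort("Rayleigh fitting needs at least 50 voxels.")
  if (any(!is.finite(x)) || any(x <= 0))
    abort("Intensities must be positive and finite (magnitude data).")
  if (tail_prob <= 0 || tail_prob >= 1)
    abort("`tail_prob` must be in (0, 1).")

  cutoff <- as.numeric(quantile(x, trim_quantile, type = 7))
  s2 <- trunc_rayleigh_mle(x[x <= cutoff], cutoff)
  for (i in seq_len(refine)) {
    cutoff <- sqrt(-2 * s2 * log(1 - trim_quantile))
    xs <- x[x <= cutoff]
    if (length(xs) < 50L) break
    s2 <- trunc_rayleigh_mle(xs, cutoff)
  }
  sigma <- sqrt(s2)
  structure(
    list(sigma = sigma,
         threshold = sigma * sqrt(-2 * log(tail_prob)),
         tail_prob = tail_prob, trim_quantile = trim_quantile,
         n = length(x), n_used = sum(x <= cutoff)),
    class = "rayleigh_fit"
  )
}

# MLE of sigma^2 for a Rayleigh sample right-truncated at `cutoff`.
# Score equation (in s = sigma^2): mean(x^2) + c^2 / (exp(c^2/2s) - 1) = 2s.
trunc_rayleigh_mle <- function(x, cutoff) {
  m2 <- mean(x^2)
  h <- function(s) m2 + cutoff^2 / expm1(cutoff^2 / (2 * s)) - 2 * s
  lo <- m2 / 4
  hi <- m2 * 4
  while (h(hi) > 0 && hi < m2 * 1e6) hi <- hi * 4
  while (h(lo) < 0 && lo > m2 * 1e-6) lo <- lo / 4
  uniroot(h, c(lo, hi), tol = .Machine$double.eps^0.75)$root
}

#' @export
print.rayleigh_fit <- function(x, ...) {
  cat("<rayleigh_fit> sigma =", signif(x$sigma, 5),
      "| threshold =", signif(x$threshold, 5),
      sprintf("(tail prob %g)\n", x$tail_prob))
  cat("  fitted on", x$n_used, "of", x$n, "voxels\n")
  invisible(x)
}

#' Choroid-plexus volume by Rayleigh thresholding
#'
#' Counts supra-threshold voxels inside the ventricle mask — the bright
#' choroid-plexus tissue standing out of the Rayleigh noise floor — and
#' converts the count to a volume (1 mm^3 = 1 uL). Optionally removes small
#' isolated supra-threshold clusters (26-connectivity); this filter is off
#' by default.
#'
#' @param volume 3D intensity array (or path to a NIfTI file).
#' @param mask Ventricle mask, same dimensions (or NIfTI path).
#' @param model A `rayleigh_fit`, or `NULL` to fit one on the masked
#'   intensities.
#' @param voxel_volume Voxel volume in mm^3.
#' @param min_cluster Minimum 26-connected cluster size kept (1 = no
#'   filtering).
#' @param ... Passed to [fit_rayleigh()] when `model` is `NULL`.
#' @return A one-row tibble: `n_cp_voxels`, `voxel_volume`, `cp_volume_ul`,
#'   `sigma`, `threshold`.
#' @export
cp_volume <- function(volume, mask, model = NULL, voxel_volume,
                      min_cluster = 1L, ...) {
  if (is.character(volume)) volume <- read_nifti_array(volume)
  if (is.character(mask)) mask <- read_nifti_array(mask)
  mask <- mask != 0
  if (!identical(dim(volume), dim(mask)))
    abort("`volume` and `mask` dimensions differ.")
  if (!any(mask)) {
    warn("Empty ventricle mask; CP volume is 0.")
    return(tibble::tibble(n_cp_voxels = 0L, voxel_volume = voxel_volume,
                          cp_volume_ul = 0, sigma = NA_real_,
                          threshold = NA_real_))
  }
  if (is.null(model)) model <- fit_rayleigh(volume[mask], ...)
  bright <- mask & (volume > model$threshold)
  if (min_cluster > 1L) bright <- drop_small_clusters(bright, min_cluster)
  n <- sum(bright)
  tibble::tibble(n_cp_voxels = as.integer(n), voxel_volume = voxel_volume,
                 cp_volume_ul = n * voxel_volume,
                 sigma = model$sigma, threshold = model$threshold)
}

# Remove 26-connected components smaller than `min_size` from a logical 3D
# array. Supra-threshold voxels are few, so a union-find over their list is
# cheap.
drop_small_clusters <- function(bright, min_size) {
  idx <- which(bright, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(bright)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lookup <- setNames(seq_len(n), key(idx))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  for (i in seq_len(n)) {
    nb <- sweep(offsets, 2, as.numeric(idx[i, ]), "+")
    hits <- lookup[key(nb)]
    for (j in hits[!is.na(hits)]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- table(roots)
  keep <- roots %in% as.integer(names(sizes)[sizes >= min_size])
  out <- array(FALSE, dim(bright))
  out[idx[keep, , drop = FALSE]] <- TRUE
  out
}

read_nifti_array <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("Reading NIfTI files requires the RNifti package.")
  as.array(RNifti::readNifti(path))
}
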