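#' Quality-control thresholds for native-space masking
#'
#' Retention rules for native-space analyses: gray-matter probability at
#' least 0.5, and exclusion of CSF-prone voxels (T2 > 90 ms),
#' high-susceptibility voxels (R2' > 9 s^-1), macrovessel-dominated voxels
#' (CBV > 10 %vol) and biologically implausible values (OEF > 0.9,
#' CBF > 90 ml/100g/min). The temporal-SNR rule drops voxels in a subject's
#' lowest 15th percentile for more than two-thirds of subjects.
#'
#' @param t2_max,r2p_max,cbv_max,oef_max,cbf_max Upper plausibility bounds.
#' @param gm_prob_min Minimum gray-matter probability.
#' @param tsnr_percentile Per-subject percentile defining the low-tSNR tail.
#' @param tsnr_subject_fraction Fraction of subjects above which a
#'   recurrently low-tSNR voxel is excluded (strict `>`).
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(t2_max = 90, r2p_max = 9, cbv_max = 10,
                          oef_max = 0.9, cbf_max = 90, gm_prob_min = 0.5,
                          tsnr_percentile = 15,
                          tsnr_subject_fraction = 2 / 3) {
  stopifnot(t2_max > 0, r2p_max > 0, cbv_max > 0, oef_max > 0, cbf_max > 0,
            gm_prob_min > 0, tsnr_percentile > 0, tsnr_percentile < 100,
            tsnr_subject_fraction > 0, tsnr_subject_fraction < 1)
  structure(list(t2_max = t2_max, r2p_max = r2p_max, cbv_max = cbv_max,
                 oef_max = oef_max, cbf_max = cbf_max,
                 gm_prob_min = gm_prob_min,
                 tsnr_percentile = tsnr_percentile,
                 tsnr_subject_fraction = tsnr_subject_fraction),
            class = "qc_thresholds")
}

#' Voxelwise monoexponential decay fit
#'
#' Fits `S(TE) = S0 exp(-TE / tau)` per voxel by weighted log-linear least
#' squares (weights = squared signal, the first-order variance weighting for
#' log-transformed Gaussian noise). Deterministic, needs no initialization,
#' and recovers the generating constants exactly on noiseless data. Voxels
#' with non-positive signal at any echo or a non-negative slope (no decay)
#' are flagged invalid.
#'
#' @param series 4-D array, last dimension = echoes, or a matrix
#'   (voxels x echoes).
#' @param te_list Echo times in ms, length matching the echo dimension.
#' @return List of `s0` and `tau` (decay constant, ms) arrays/vectors plus
#'   a logical `valid` of the same shape.
#' @export
fit_monoexponential <- function(series, te_list) {
  d <- dim(series)
  if (is.null(d)) stop("series must be an array or matrix")
  ne <- d[length(d)]
  if (ne != length(te_list)) stop("echo dimension does not match te_list")
  if (length(te_list) < 3) stop("need at least 3 echoes")
  sig <- matrix(series, ncol = ne)
  usable <- rowSums(!is.finite(sig) | sig <= 0) == 0
  n <- nrow(sig)
  s0 <- rep(NA_real_, n)
  tau <- rep(NA_real_, n)
  if (any(usable)) {
    s <- sig[usable, , drop = FALSE]
    y <- log(s)
    w <- s^2
    te <- te_list
    sw <- rowSums(w)
    mx <- rowSums(w * rep(te, each = nrow(w))) / sw
    my <- rowSums(w * y) / sw
    xc <- sweep(matrix(te, nrow(w), ne, byrow = TRUE), 1, mx)
    slope <- rowSums(w * xc * y) / rowSums(w * xc^2)
    intercept <- my - slope * mx
    s0[usable] <- exp(intercept)
    tau[usable] <- -1 / slope
  }
  valid <- usable & is.finite(tau) & tau > 0
  spatial <- d[-length(d)]
  if (length(spatial) > 1) {
    s0 <- array(s0, spatial); tau <- array(tau, spatial)
    valid <- array(valid, spatial)
  }
  list(s0 = s0, tau = tau, valid = valid)
}

#' Reversible transverse relaxation rate R2'
#'
#' `R2' = 1/T2* - 1/T2` (rates in s^-1; the stored maps are in ms and are
#' converted internally). R2' reflects a voxel's deoxyhemoglobin content.
#' Voxels where T2* exceeds T2 (negative R2', physically impossible for
#' susceptibility-driven dephasing) are marked invalid, so the valid map is
#' non-negative by construction.
#'
#' @param t2 T2 [parameter_map()], ms.
#' @param t2star T2* [parameter_map()], ms.
#' @return R2' [parameter_map()], s^-1.
#' @export
compute_r2prime <- function(t2, t2star) {
  if (!same_grid(t2$grid, t2star$grid)) stop("grid mismatch between T2 and T2*")
  ok <- t2$validity & t2star$validity & t2$values > 0 & t2star$values > 0
  r2p <- 1000 / t2star$values - 1000 / t2$values
  parameter_map(r2p, "r2prime", t2$grid, validity = ok & is.finite(r2p) &
                  r2p >= 0)
}

#' Temporal SNR of a 4-D series
#'
#' @param series 4-D array, last dimension time.
#' @return 3-D tSNR array (`NA` where temporal s.d. is zero).
#' @export
tsnr_volume <- function(series) {
  d <- dim(series)
  stopifnot(length(d) == 4L)
  m <- matrix(series, ncol = d[4])
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (d[4] - 1))
  tsnr <- ifelse(sdv > 0, mu / sdv, NA_real_)
  array(tsnr, d[1:3])
}

#' Group temporal-SNR retention mask
#'
#' Per subject, voxels in the lowest `tsnr_percentile` of that subject's
#' tSNR distribution are marked low; a voxel is excluded from the group
#' mask when it is low for strictly more than `tsnr_subject_fraction` of
#' subjects. Voxels with undefined tSNR (zero temporal variance) count as
#' low for that subject.
#'
#' @param bold_list List of 4-D BOLD arrays (or precomputed 3-D tSNR
#'   arrays), one per subject, on a common grid.
#' @param thresholds A [qc_thresholds()].
#' @return Logical retention mask (TRUE = keep).
#' @export
tsnr_mask <- function(bold_list, thresholds = qc_thresholds()) {
  if (length(bold_list) < 2) stop("need at least 2 subjects")
  low <- lapply(bold_list, function(x) {
    tsnr <- if (length(dim(x)) == 4L) tsnr_volume(x) else as.array(x)
    cut <- stats::quantile(tsnr, thresholds$tsnr_percentile / 100,
                           na.rm = TRUE, names = FALSE)
    is.na(tsnr) | tsnr <= cut
  })
  frac_low <- Reduce(`+`, low) / length(low)
  # "more than 66%" read strictly, with an epsilon so 2/3 itself is excluded
  frac_low <= thresholds$tsnr_subject_fraction - 1e-9
}

#' Native-space quality-control mask
#'
#' Applies all plausibility thresholds jointly: a voxel is retained iff the
#' gray-matter probability is at least `gm_prob_min` and every parameter
#' lies at or below its ceiling. Maps are supplied as a named list; only
#' names present among the thresholds are tested, but `gmprob` is required.
#'
#' @param maps Named list of [parameter_map()]s; recognized names `gmprob`,
#'   `t2`, `r2prime`, `cbv`, `oef`, `cbf`.
#' @param thresholds A [qc_thresholds()].
#' @param require Character vector of map names that must be present.
#' @return Logical retention mask.
#' @export
native_qc_mask <- function(maps,
                           thresholds = qc_thresholds(),
                           require = c("gmprob", "t2", "r2prime", "cbv",
                                       "oef", "cbf")) {
  missing <- setdiff(require, names(maps))
  if (length(missing)) stop("missing required map(s): ",
                            paste(missing, collapse = ", "))
  g <- maps[[1]]$grid
  for (m in maps) if (!same_grid(m$grid, g)) stop("maps do not share a grid")
  keep <- array(TRUE, g$shape)
  ceilings <- c(t2 = thresholds$t2_max, r2prime = thresholds$r2p_max,
                cbv = thresholds$cbv_max, oef = thresholds$oef_max,
                cbf = thresholds$cbf_max)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (nm == "gmprob") {
      keep <- keep & m$validity & m$values >= thresholds$gm_prob_min
    } else if (nm %in% names(ceilings)) {
      keep <- keep & m$validity & m$values <= ceilings[[nm]]
    }
  }
  keep
}
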