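#' Davis calibrated-fMRI model parameters
#'
#' `M` is the maximum BOLD signal change (%) obtained when all hemoglobin is
#' fully oxygenated, `alpha` the power-law exponent coupling fractional CBV
#' to fractional CBF changes, and `beta` a field- and vessel-geometry
#' dependent microvascular exponent. Two published settings are common at
#' 3 T: a literature set (M = 5.5, alpha = 0.23, beta = 1.3) and an
#' empirically calibrated set (M = 11.2, alpha = 0.38, beta = 1.3).
#'
#' @param m Calibration factor M, percent; must be positive.
#' @param alpha CBV-CBF coupling exponent, `0 <= alpha < beta`.
#' @param beta Microvascular exponent, positive.
#' @return Object of class `davis_params`.
#' @export
davis_params <- function(m = 5.5, alpha = 0.23, beta = 1.3) {
  stopifnot(m > 0, alpha >= 0, beta > 0, alpha < beta)
  structure(list(m = m, alpha = alpha, beta = beta), class = "davis_params")
}

#' Predict the BOLD signal change from flow and metabolism changes
#'
#' Forward Davis model:
#' \deqn{\Delta S/S_0 (\%) = M [1 - f^{\alpha-\beta} r^{\beta}]}
#' with `f` the task/baseline CBF ratio and `r` the CMRO2 ratio. Because
#' `alpha < beta`, the prediction increases with flow and decreases with
#' metabolism; a positive CMRO2 change with a sufficiently small flow change
#' therefore yields a negative (discordant) BOLD response.
#'
#' @param cbf_ratio Task/baseline CBF ratio(s), positive.
#' @param cmro2_ratio Task/baseline CMRO2 ratio(s), positive.
#' @param params A [davis_params()].
#' @return Predicted BOLD signal change in percent, same shape as inputs.
#' @export
davis_forward <- function(cbf_ratio, cmro2_ratio, params = davis_params()) {
  if (any(cbf_ratio <= 0, na.rm = TRUE) || any(cmro2_ratio <= 0, na.rm = TRUE)) {
    stop("cbf_ratio and cmro2_ratio must be positive")
  }
  params$m * (1 - cbf_ratio^(params$alpha - params$beta) *
                cmro2_ratio^params$beta)
}

#' Invert the Davis model for the CMRO2 ratio
#'
#' Solves the forward relation for the CMRO2 task/baseline ratio given a
#' measured BOLD signal change and CBF ratio:
#' \deqn{r = [(1 - \Delta S/S_0/M)\, f^{\beta-\alpha}]^{1/\beta}}
#'
#' @param dbold_pct BOLD signal change, percent.
#' @param cbf_ratio Task/baseline CBF ratio(s), positive.
#' @param params A [davis_params()].
#' @return CMRO2 ratio(s); `NA` where `dbold_pct >= M` (physically
#'   impossible, flagged invalid).
#' @export
davis_invert_cmro2 <- function(dbold_pct, cbf_ratio, params = davis_params()) {
  if (any(cbf_ratio <= 0, na.rm = TRUE)) stop("cbf_ratio must be positive")
  rem <- 1 - dbold_pct / params$m
  bad <- rem <= 0
  if (all(bad, na.rm = TRUE) && length(rem) == 1L) {
    stop("dbold_pct >= M: no physical CMRO2 ratio exists")
  }
  out <- (rem * cbf_ratio^(params$beta - params$alpha))^(1 / params$beta)
  out[bad] <- NA_real_
  out
}

#' Estimate the CBV-CBF coupling exponent alpha
#'
#' Under the power law `cbv_ratio = cbf_ratio^alpha` both log-ratios vanish
#' at baseline, so alpha is fit as the through-origin least-squares slope of
#' `log(cbv_ratio)` on `log(cbf_ratio)`.
#'
#' @param cbv_ratios Task/baseline CBV ratios, positive.
#' @param cbf_ratios Task/baseline CBF ratios, positive, paired with
#'   `cbv_ratios`.
#' @return Estimated exponent alpha.
#' @export
estimate_alpha <- function(cbv_ratios, cbf_ratios) {
  stopifnot(length(cbv_ratios) == length(cbf_ratios))
  keep <- is.finite(cbv_ratios) & is.finite(cbf_ratios) &
    cbv_ratios > 0 & cbf_ratios > 0
  x <- log(cbf_ratios[keep])
  y <- log(cbv_ratios[keep])
  if (sum(x^2) == 0) stop("all cbf_ratios equal 1: no leverage to fit alpha")
  sum(x * y) / sum(x^2)
}

#' Estimate a subject's calibration factor M
#'
#' Per voxel, `M_v = dBOLD_v / (1 - f_v^(alpha-beta) r_v^beta)`; the subject
#' value is the median over voxels whose denominator is bounded away from
#' zero. The median guards against near-singular denominators at voxels with
#' tiny responses.
#'
#' @param dbold_pct BOLD signal changes, percent, per voxel.
#' @param cbf_ratio CBF task/baseline ratios per voxel.
#' @param cmro2_ratio CMRO2 task/baseline ratios per voxel.
#' @param alpha,beta Davis exponents used in the denominator.
#' @param min_denom Minimum |denominator| for a voxel to be eligible.
#' @return Median M over eligible voxels.
#' @export
estimate_m <- function(dbold_pct, cbf_ratio, cmro2_ratio,
                       alpha = 0.38, beta = 1.3, min_denom = 1e-6) {
  denom <- 1 - cbf_ratio^(alpha - beta) * cmro2_ratio^beta
  keep <- is.finite(denom) & is.finite(dbold_pct) & abs(denom) > min_denom
  if (!any(keep)) stop("no eligible voxels: all Davis denominators below ",
                       min_denom)
  stats::median(dbold_pct[keep] / denom[keep])
}
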