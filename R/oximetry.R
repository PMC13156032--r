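#' Susceptibility scaling constant of the oxygenation equation
#'
#' Computes `c = gamma * (4/3) * pi * delta_chi0 * Hct_sv * B0`, where
#' `Hct_sv` is the small-vessel hematocrit (85% of the measured large-vessel
#' value by default). `c` converts the deoxyhemoglobin-sensitive relaxation
#' rate R2' and the blood volume fraction into an oxygen extraction
#' fraction.
#'
#' @param phys A [subject_physiology()].
#' @param consts A [physical_constants()].
#' @return Scaling constant `c` in s^-1.
#' @export
compute_c <- function(phys, consts = physical_constants()) {
  if (phys$hct_large_vessel <= 0) stop("hematocrit must be positive")
  hct_sv <- phys$small_vessel_factor * phys$hct_large_vessel
  consts$gamma * (4 / 3) * pi * consts$delta_chi0 * hct_sv * consts$b0
}

#' Oxygen extraction fraction from R2' and CBV
#'
#' The multiparametric quantitative BOLD relation `OEF = R2' / (c * CBV)`,
#' with CBV converted from percent volume to a fraction inside this
#' function only (stored maps stay in %vol). Voxels with non-positive CBV
#' or OEF above `oef_max` are marked invalid.
#'
#' @param r2p R2' [parameter_map()], s^-1.
#' @param cbv CBV [parameter_map()], %vol.
#' @param c_const Scaling constant from [compute_c()], s^-1.
#' @param oef_max Plausibility ceiling for OEF; values above are invalid.
#' @return OEF [parameter_map()] (ratio).
#' @export
compute_oef <- function(r2p, cbv, c_const, oef_max = 0.9) {
  if (c_const <= 0) stop("c must be positive")
  if (!same_grid(r2p$grid, cbv$grid)) stop("grid mismatch between R2' and CBV")
  cbv_frac <- cbv$values / 100
  oef <- r2p$values / (c_const * cbv_frac)
  ok <- r2p$validity & cbv$validity & cbv_frac > 0
  ok <- ok & is.finite(oef) & oef <= oef_max
  parameter_map(oef, "oef", r2p$grid, validity = ok)
}

#' Arterial oxygen content
#'
#' `CaO2 = 0.334 * Hct * 55.6 * O2sat`, in umol O2 per ml blood, from the
#' subject's large-vessel hematocrit and pulse-oximetry saturation.
#'
#' @param phys A [subject_physiology()].
#' @param consts A [physical_constants()].
#' @return Arterial oxygen content, umol/ml.
#' @export
compute_cao2 <- function(phys, consts = physical_constants()) {
  consts$cao2_slope * phys$hct_large_vessel * consts$cao2_mmol_factor *
    phys$o2sat
}

#' CMRO2 via Fick's principle
#'
#' Voxelwise `CMRO2 = OEF * CBF * CaO2`, in umol per 100 g per min.
#'
#' @param oef OEF [parameter_map()].
#' @param cbf CBF [parameter_map()], ml/100g/min.
#' @param cao2 Arterial oxygen content from [compute_cao2()], umol/ml.
#' @return CMRO2 [parameter_map()].
#' @export
compute_cmro2 <- function(oef, cbf, cao2) {
  if (!same_grid(oef$grid, cbf$grid)) stop("grid mismatch between OEF and CBF")
  parameter_map(oef$values * cbf$values * cao2, "cmro2", oef$grid,
                validity = oef$validity & cbf$validity)
}

#' BOLD-informed task R2'
#'
#' Instead of refitting T2* during a task, the task-state R2' is derived
#' from the baseline R2' and the BOLD percent signal change:
#' \deqn{\Delta R2' = -\frac{\Delta S/S_0}{TE \times R2'_0}}
#' treated as a fractional change, i.e. `R2'_task = R2'_0 (1 + dR2')`. This
#' semiquantitative path avoids propagating noisy task-state multi-echo
#' fits into OEF and CMRO2.
#'
#' @param baseline_r2p Baseline R2' [parameter_map()], s^-1.
#' @param psc_frac BOLD signal change as a fraction (dS/S0, not percent):
#'   a numeric array or a `psc` [parameter_map()] holding percent (then
#'   divided by 100 internally).
#' @param te_bold BOLD echo time in ms (converted to seconds internally).
#' @return Task-state R2' [parameter_map()]; voxels with non-positive
#'   baseline R2' or non-positive task R2' are invalid.
#' @export
bold_informed_r2prime <- function(baseline_r2p, psc_frac, te_bold = 30) {
  if (inherits(psc_frac, "parameter_map")) {
    ok <- psc_frac$validity
    psc_frac <- psc_frac$values / 100
  } else {
    psc_frac <- as.array(psc_frac)
    ok <- is.finite(psc_frac)
  }
  te_s <- te_bold / 1000
  r2p0 <- baseline_r2p$values
  pos <- baseline_r2p$validity & r2p0 > 0
  dr2p_frac <- -psc_frac / (te_s * r2p0)
  task <- r2p0 * (1 + dr2p_frac)
  parameter_map(task, "r2prime", baseline_r2p$grid,
                validity = pos & ok & is.finite(task) & task > 0)
}
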