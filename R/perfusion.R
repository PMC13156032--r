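#' ASL quantification constants
#'
#' Single-compartment consensus constants for pCASL quantification:
#' blood-brain partition coefficient lambda = 0.9 ml/g, arterial blood T1 =
#' 1650 ms at 3 T, labeling efficiency 0.85, and the 25% upscaling factor
#' that compensates the systematic CBF underestimation caused by the four
#' background-suppression pulses.
#'
#' @param lambda_partition Blood-brain partition coefficient, ml/g.
#' @param t1_blood T1 of arterial blood, ms.
#' @param label_efficiency Labeling efficiency (fraction).
#' @param upscale Multiplicative correction applied to quantified CBF.
#' @param pld Post-labeling delay, ms.
#' @param label_duration Label duration, ms.
#' @return Object of class `asl_constants`.
#' @export
asl_constants <- function(lambda_partition = 0.9, t1_blood = 1650,
                          label_efficiency = 0.85, upscale = 1.25,
                          pld = 1800, label_duration = 1800) {
  stopifnot(lambda_partition > 0, t1_blood > 0, label_efficiency > 0,
            label_efficiency <= 1, upscale > 0, pld > 0, label_duration > 0)
  structure(list(lambda_partition = lambda_partition, t1_blood = t1_blood,
                 label_efficiency = label_efficiency, upscale = upscale,
                 pld = pld, label_duration = label_duration),
            class = "asl_constants")
}

#' DSC normalization constants
#'
#' @param wm_reference_cbv CBV value (in %vol) that the white-matter
#'   reference region is pinned to.
#' @param n_baseline_dynamics Number of pre-bolus frames used for the
#'   baseline signal.
#' @return Object of class `dsc_constants`.
#' @export
dsc_constants <- function(wm_reference_cbv = 2.5, n_baseline_dynamics = 5) {
  stopifnot(wm_reference_cbv > 0, n_baseline_dynamics >= 1)
  structure(list(wm_reference_cbv = wm_reference_cbv,
                 n_baseline_dynamics = as.integer(n_baseline_dynamics)),
            class = "dsc_constants")
}

# Scale factor of the single-compartment pCASL model: CBF = asl_scale * dM/M0.
# Shared by quantification and by the phantom's forward signal model.
asl_scale_factor <- function(consts) {
  t1b_s <- consts$t1_blood / 1000
  6000 * consts$lambda_partition * exp(consts$pld / consts$t1_blood) /
    (2 * consts$label_efficiency * t1b_s *
       (1 - exp(-consts$label_duration / consts$t1_blood)))
}

#' Quantify CBF from a pCASL series
#'
#' Averages the pairwise control-minus-label differences, scales by the
#' proton-density-weighted M0 image through the single-compartment
#' consensus model, and applies the background-suppression upscaling:
#' \deqn{CBF = 1.25 \times \frac{6000\,\lambda\,\Delta M\, e^{PLD/T1b}}
#' {2\,\epsilon\, T1b\, M0\, (1 - e^{-\tau/T1b})}}
#' in ml/100g/min (T1b in seconds inside the quotient).
#'
#' @param series List with 4-D arrays `control` and `label` (last dimension
#'   = dynamics, equal counts).
#' @param m0 3-D proton-density-weighted array; voxels with `m0 <= 0` are
#'   invalid.
#' @param grid The [volume_grid()] of the series.
#' @param consts An [asl_constants()].
#' @return CBF [parameter_map()], ml/100g/min.
#' @export
quantify_cbf <- function(series, m0, grid, consts = asl_constants()) {
  ctrl <- series$control; lab <- series$label
  dc <- dim(ctrl); dl <- dim(lab)
  if (!identical(dc, dl)) stop("mismatched label/control dynamics")
  if (all(m0 <= 0)) stop("all-zero M0 volume")
  nd <- dc[4]
  dm <- (rowMeans(matrix(ctrl, ncol = nd)) -
           rowMeans(matrix(lab, ncol = nd)))
  m0v <- as.numeric(m0)
  ok <- is.finite(m0v) & m0v > 0
  cbf <- rep(NA_real_, length(m0v))
  cbf[ok] <- consts$upscale * asl_scale_factor(consts) * dm[ok] / m0v[ok]
  parameter_map(array(cbf, grid$shape), "cbf", grid,
                validity = array(ok, grid$shape))
}

#' Quantify CBV from a DSC bolus series
#'
#' Converts the bolus signal drop to a relaxation-rate curve
#' `dR2*(t) = -ln(S(t)/S0)/TE` with `S0` the mean of the pre-bolus frames,
#' integrates it (trapezoid) over the bolus window -- the contiguous run of
#' frames around the peak where `dR2*` exceeds 5% of its peak -- and
#' normalizes the relative integral so the white-matter median equals the
#' reference CBV (2.5 %vol).
#'
#' @param series 4-D DSC signal array (last dimension = dynamics).
#' @param wm_mask Logical 3-D array marking the white-matter reference.
#' @param grid The [volume_grid()].
#' @param te_dsc DSC echo time, ms.
#' @param tr_dsc Dynamic spacing, s.
#' @param consts A [dsc_constants()].
#' @return CBV [parameter_map()], %vol.
#' @export
quantify_cbv <- function(series, wm_mask, grid, te_dsc = 30, tr_dsc = 2.0,
                         consts = dsc_constants()) {
  if (!any(wm_mask)) stop("empty WM mask")
  d <- dim(series)
  nd <- d[4]
  nb <- consts$n_baseline_dynamics
  if (nd <= nb) stop("need more dynamics than pre-bolus frames")
  sig <- matrix(series, ncol = nd)
  usable <- rowSums(!is.finite(sig) | sig <= 0) == 0
  if (!any(usable)) stop("non-positive DSC signal at every voxel")
  sig[!usable, ] <- 1                    # placeholder; flagged invalid below
  s0 <- rowMeans(sig[, seq_len(nb), drop = FALSE])
  te_s <- te_dsc / 1000
  dr2s <- -log(sig / s0) / te_s
  # bolus window: contiguous frames around the global peak of the mean curve
  mean_curve <- colMeans(dr2s[usable, , drop = FALSE])
  pk <- which.max(mean_curve)
  thr <- 0.05 * mean_curve[pk]
  lo <- pk; while (lo > 1 && mean_curve[lo - 1] > thr) lo <- lo - 1
  hi <- pk; while (hi < nd && mean_curve[hi + 1] > thr) hi <- hi + 1
  idx <- lo:hi
  if (length(idx) >= 2) {
    wts <- rep(tr_dsc, length(idx))
    wts[c(1, length(idx))] <- tr_dsc / 2
    rel <- as.numeric(dr2s[, idx, drop = FALSE] %*% wts)
  } else {
    rel <- dr2s[, idx] * tr_dsc
  }
  wm_ok <- as.logical(wm_mask) & usable
  if (!any(wm_ok)) stop("empty WM mask (no usable WM voxels)")
  wm_ref <- stats::median(rel[wm_ok])
  if (!is.finite(wm_ref) || wm_ref <= 0) stop("WM reference integral is not positive")
  cbv <- rel * consts$wm_reference_cbv / wm_ref
  parameter_map(array(cbv, grid$shape), "cbv", grid,
                validity = array(usable, grid$shape))
}

#' Parcel-based task CBV surrogate
#'
#' Applies parcel-averaged fractional CBV changes (measured in a subject
#' subset) to a baseline CBV map: `CBV_task(v) = CBV_base(v) *
#' (1 + dCBV%(parcel(v))/100)`.
#'
#' @param baseline_cbv Baseline CBV [parameter_map()].
#' @param parcel_map Integer 3-D array assigning each voxel a parcel id
#'   (0 or NA = unassigned; unassigned valid voxels are an error).
#' @param parcel_delta_pct Data frame with columns `parcel_id` and
#'   `delta_cbv_pct`.
#' @return Task-state CBV [parameter_map()].
#' @export
apply_cbv_surrogate <- function(baseline_cbv, parcel_map, parcel_delta_pct) {
  stopifnot(is.data.frame(parcel_delta_pct),
            all(c("parcel_id", "delta_cbv_pct") %in% names(parcel_delta_pct)))
  pm <- as.array(parcel_map)
  if (!identical(dim(pm), as.integer(baseline_cbv$grid$shape))) {
    stop("parcel map shape does not match CBV grid")
  }
  ids <- pm[baseline_cbv$validity & !is.na(pm) & pm > 0]
  missing <- setdiff(unique(ids), parcel_delta_pct$parcel_id)
  if (length(missing)) stop("no delta-CBV entry for parcel id(s): ",
                            paste(missing, collapse = ", "))
  delta <- array(0, dim(pm))
  idx <- match(pm, parcel_delta_pct$parcel_id)
  got <- !is.na(idx)
  delta[got] <- parcel_delta_pct$delta_cbv_pct[idx[got]]
  vals <- baseline_cbv$values * (1 + delta / 100)
  parameter_map(vals, "cbv", baseline_cbv$grid,
                validity = baseline_cbv$validity)
}
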