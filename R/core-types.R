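#' Define a volume grid
#'
#' A `volume_grid` records the voxel lattice shared by all maps and series of
#' one subject: array dimensions, voxel size in mm, and a 4x4 voxel-to-world
#' affine (RAS+, 0-based voxel indices).
#'
#' @param shape Integer vector of length 3, array dimensions (voxels).
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(2, 2, 3), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be invertible")
  }
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, voxel %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$affine, b$affine))
}

#' Recognized parameter-map kinds and their units
#'
#' @return Named character vector mapping kind to unit string.
#' @export
map_kinds <- function() {
  c(t2 = "ms", t2star = "ms", r2prime = "1/s", cbv = "%vol",
    oef = "ratio", cbf = "ml/100g/min", cmro2 = "umol/100g/min",
    tsnr = "unitless", gmprob = "ratio", psc = "%", delta_pct = "%",
    zstat = "z", bsr = "bsr")
}

#' Construct a voxelwise parameter map
#'
#' One scalar value per voxel with a physical kind, plus an explicit validity
#' flag per voxel. Validity is never encoded as a sentinel value: invalid
#' voxels keep whatever number they held, and downstream summaries ignore
#' them.
#'
#' @param values Numeric 3-D array matching `grid$shape`.
#' @param kind One of `names(map_kinds())`.
#' @param grid A [volume_grid()].
#' @param validity Logical array of the same shape; defaults to
#'   `is.finite(values)`.
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(values, kind, grid, validity = NULL) {
  kind <- match.arg(kind, names(map_kinds()))
  values <- as.array(values)
  stopifnot(identical(dim(values), as.integer(grid$shape)))
  if (is.null(validity)) {
    validity <- is.finite(values)
  }
  validity <- as.array(validity)
  stopifnot(identical(dim(validity), dim(values)), is.logical(validity))
  validity <- validity & is.finite(values)
  structure(list(values = values, validity = validity, kind = kind,
                 grid = grid),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$validity]
  cat(sprintf("<parameter_map %s [%s], %s, %d/%d valid, median %.4g>\n",
              x$kind, map_kinds()[[x$kind]],
              paste(x$grid$shape, collapse = "x"),
              sum(x$validity), length(x$validity),
              if (length(v)) stats::median(v) else NA_real_))
  invisible(x)
}

#' Summary statistics of a parameter map over its valid voxels
#'
#' @param map A [parameter_map()].
#' @param mask Optional logical array restricting the summary.
#' @return Named list with n, mean, sd, median.
#' @export
map_stats <- function(map, mask = NULL) {
  keep <- map$validity
  if (!is.null(mask)) keep <- keep & mask
  v <- map$values[keep]
  list(n = length(v), mean = mean(v), sd = stats::sd(v),
       median = stats::median(v))
}

#' Subject physiology
#'
#' Large-vessel hematocrit and pulse-oximetry oxygen saturation, plus the
#' factor converting large-vessel to small-vessel hematocrit (85%).
#'
#' @param hct Large-vessel hematocrit, fraction in (0, 1).
#' @param o2sat Arterial oxygen saturation, fraction in (0, 1].
#' @param small_vessel_factor Small-vessel hematocrit as a fraction of the
#'   large-vessel value.
#' @return Object of class `subject_physiology`.
#' @export
subject_physiology <- function(hct = 0.375, o2sat = 0.98,
                               small_vessel_factor = 0.85) {
  stopifnot(hct > 0, hct < 1, o2sat > 0, o2sat <= 1,
            small_vessel_factor > 0, small_vessel_factor <= 1)
  structure(list(hct_large_vessel = hct, o2sat = o2sat,
                 small_vessel_factor = small_vessel_factor),
            class = "subject_physiology")
}

#' Physical constants of the oxygenation model
#'
#' @param gamma Gyromagnetic ratio of the proton, s^-1 T^-1.
#' @param delta_chi0 Susceptibility difference between fully deoxygenated
#'   and fully oxygenated hemoglobin (dimensionless, SI).
#' @param b0 Main field strength in tesla.
#' @param cao2_slope Hemoglobin O2-carrying slope in the arterial oxygen
#'   content formula.
#' @param cao2_mmol_factor Conversion factor to umol O2 per ml blood.
#' @return Object of class `physical_constants`.
#' @export
physical_constants <- function(gamma = 2.675e8, delta_chi0 = 0.264e-6,
                               b0 = 3, cao2_slope = 0.334,
                               cao2_mmol_factor = 55.6) {
  stopifnot(gamma > 0, delta_chi0 > 0, b0 > 0, cao2_slope > 0,
            cao2_mmol_factor > 0)
  structure(list(gamma = gamma, delta_chi0 = delta_chi0, b0 = b0,
                 cao2_slope = cao2_slope,
                 cao2_mmol_factor = cao2_mmol_factor),
            class = "physical_constants")
}

#' Acquisition parameters
#'
#' Echo times and timing of the multi-echo, BOLD, ASL and DSC sequences.
#' Defaults mirror a 3 T protocol: 8 spin-echo echoes at TE1 = dTE = 16 ms,
#' 12 gradient-echo echoes at TE1 = dTE = 5 ms, BOLD TE 30 ms / TR 1.2 s,
#' labeling 1800 ms with 1800 ms post-labeling delay, DSC TE 30 ms at
#' TR 2 s.
#'
#' @param te_list_se Spin-echo echo times, ms.
#' @param te_list_gre Gradient-echo echo times, ms.
#' @param te_bold BOLD echo time, ms.
#' @param tr_bold BOLD repetition time, s.
#' @param pld Post-labeling delay, ms.
#' @param label_duration Label duration, ms.
#' @param te_dsc DSC echo time, ms.
#' @param tr_dsc DSC repetition time, s.
#' @return Object of class `acquisition_params`.
#' @export
acquisition_params <- function(te_list_se = seq(16, by = 16, length.out = 8),
                               te_list_gre = seq(5, by = 5, length.out = 12),
                               te_bold = 30, tr_bold = 1.2,
                               pld = 1800, label_duration = 1800,
                               te_dsc = 30, tr_dsc = 2.0) {
  stopifnot(all(diff(te_list_se) > 0), all(te_list_se > 0),
            all(diff(te_list_gre) > 0), all(te_list_gre > 0),
            te_bold > 0, tr_bold > 0, pld > 0, label_duration > 0,
            te_dsc > 0, tr_dsc > 0)
  structure(list(te_list_se = te_list_se, te_list_gre = te_list_gre,
                 te_bold = te_bold, tr_bold = tr_bold, pld = pld,
                 label_duration = label_duration, te_dsc = te_dsc,
                 tr_dsc = tr_dsc),
            class = "acquisition_params")
}
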