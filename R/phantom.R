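#' Specification of a synthetic multiparametric fMRI subject cohort
#'
#' The phantom is a cortical-shell ellipsoid: a gray-matter (GM) ribbon
#' wrapped around a white-matter (WM) core inside an otherwise empty grid.
#' Per subject, GM baseline fields for R2', CBV, CBF and T2 are drawn as a
#' subject mean (Gaussian across subjects with the stated cohort means and
#' between-subject s.d.) plus voxelwise Gaussian spatial variation,
#' truncated to positive. OEF is then *derived* from R2' and CBV through
#' the oxygenation equation with the subject's hematocrit, and CMRO2 is
#' derived through Fick's principle, so both identities hold exactly on
#' every ground-truth map. Task-state fields apply the requested effect
#' populations: canonical voxels couple flow to metabolism through an
#' n-ratio, discordant voxels receive a stated (weak or opposite) flow
#' change, and in both cases the OEF change solves Fick's identity.
#'
#' @param grid A [volume_grid()]; default 32 x 32 x 16 voxels.
#' @param n_subjects Number of subjects to generate.
#' @param seed Base random seed; subject `i` uses `seed + i`.
#' @param gm_fraction Fraction of the brain ellipsoid occupied by the GM
#'   shell (sets the WM core radius).
#' @param baseline_means Named GM cohort means: `r2prime` (s^-1), `cbv`
#'   (%vol), `cbf` (ml/100g/min), `t2` (ms).
#' @param baseline_sds Between-subject s.d. of the same quantities.
#' @param within_map_sd Voxelwise spatial s.d. of the same quantities
#'   (within a subject's GM).
#' @param wm_means WM tissue values; WM R2' is derived from `oef` via the
#'   oxygenation equation so WM is Fick-consistent too.
#' @param physiology_means,physiology_sds Cohort mean and s.d. of
#'   large-vessel hematocrit and O2 saturation.
#' @param snr Signal-to-noise ratio per modality (`se`, `gre`, `asl`,
#'   `dsc`, `bold`); `Inf` disables noise.
#' @param effect_spec List of voxel populations. Each element is a list
#'   with `name`, `dcmro2_pct`, `gm_frac` (fraction of GM voxels) and
#'   either `mode = "canonical"` with `n_ratio` or `mode = "discordant"`
#'   with `dcbf_pct`.
#' @param amp_jitter Voxelwise effect-amplitude heterogeneity: each effect
#'   voxel's `dCMRO2` and `dCBF` are scaled by a factor drawn uniformly
#'   from `[1 - amp_jitter, 1 + amp_jitter]` (a cohort-level map, shared
#'   by all subjects, like the effect footprint itself). Real task
#'   responses span an amplitude range; a bounded jitter keeps every
#'   designed effect detectable.
#' @param davis A [davis_params()] used to generate BOLD responses.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = volume_grid(c(32, 32, 16)),
                         n_subjects = 20,
                         seed = 1,
                         gm_fraction = 0.5,
                         baseline_means = c(r2prime = 5.3, cbv = 4.8,
                                            cbf = 44.5, t2 = 75),
                         baseline_sds = c(r2prime = 0.4, cbv = 0.2,
                                          cbf = 7.2, t2 = 3),
                         within_map_sd = c(r2prime = 0.6, cbv = 0.35,
                                           cbf = 3, t2 = 3),
                         wm_means = c(cbv = 2.5, cbf = 25, t2 = 65,
                                      oef = 0.39),
                         physiology_means = c(hct = 0.375, o2sat = 0.98),
                         physiology_sds = c(hct = 0.03, o2sat = 0.005),
                         snr = c(se = 100, gre = 100, asl = 100, dsc = 100,
                                 bold = 100),
                         effect_spec = list(
                           list(name = "canonical", mode = "canonical",
                                dcmro2_pct = 3.1, n_ratio = 2.1,
                                gm_frac = 0.15),
                           list(name = "discordant", mode = "discordant",
                                dcmro2_pct = 1.68, dcbf_pct = -0.47,
                                gm_frac = 0.10)),
                         amp_jitter = 0.25,
                         davis = davis_params()) {
  stopifnot(all(baseline_means > 0), gm_fraction > 0, gm_fraction < 1,
            n_subjects >= 1, all(unlist(snr) > 0))
  total_frac <- sum(vapply(effect_spec, function(e) e$gm_frac, 0))
  stopifnot(total_frac < 1)
  structure(list(grid = grid, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), gm_fraction = gm_fraction,
                 baseline_means = baseline_means,
                 baseline_sds = baseline_sds,
                 within_map_sd = within_map_sd, wm_means = wm_means,
                 physiology_means = physiology_means,
                 physiology_sds = physiology_sds,
                 snr = snr, effect_spec = effect_spec,
                 amp_jitter = amp_jitter, davis = davis),
            class = "phantom_spec")
}

# Ellipsoid tissue geometry: normalized radius, WM core sized so the GM
# shell holds gm_fraction of the brain volume.
phantom_geometry <- function(grid, gm_fraction) {
  sh <- grid$shape
  ctr <- (sh + 1) / 2
  semi <- sh / 2 - 0.5
  idx <- arrayInd(seq_len(prod(sh)), sh)
  r <- sqrt(((idx[, 1] - ctr[1]) / semi[1])^2 +
              ((idx[, 2] - ctr[2]) / semi[2])^2 +
              ((idx[, 3] - ctr[3]) / semi[3])^2)
  r <- array(r, sh)
  rc <- (1 - gm_fraction)^(1 / 3)
  brain <- r < 1
  wm <- r < rc
  gm <- brain & !wm
  list(brain = brain, gm = gm, wm = wm)
}

# Positive-truncated Gaussian spatial field over a mask.
spatial_field <- function(shape, mask, mean, sd, floor = NULL) {
  f <- array(0, shape)
  n <- sum(mask)
  if (is.null(floor)) floor <- mean * 0.05
  f[mask] <- pmax(stats::rnorm(n, mean, sd), floor)
  f
}

#' Generate ground-truth parameter fields for one synthetic subject
#'
#' Draws the subject's physiology and baseline GM/WM fields, applies the
#' effect populations to form task-state fields, derives OEF and CMRO2 so
#' that the oxygenation equation and Fick's principle hold exactly at every
#' brain voxel, and records the designed voxel class labels and the
#' designed BOLD response (Davis forward model) per voxel. Generation
#' fails if any effect drives OEF outside (0, 0.9], or if a designed label
#' contradicts the sign relation it encodes (checked exhaustively).
#'
#' @param spec A [phantom_spec()].
#' @param subject_index Subject number in `1:spec$n_subjects`.
#' @return Object of class `ground_truth`: per-condition map lists
#'   (`ctrl`, `task`), tissue masks, designed labels and BOLD amplitudes,
#'   effect table and subject physiology.
#' @export
generate_ground_truth <- function(spec, subject_index = 1) {
  stopifnot(subject_index >= 1, subject_index <= spec$n_subjects)
  set.seed(spec$seed + subject_index)
  g <- spec$grid
  sh <- g$shape
  geo <- phantom_geometry(g, spec$gm_fraction)

  hct <- min(max(stats::rnorm(1, spec$physiology_means[["hct"]],
                              spec$physiology_sds[["hct"]]), 0.25), 0.55)
  o2sat <- min(stats::rnorm(1, spec$physiology_means[["o2sat"]],
                            spec$physiology_sds[["o2sat"]]), 1)
  phys <- subject_physiology(hct = hct, o2sat = o2sat)
  c_const <- compute_c(phys)
  cao2 <- compute_cao2(phys)

  # subject-level GM means, then spatial fields; WM is fixed-tissue + noise
  kinds <- c("r2prime", "cbv", "cbf", "t2")
  subj_mean <- stats::setNames(vapply(kinds, function(k) {
    pmax(stats::rnorm(1, spec$baseline_means[[k]], spec$baseline_sds[[k]]),
         spec$baseline_means[[k]] * 0.2)
  }, 0), kinds)
  wm_r2p <- c_const * (spec$wm_means[["cbv"]] / 100) * spec$wm_means[["oef"]]
  wm_val <- c(r2prime = unname(wm_r2p), cbv = spec$wm_means[["cbv"]],
              cbf = spec$wm_means[["cbf"]], t2 = spec$wm_means[["t2"]])
  base <- lapply(kinds, function(k) {
    f <- spatial_field(sh, geo$gm, subj_mean[[k]], spec$within_map_sd[[k]])
    if (k == "cbv") {
      # WM is the DSC normalization anchor: homogeneous by construction,
      # so the pipeline's WM-median rescaling is exact
      f[geo$wm] <- wm_val[[k]]
    } else {
      f[geo$wm] <- pmax(stats::rnorm(sum(geo$wm), wm_val[[k]],
                                     spec$within_map_sd[[k]] / 2),
                        wm_val[[k]] * 0.05)
    }
    f
  })
  names(base) <- kinds

  # designed effect populations on disjoint random GM voxel sets; the
  # layout is drawn from the cohort seed so every subject activates the
  # same voxels (a group effect), independent of subject-level noise
  layout <- local({
    set.seed(spec$seed)
    ord <- sample(which(geo$gm))
    list(order = ord,
         amp = stats::runif(length(ord), 1 - spec$amp_jitter,
                            1 + spec$amp_jitter))
  })
  set.seed(spec$seed + spec$n_subjects + subject_index)
  labels <- array("none", sh)
  dcbf <- array(0, sh)
  dcmro2 <- array(0, sh)
  gm_idx <- layout$order
  n_gm <- length(gm_idx)
  taken <- 0L
  effects <- list()
  for (e in spec$effect_spec) {
    nv <- round(e$gm_frac * n_gm)
    pick <- taken + seq_len(nv)
    vox <- gm_idx[pick]
    taken <- taken + nv
    df <- if (e$mode == "canonical") e$n_ratio * e$dcmro2_pct else e$dcbf_pct
    labels[vox] <- e$mode
    dcbf[vox] <- df * layout$amp[pick]
    dcmro2[vox] <- e$dcmro2_pct * layout$amp[pick]
    effects[[e$name]] <- list(mode = e$mode, dcmro2_pct = e$dcmro2_pct,
                              dcbf_pct = df, n_voxels = nv)
  }
  # OEF change solving Fick's identity on the ratios
  doef <- array(0, sh)
  act <- labels != "none"
  doef[act] <- 100 * ((1 + dcmro2[act] / 100) / (1 + dcbf[act] / 100) - 1)

  make_cond <- function(cbf, oef_scale) {
    oef <- array(0, sh)
    brain <- geo$brain
    oef[brain] <- base$r2prime[brain] /
      (c_const * base$cbv[brain] / 100) * oef_scale[brain]
    if (any(oef[brain] <= 0 | oef[brain] > 0.9)) {
      stop("effect magnitudes drive OEF outside (0, 0.9]")
    }
    r2p <- c_const * (base$cbv / 100) * oef            # Eq. consistency
    t2star <- 1000 / (1000 / base$t2 + r2p)
    cmro2 <- oef * cbf * cao2
    mk <- function(v, k) parameter_map(v, k, g, validity = brain)
    list(t2 = mk(base$t2, "t2"), t2star = mk(t2star, "t2star"),
         r2prime = mk(r2p, "r2prime"), cbv = mk(base$cbv, "cbv"),
         cbf = mk(cbf, "cbf"), oef = mk(oef, "oef"),
         cmro2 = mk(cmro2, "cmro2"))
  }
  ones <- array(1, sh)
  ctrl <- make_cond(base$cbf, ones)
  task <- make_cond(base$cbf * (1 + dcbf / 100), ones * (1 + doef / 100))

  # designed BOLD response per voxel, and the sign checks the labels encode
  f_ratio <- 1 + dcbf / 100
  r_ratio <- 1 + dcmro2 / 100
  dbold <- davis_forward(f_ratio, r_ratio, spec$davis)
  can <- labels == "canonical"
  dis <- labels == "discordant"
  if (any(sign(dbold[can]) != sign(dcmro2[can])) ||
      any(sign(dbold[dis]) == sign(dcmro2[dis]))) {
    stop("designed BOLD signs contradict the designed labels")
  }

  structure(list(grid = g, subject_index = subject_index,
                 physiology = phys, cao2 = cao2, c_const = c_const,
                 masks = geo, conditions = list(ctrl = ctrl, task = task),
                 labels = labels,
                 designed = list(dbold_pct = dbold, dcbf_pct = dcbf,
                                 dcmro2_pct = dcmro2, doef_pct = doef),
                 effects = effects, davis = spec$davis),
            class = "ground_truth")
}

#' Simulate a multi-echo spin- or gradient-echo acquisition
#'
#' Forward model of the relaxometry fit: `S(TE) = S0 exp(-TE/tau)` voxelwise
#' with `tau` the ground-truth T2 (spin echo) or T2* (gradient echo), plus
#' Gaussian noise of s.d. `S0/snr`, truncated at zero. Magnitude noise is
#' modeled as Gaussian, adequate in the SNR >= 50 regime.
#'
#' @param gt A [generate_ground_truth()] result.
#' @param sequence `"se"` or `"gre"`.
#' @param condition `"ctrl"` or `"task"`.
#' @param snr Signal-to-noise ratio; `Inf` for noiseless.
#' @param seed Random seed.
#' @param acq An [acquisition_params()] providing the echo times.
#' @param s0 Baseline signal amplitude inside the brain.
#' @return List with the 4-D `data` (last dim = echoes), `te_list`, `grid`.
#' @export
simulate_multiecho <- function(gt, sequence = c("se", "gre"),
                               condition = "ctrl", snr = Inf, seed = 1,
                               acq = acquisition_params(), s0 = 1000) {
  sequence <- match.arg(sequence)
  if (snr <= 0) stop("snr must be positive")
  set.seed(seed)
  te <- if (sequence == "se") acq$te_list_se else acq$te_list_gre
  tau <- if (sequence == "se") gt$conditions[[condition]]$t2$values
         else gt$conditions[[condition]]$t2star$values
  sh <- gt$grid$shape
  brain <- gt$masks$brain
  sig <- array(0, c(sh, length(te)))
  for (k in seq_along(te)) {
    s <- array(0, sh)
    s[brain] <- s0 * exp(-te[k] / tau[brain])
    if (is.finite(snr)) {
      s[brain] <- pmax(s[brain] + stats::rnorm(sum(brain), 0, s0 / snr), 0)
    }
    sig[, , , k] <- s
  }
  list(data = sig, te_list = te, grid = gt$grid, sequence = sequence)
}

#' Simulate a pCASL label/control series with M0
#'
#' The control-minus-label difference is built by inverting the
#' single-compartment quantification model at 0.8 x the true CBF,
#' emulating the signal loss caused by background suppression, so that the
#' pipeline's 25% upscaling restores the true value. Noise is added per
#' dynamic.
#'
#' @param gt A [generate_ground_truth()] result.
#' @param condition `"ctrl"` or `"task"`.
#' @param n_pairs Number of label/control pairs.
#' @param snr SNR of the perfusion-weighted signal: per-dynamic noise s.d.
#'   is `mean(brain dM)/snr`. Background suppression removes most static
#'   tissue signal, so the difference signal is the quantity the modality
#'   delivers and the natural SNR reference. `Inf` for noiseless.
#' @param seed Random seed.
#' @param consts An [asl_constants()] (same constants the pipeline uses).
#' @param m0_value Tissue M0 amplitude inside the brain.
#' @param suppression_factor Fraction of the labeled signal surviving
#'   background suppression (the pipeline's upscale is its reciprocal).
#' @return List with 4-D `control` and `label` arrays, 3-D `m0`, `grid`.
#' @export
simulate_pcasl <- function(gt, condition = "ctrl", n_pairs = 20, snr = Inf,
                           seed = 1, consts = asl_constants(),
                           m0_value = 1000, suppression_factor = 0.8) {
  if (snr <= 0) stop("snr must be positive")
  set.seed(seed)
  sh <- gt$grid$shape
  brain <- gt$masks$brain
  cbf <- gt$conditions[[condition]]$cbf$values
  m0 <- array(0, sh)
  m0[brain] <- m0_value
  dm <- array(0, sh)
  dm[brain] <- suppression_factor * cbf[brain] * m0_value /
    asl_scale_factor(consts)
  control <- array(0, c(sh, n_pairs))
  label <- array(0, c(sh, n_pairs))
  nb <- sum(brain)
  noise_sd <- mean(dm[brain]) / snr
  for (k in seq_len(n_pairs)) {
    cc <- array(0, sh); ll <- array(0, sh)
    cc[brain] <- m0_value
    ll[brain] <- m0_value - dm[brain]
    if (is.finite(snr)) {
      cc[brain] <- cc[brain] + stats::rnorm(nb, 0, noise_sd)
      ll[brain] <- ll[brain] + stats::rnorm(nb, 0, noise_sd)
    }
    control[, , , k] <- cc
    label[, , , k] <- ll
  }
  list(control = control, label = label, m0 = m0, grid = gt$grid)
}

#' Simulate a DSC bolus-passage series
#'
#' The bolus is a gamma-variate relaxation-rate curve whose time integral is
#' proportional to the true CBV: `dR2*(v, t) = k CBV(v) g(t)` with `g`
#' peak-normalized, so relative CBV integrals recover the true ratios.
#' `S(t) = S0 exp(-TE dR2*(t))` plus Gaussian noise; the first
#' `n_prebolus` frames are bolus-free. No contrast-agent leakage is
#' modeled.
#'
#' @param gt A [generate_ground_truth()] result.
#' @param condition `"ctrl"` or `"task"`.
#' @param snr SNR of the baseline signal; `Inf` for noiseless.
#' @param seed Random seed.
#' @param acq An [acquisition_params()] (DSC TE and TR).
#' @param n_dynamics Total number of dynamics.
#' @param n_prebolus Pre-bolus frames.
#' @param s0 Baseline signal amplitude.
#' @param peak_dr2s Peak dR2* (s^-1) at the GM reference CBV of 4.8 %vol.
#' @return List with 4-D `data`, `grid`, timing.
#' @export
simulate_dsc <- function(gt, condition = "ctrl", snr = Inf, seed = 1,
                         acq = acquisition_params(), n_dynamics = 80,
                         n_prebolus = 5, s0 = 1000, peak_dr2s = 25) {
  if (snr <= 0) stop("snr must be positive")
  set.seed(seed)
  sh <- gt$grid$shape
  brain <- gt$masks$brain
  cbv <- gt$conditions[[condition]]$cbv$values
  t <- (seq_len(n_dynamics) - 1) * acq$tr_dsc
  t0 <- n_prebolus * acq$tr_dsc
  a <- 3; tp <- 8                       # gamma-variate shape: peak 8 s post-arrival
  tt <- pmax(t - t0, 0)
  gshape <- ifelse(tt > 0, (tt / tp)^a * exp(a * (1 - tt / tp)), 0)
  k <- peak_dr2s / 4.8
  te_s <- acq$te_dsc / 1000
  sig <- array(0, c(sh, n_dynamics))
  nb <- sum(brain)
  for (j in seq_len(n_dynamics)) {
    s <- array(0, sh)
    s[brain] <- s0 * exp(-te_s * k * cbv[brain] * gshape[j])
    if (is.finite(snr)) {
      s[brain] <- pmax(s[brain] + stats::rnorm(nb, 0, s0 / snr), 1)
    }
    sig[, , , j] <- s
  }
  list(data = sig, grid = gt$grid, tr_dsc = acq$tr_dsc, te_dsc = acq$te_dsc,
       n_prebolus = n_prebolus)
}

#' Simulate a block-design BOLD time series
#'
#' Each voxel's response amplitude is the Davis-forward BOLD change
#' computed from its true CBF and CMRO2 ratios at generation time. The
#' block boxcar is convolved with a double-gamma hemodynamic response
#' (normalized to unit plateau, reaching it within ~6 s), scaled by the
#' designed amplitude, and overlaid with a linear drift and Gaussian noise.
#'
#' @param gt A [generate_ground_truth()] result.
#' @param design A [block_design()]; its `task` blocks carry the response.
#' @param snr SNR of the baseline signal; `Inf` for noiseless.
#' @param seed Random seed.
#' @param s0 Baseline signal amplitude.
#' @param drift_pct Linear drift amplitude over the whole run, percent.
#' @return List with the 4-D `data` (last dim = time) and `grid`.
#' @export
simulate_bold <- function(gt, design, snr = Inf, seed = 1, s0 = 1000,
                          drift_pct = 0.1) {
  if (snr <= 0) stop("snr must be positive")
  set.seed(seed)
  sh <- gt$grid$shape
  brain <- gt$masks$brain
  resp <- convolved_regressor(design)
  # express the response in the analysis-window metric that defines the
  # designed amplitude: task-window median 1, baseline-window median 0
  ti <- design$labels == "task" & design$analyze
  bi <- design$labels == "baseline" & design$analyze
  mb <- stats::median(resp[bi])
  resp <- (resp - mb) / (stats::median(resp[ti]) - mb)
  nt <- length(resp)
  amp <- gt$designed$dbold_pct / 100
  drift <- drift_pct / 100 * seq(0, 1, length.out = nt)
  sig <- array(0, c(sh, nt))
  nb <- sum(brain)
  for (j in seq_len(nt)) {
    s <- array(0, sh)
    s[brain] <- s0 * (1 + amp[brain] * resp[j] + drift[j])
    if (is.finite(snr)) {
      s[brain] <- s[brain] + stats::rnorm(nb, 0, s0 / snr)
    }
    sig[, , , j] <- s
  }
  list(data = sig, grid = gt$grid, design = design)
}

#' Generate all raw signals for one phantom subject
#'
#' Convenience wrapper producing the ground truth plus every modality the
#' fitting pipeline consumes, with per-modality seeds derived from the
#' subject seed.
#'
#' @param spec A [phantom_spec()].
#' @param subject_index Subject number.
#' @param design Optional [block_design()] for BOLD; `NULL` skips BOLD.
#' @param conditions Conditions to simulate.
#' @param acq An [acquisition_params()].
#' @return List with `gt` and per-condition signal lists.
#' @export
generate_subject <- function(spec, subject_index = 1, design = NULL,
                             conditions = c("ctrl", "task"),
                             acq = acquisition_params()) {
  gt <- generate_ground_truth(spec, subject_index)
  sd0 <- spec$seed + subject_index * 101L
  out <- list(gt = gt)
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    s <- sd0 + ci * 17L
    sims <- list(
      se = simulate_multiecho(gt, "se", cond, spec$snr[["se"]], s + 1L, acq),
      gre = simulate_multiecho(gt, "gre", cond, spec$snr[["gre"]], s + 2L, acq),
      asl = simulate_pcasl(gt, cond, snr = spec$snr[["asl"]], seed = s + 3L))
    if (cond == "ctrl") {
      sims$dsc <- simulate_dsc(gt, cond, snr = spec$snr[["dsc"]],
                               seed = s + 4L, acq = acq)
    }
    out[[cond]] <- sims
  }
  if (!is.null(design)) {
    out$bold <- simulate_bold(gt, design, snr = spec$snr[["bold"]],
                              seed = sd0 + 99L)
  }
  out
}
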