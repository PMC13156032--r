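#' Fit all quantitative maps for one synthetic subject
#'
#' Runs the full map-estimation chain on the raw signals of one subject:
#' monoexponential T2 and T2* fits, R2', pCASL CBF quantification (with
#' the 25% background-suppression upscaling), DSC CBV quantification
#' (white-matter normalization to 2.5 %vol, baseline condition only),
#' then OEF, arterial oxygen content and CMRO2, plus the native
#' quality-control mask per condition.
#'
#' @param sub A [generate_subject()] result.
#' @param acq An [acquisition_params()].
#' @param asl An [asl_constants()].
#' @param dsc A [dsc_constants()].
#' @param thresholds A [qc_thresholds()].
#' @param gm_prob,wm_prob Tissue probabilities assigned to the phantom's
#'   GM and WM compartments when building the GM-probability map.
#' @return List with per-condition map lists, the GM-probability map, and
#'   per-condition QC masks.
#' @export
fit_subject <- function(sub, acq = acquisition_params(),
                        asl = asl_constants(), dsc = dsc_constants(),
                        thresholds = qc_thresholds(),
                        gm_prob = 0.95, wm_prob = 0.05) {
  gt <- sub$gt
  g <- gt$grid
  gmprob_vals <- array(0, g$shape)
  gmprob_vals[gt$masks$wm] <- wm_prob
  gmprob_vals[gt$masks$gm] <- gm_prob
  gmprob <- parameter_map(gmprob_vals, "gmprob", g,
                          validity = gt$masks$brain)
  phys <- gt$physiology
  c_const <- compute_c(phys)
  cao2 <- compute_cao2(phys)

  cbv <- NULL
  conds <- intersect(c("ctrl", "task"), names(sub))
  out <- list(gmprob = gmprob, physiology = phys, cao2 = cao2,
              c_const = c_const)
  for (cond in conds) {
    sig <- sub[[cond]]
    se_fit <- fit_monoexponential(sig$se$data, sig$se$te_list)
    gre_fit <- fit_monoexponential(sig$gre$data, sig$gre$te_list)
    t2 <- parameter_map(se_fit$tau, "t2", g, validity = se_fit$valid)
    t2star <- parameter_map(gre_fit$tau, "t2star", g,
                            validity = gre_fit$valid)
    r2p <- compute_r2prime(t2, t2star)
    cbf <- quantify_cbf(sig$asl[c("control", "label")], sig$asl$m0, g, asl)
    if (!is.null(sig$dsc)) {
      cbv <- quantify_cbv(sig$dsc$data, gt$masks$wm, g,
                          te_dsc = sig$dsc$te_dsc, tr_dsc = sig$dsc$tr_dsc,
                          consts = dsc)
    }
    if (is.null(cbv)) stop("no DSC acquisition available for CBV")
    oef <- compute_oef(r2p, cbv, c_const, oef_max = thresholds$oef_max)
    cmro2 <- compute_cmro2(oef, cbf, cao2)
    qc <- native_qc_mask(list(gmprob = gmprob, t2 = t2, r2prime = r2p,
                              cbv = cbv, oef = oef, cbf = cbf),
                         thresholds)
    out[[cond]] <- list(t2 = t2, t2star = t2star, r2prime = r2p,
                        cbv = cbv, cbf = cbf, oef = oef, cmro2 = cmro2,
                        qc_mask = qc)
  }
  out
}

#' Semiquantitative task-state maps from BOLD and baseline maps
#'
#' The BOLD-informed path to task-state metabolism: the task R2' is
#' derived from the baseline R2' and the BOLD percent signal change, fed
#' through the oxygenation equation (reusing the baseline CBV) and Fick's
#' principle with the task-state CBF.
#'
#' @param fit A [fit_subject()] result.
#' @param psc Task-vs-baseline `psc` [parameter_map()].
#' @param te_bold BOLD echo time, ms.
#' @return List of percent-change maps `dcmro2_pct`, `doef_pct`,
#'   `dcbf_pct` (arrays, NA outside valid voxels) and the task maps.
#' @export
bold_informed_deltas <- function(fit, psc, te_bold = 30) {
  base <- fit$ctrl
  r2p_task <- bold_informed_r2prime(base$r2prime, psc, te_bold)
  oef_task <- compute_oef(r2p_task, base$cbv, fit$c_const)
  cmro2_task <- compute_cmro2(oef_task, fit$task$cbf, fit$cao2)
  pct <- function(task, ctrl) {
    ok <- task$validity & ctrl$validity & ctrl$values != 0
    out <- array(NA_real_, dim(task$values))
    out[ok] <- 100 * (task$values[ok] / ctrl$values[ok] - 1)
    out
  }
  list(dcmro2_pct = pct(cmro2_task, base$cmro2),
       doef_pct = pct(oef_task, base$oef),
       dcbf_pct = pct(fit$task$cbf, base$cbf),
       r2prime_task = r2p_task, oef_task = oef_task,
       cmro2_task = cmro2_task)
}

#' Run the end-to-end phantom pipeline
#'
#' Generates a cohort of synthetic subjects, fits all quantitative maps,
#' computes BOLD percent signal change and group significance
#' (mean-centered PLS bootstrap ratios over the subject stack), derives
#' the BOLD-informed task-state metabolism, classifies voxels as
#' concordant or discordant, and writes a JSON run manifest recording
#' inputs, seeds, package version and voxel counts surviving each mask.
#'
#' @param config Named list. Recognized entries: `phantom` (arguments to
#'   [phantom_spec()]), `design` (arguments to [block_design()]), `seed`,
#'   `out_dir`, `write_nifti` (write per-subject maps as NIfTI), `nperm`,
#'   `nboot` (group PLS resampling), `bsr_threshold`.
#' @return The run manifest (list), invisibly written to
#'   `out_dir/manifest.json` when `out_dir` is set; plus the cohort
#'   results under `$results`.
#' @export
run_pipeline <- function(config = list()) {
  seed <- as.integer(config$seed %||% 1L)
  ph_args <- config$phantom %||% list()
  if (is.null(ph_args$seed)) ph_args$seed <- seed
  spec <- do.call(phantom_spec, ph_args)
  design <- do.call(block_design, config$design %||% list())
  nperm <- config$nperm %||% 500
  nboot <- config$nboot %||% 500
  bsr_thr <- config$bsr_threshold %||% 2
  out_dir <- config$out_dir
  write_nifti <- isTRUE(config$write_nifti)
  verbose <- !isFALSE(config$verbose)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  stages <- c("phantom", "relaxometry", "perfusion", "oximetry", "qc",
              "taskstats", "davis", "concordance")
  n <- spec$n_subjects
  g <- spec$grid
  fits <- vector("list", n)
  psc_maps <- vector("list", n)
  deltas <- vector("list", n)
  qc_counts <- data.frame(subject = integer(), condition = character(),
                          n_valid = integer())
  subj_rows <- list()
  labels <- NULL
  for (i in seq_len(n)) {
    sub <- generate_subject(spec, i, design = design)
    if (is.null(labels)) labels <- sub$gt$labels
    fit <- fit_subject(sub)
    psc <- percent_signal_change(sub$bold$data, design, grid = g)
    dl <- bold_informed_deltas(fit, psc)
    for (cond in c("ctrl", "task")) {
      qc_counts <- rbind(qc_counts,
                         data.frame(subject = i, condition = cond,
                                    n_valid = sum(fit[[cond]]$qc_mask)))
    }
    gm_qc <- fit$ctrl$qc_mask
    subj_rows[[i]] <- data.frame(
      subject = i,
      hct = fit$physiology$hct_large_vessel,
      r2prime = map_stats(fit$ctrl$r2prime, gm_qc)$mean,
      cbv = map_stats(fit$ctrl$cbv, gm_qc)$mean,
      oef = map_stats(fit$ctrl$oef, gm_qc)$mean,
      cbf = map_stats(fit$ctrl$cbf, gm_qc)$mean,
      cmro2 = map_stats(fit$ctrl$cmro2, gm_qc)$mean)
    fits[[i]] <- fit
    psc_maps[[i]] <- psc
    deltas[[i]] <- dl
    if (write_nifti && !is.null(out_dir)) {
      for (nm in c("r2prime", "cbv", "oef", "cbf", "cmro2")) {
        write_volume(fit$ctrl[[nm]],
                     file.path(out_dir, sprintf("sub-%02d_%s.nii.gz",
                                                i, nm)))
      }
    }
    log_stage("fit", i, qc_voxels = sum(gm_qc), verbose = verbose)
  }
  subjects <- do.call(rbind, subj_rows)

  # group significance: PLS over the subject x condition PSC stack on the
  # voxels valid in every subject
  common <- Reduce(`&`, lapply(seq_len(n), function(i) {
    psc_maps[[i]]$validity & fits[[i]]$ctrl$qc_mask
  }))
  vox <- which(common)
  stack <- array(0, c(n, 2, length(vox)))
  for (i in seq_len(n)) {
    stack[i, 1, ] <- psc_maps[[i]]$values[vox]
    stack[i, 2, ] <- 0          # baseline condition: zero change by definition
  }
  pls <- mean_centered_pls(stack, nperm = nperm, nboot = nboot, seed = seed)
  lv <- 1L
  bsr_vol <- array(NA_real_, g$shape)
  # orient the LV so positive BSR means task > baseline
  flip <- sign(pls$design_scores[1, lv] - pls$design_scores[2, lv])
  bsr_vol[vox] <- flip * pls$bsr[, lv]
  group_psc <- array(NA_real_, g$shape)
  group_psc[vox] <- apply(vapply(seq_len(n), function(i)
    psc_maps[[i]]$values[vox], numeric(length(vox))), 1, stats::median)
  psc_map <- parameter_map(group_psc, "psc", g, validity = common)
  cmap <- contrast_map(psc_map, bsr_vol, threshold = bsr_thr,
                       source = "PLS-BSR")

  med_delta <- function(field) {
    m <- vapply(seq_len(n), function(i) deltas[[i]][[field]][vox],
                numeric(length(vox)))
    out <- array(NA_real_, g$shape)
    out[vox] <- apply(m, 1, stats::median, na.rm = TRUE)
    out
  }
  dcmro2 <- med_delta("dcmro2_pct")
  dcbf <- med_delta("dcbf_pct")
  doef <- med_delta("doef_pct")
  classes <- classify_voxels(cmap, dcmro2)
  summary <- coupling_summary(classes, dcbf, dcmro2)

  results <- list(subjects = subjects, pls = pls, contrast = cmap,
                  classes = classes, coupling = summary,
                  deltas = list(dcmro2_pct = dcmro2, dcbf_pct = dcbf,
                                doef_pct = doef),
                  designed_labels = labels,
                  cohort_means = colMeans(subjects[, c("r2prime", "cbv",
                                                       "oef", "cbf",
                                                       "cmro2")]))
  manifest <- list(
    package = "mqbold",
    version = as.character(utils::packageVersion("mqbold")),
    seed = seed, n_subjects = n,
    grid = list(shape = g$shape, voxel_size = g$voxel_size),
    stages = stages,
    design = list(order = design$order, block_s = design$block_s,
                  tr = design$tr),
    pls = list(nperm = nperm, nboot = nboot, seed = seed),
    qc_voxel_counts = qc_counts,
    cohort_means = as.list(results$cohort_means),
    class_counts = as.list(summary$counts))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(manifest, list(results = results)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
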