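#' Block design of a task run
#'
#' Alternating condition blocks on a fixed TR grid. The analysis window of
#' each block excludes its first `discard_lead` seconds (hemodynamic lag)
#' and keeps the following `analysis_window` seconds; with 30-s blocks at
#' TR 1.2 s that is 5 discarded and 20 analyzed TRs per block.
#'
#' @param order Condition label per block, in presentation order.
#' @param block_s Block length, s; must be a multiple of `tr`.
#' @param tr Repetition time, s.
#' @param discard_lead Seconds discarded at each block start.
#' @param analysis_window Seconds analyzed per block after the discard.
#' @return Object of class `block_design` with per-TR `labels` and
#'   per-TR `analyze` flags.
#' @export
block_design <- function(order = rep(c("baseline", "task"), 8),
                         block_s = 30, tr = 1.2, discard_lead = 6,
                         analysis_window = 24) {
  ntr_block <- block_s / tr
  if (abs(ntr_block - round(ntr_block)) > 1e-9) {
    stop("block schedule not aligned to TR grid")
  }
  ntr_block <- round(ntr_block)
  stopifnot(discard_lead + analysis_window <= block_s)
  labels <- rep(order, each = ntr_block)
  block_id <- rep(seq_along(order), each = ntr_block)
  within_t <- rep((seq_len(ntr_block) - 1) * tr, length(order))
  analyze <- within_t >= discard_lead &
    within_t < discard_lead + analysis_window
  structure(list(labels = labels, block_id = block_id, analyze = analyze,
                 order = order, block_s = block_s, tr = tr,
                 discard_lead = discard_lead,
                 analysis_window = analysis_window,
                 n_tr = length(labels)),
            class = "block_design")
}

# Canonical double-gamma hemodynamic response sampled at the design TR,
# normalized to unit sum so a sustained block plateaus at 1.
hrf_double_gamma <- function(tr, duration = 32, a1 = 6, b1 = 1, a2 = 16,
                             b2 = 1, undershoot_ratio = 1 / 6) {
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = a1, rate = b1) -
    undershoot_ratio * stats::dgamma(t, shape = a2, rate = b2)
  h / sum(h)
}

#' Task regressor: block boxcar convolved with the double-gamma response
#'
#' @param design A [block_design()].
#' @param task Label of the active condition.
#' @return Numeric vector, one value per TR.
#' @export
convolved_regressor <- function(design, task = "task") {
  box <- as.numeric(design$labels == task)
  h <- hrf_double_gamma(design$tr)
  full <- stats::convolve(box, rev(h), type = "open")
  full[seq_along(box)]
}

#' Percent signal change between two conditions
#'
#' Per voxel, `PSC = 100 (median_task - median_baseline)/median_baseline`,
#' where the medians pool the analysis-window TRs (first 6 s of each block
#' excluded) across all repetitions of the respective condition.
#'
#' @param series 4-D time series (last dimension = time) or matrix
#'   (voxels x time).
#' @param design A [block_design()].
#' @param task,baseline Condition labels.
#' @param grid Optional [volume_grid()] when `series` is 4-D.
#' @return A `psc` [parameter_map()] (grid given) or numeric vector;
#'   voxels with non-positive baseline median are invalid/`NA`.
#' @export
percent_signal_change <- function(series, design, task = "task",
                                  baseline = "baseline", grid = NULL) {
  if (!all(c(task, baseline) %in% design$labels)) {
    stop("task or baseline label absent from design")
  }
  d <- dim(series)
  nt <- d[length(d)]
  stopifnot(nt == design$n_tr)
  m <- matrix(series, ncol = nt)
  ti <- design$labels == task & design$analyze
  bi <- design$labels == baseline & design$analyze
  med_t <- apply(m[, ti, drop = FALSE], 1, stats::median)
  med_b <- apply(m[, bi, drop = FALSE], 1, stats::median)
  ok <- is.finite(med_b) & med_b > 0
  psc <- rep(NA_real_, nrow(m))
  psc[ok] <- 100 * (med_t[ok] - med_b[ok]) / med_b[ok]
  if (length(d) == 4L) {
    if (is.null(grid)) grid <- volume_grid(d[1:3])
    parameter_map(array(psc, d[1:3]), "psc", grid,
                  validity = array(ok, d[1:3]))
  } else {
    psc
  }
}

#' Attach significance labels to a percent-signal-change map
#'
#' @param psc A `psc` [parameter_map()].
#' @param stat Statistic array or [parameter_map()] (BSR or z) on the same
#'   grid.
#' @param threshold Two-sided significance threshold on `stat`.
#' @param source Character tag (`"PLS-BSR"` or `"GLM-z"`).
#' @return Object of class `contrast_map`: the psc map plus a per-voxel
#'   significance label in `{positive, negative, none}`.
#' @export
contrast_map <- function(psc, stat, threshold = 2,
                         source = c("PLS-BSR", "GLM-z")) {
  source <- match.arg(source)
  sv <- if (inherits(stat, "parameter_map")) stat$values else as.array(stat)
  stopifnot(identical(dim(sv), as.integer(psc$grid$shape)))
  lab <- array("none", psc$grid$shape)
  sig <- psc$validity & is.finite(sv) & abs(sv) > threshold
  lab[sig & sv > 0] <- "positive"
  lab[sig & sv < 0] <- "negative"
  structure(list(psc = psc, significance = lab, stat = sv,
                 threshold = threshold, source = source,
                 grid = psc$grid),
            class = "contrast_map")
}

mean_center_conditions <- function(cond_means) {
  sweep(cond_means, 2, colMeans(cond_means))
}

#' Mean-centered task partial least squares
#'
#' Data-reduction group statistic relating voxel patterns to task
#' conditions. The condition-by-voxel matrix of condition means (averaged
#' over subjects) is column-centered by the grand mean and decomposed by
#' SVD into latent variables (LVs). LV significance comes from permutation
#' tests that shuffle condition labels within subject; voxel salience
#' reliability from bootstrap resampling of subjects with replacement,
#' summarized as bootstrap ratios (BSR = observed salience / bootstrap
#' standard error), with bootstrap saliences sign-aligned to the observed
#' LV before accumulation.
#'
#' @param data 3-D array `subjects x conditions x voxels` (e.g. stacked
#'   percent-signal-change or quantitative parameter values).
#' @param nperm Number of label permutations.
#' @param nboot Number of bootstrap resamples.
#' @param seed Random seed for both resampling loops (logged in the
#'   result).
#' @return Object of class `pls_result`: singular values (non-increasing),
#'   permutation p per LV, voxel saliences, BSR per voxel and LV, design
#'   scores per condition.
#' @export
mean_centered_pls <- function(data, nperm = 3000, nboot = 3000, seed = 1) {
  d <- dim(data)
  stopifnot(length(d) == 3L)
  ns <- d[1]; nc <- d[2]; nv <- d[3]
  if (nc < 2) stop("degenerate input: need at least 2 conditions")
  if (ns < 3) stop("need at least 3 subjects")
  set.seed(seed)

  cond_means <- function(x) {
    apply(x, c(2, 3), mean)
  }
  decomp <- function(x) {
    mc <- mean_center_conditions(cond_means(x))
    sv <- svd(mc)
    list(mc = mc, d = sv$d, u = sv$u, v = sv$v)
  }
  obs <- decomp(data)
  nl <- length(obs$d)

  # permutation: shuffle condition labels within each subject
  perm_ge <- rep(0L, nl)
  for (p in seq_len(nperm)) {
    xp <- data
    for (s in seq_len(ns)) {
      xp[s, , ] <- data[s, sample(nc), ]
    }
    dp <- svd(mean_center_conditions(cond_means(xp)), nu = 0, nv = 0)$d
    perm_ge <- perm_ge + as.integer(dp >= obs$d - 1e-12)
  }
  p_perm <- (1 + perm_ge) / (1 + nperm)

  # bootstrap: resample subjects with replacement; sign-align saliences
  boot_sum <- matrix(0, nv, nl)
  boot_sq <- matrix(0, nv, nl)
  for (b in seq_len(nboot)) {
    idx <- sample(ns, replace = TRUE)
    db <- decomp(data[idx, , , drop = FALSE])
    vb <- db$v[, seq_len(nl), drop = FALSE]
    for (l in seq_len(nl)) {
      cc <- sum(vb[, l] * obs$v[, l])
      if (cc < 0) vb[, l] <- -vb[, l]
    }
    boot_sum <- boot_sum + vb
    boot_sq <- boot_sq + vb^2
  }
  boot_se <- sqrt(pmax(boot_sq / nboot - (boot_sum / nboot)^2, 0)) *
    sqrt(nboot / max(nboot - 1, 1))
  bsr <- obs$v / boot_se
  bsr[!is.finite(bsr)] <- NA_real_

  structure(list(singular_values = obs$d, p_perm = p_perm,
                 saliences = obs$v, bsr = bsr, design_scores = obs$u,
                 cond_mean_centered = obs$mc,
                 nperm = nperm, nboot = nboot, seed = seed),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat("<pls_result>\n  singular values:",
      paste(format(x$singular_values, digits = 4), collapse = ", "),
      "\n  permutation p: ",
      paste(format(x$p_perm, digits = 3), collapse = ", "),
      sprintf("\n  (%d permutations, %d bootstraps, seed %d)\n",
              x$nperm, x$nboot, x$seed))
  invisible(x)
}

#' Voxelwise GLM z map for a block design
#'
#' Ordinary least squares of each voxel's time series on the lag-convolved
#' task boxcar, an intercept, a linear drift, and optional confound
#' regressors. The task-effect t statistic is Gaussianized into a z value;
#' `|z| > 2.5` is the conventional single-subject significance label.
#'
#' @param series 4-D time series or voxels-x-time matrix.
#' @param design A [block_design()].
#' @param confounds Optional numeric matrix (time x regressors).
#' @param grid Optional [volume_grid()] for 4-D input.
#' @return A `zstat` [parameter_map()] (or vector); zero-variance voxels
#'   are invalid.
#' @export
glm_zmap <- function(series, design, confounds = NULL, grid = NULL) {
  d <- dim(series)
  nt <- d[length(d)]
  stopifnot(nt == design$n_tr)
  m <- matrix(series, ncol = nt)
  x <- cbind(intercept = 1, task = convolved_regressor(design),
             drift = seq(0, 1, length.out = nt))
  if (!is.null(confounds)) x <- cbind(x, as.matrix(confounds))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) stop("rank-deficient design matrix")
  xtx_inv <- chol2inv(qr.R(qrx))
  betas <- t(qr.coef(qrx, t(m)))
  fitted <- betas %*% t(x)
  rss <- rowSums((m - fitted)^2)
  df <- nt - ncol(x)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tval <- betas[, 2] / se
  ts_var <- rowSums((m - rowMeans(m))^2)
  ok <- is.finite(tval) & se > 0 & ts_var > 0
  z <- rep(NA_real_, length(tval))
  pos <- ok & tval >= 0
  neg <- ok & tval < 0
  z[pos] <- stats::qnorm(stats::pt(tval[pos], df, lower.tail = FALSE),
                         lower.tail = FALSE)
  z[neg] <- stats::qnorm(stats::pt(tval[neg], df))
  if (length(d) == 4L) {
    if (is.null(grid)) grid <- volume_grid(d[1:3])
    parameter_map(array(z, d[1:3]), "zstat", grid,
                  validity = array(ok, d[1:3]))
  } else {
    z
  }
}

# 26-connectivity connected components of a logical 3-D array via igraph.
label_components_26 <- function(mask) {
  sh <- dim(mask)
  vox <- which(mask)
  lab <- array(0L, sh)
  if (!length(vox)) return(lab)
  id <- array(0L, sh)
  id[vox] <- seq_along(vox)
  coords <- arrayInd(vox, sh)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # keep one of each +/- pair to avoid duplicate edges
  keep <- offsets[, 3] > 0 |
    (offsets[, 3] == 0 & (offsets[, 2] > 0 |
                            (offsets[, 2] == 0 & offsets[, 1] > 0)))
  offsets <- offsets[keep, , drop = FALSE]
  edges <- NULL
  for (k in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2, offsets[k, ], `+`)
    inb <- nb[, 1] >= 1 & nb[, 1] <= sh[1] &
      nb[, 2] >= 1 & nb[, 2] <= sh[2] &
      nb[, 3] >= 1 & nb[, 3] <= sh[3]
    if (!any(inb)) next
    lin <- nb[inb, 1] + (nb[inb, 2] - 1L) * sh[1] +
      (nb[inb, 3] - 1L) * sh[1] * sh[2]
    tgt <- id[lin]
    src <- id[vox[inb]]
    hit <- tgt > 0L
    if (any(hit)) edges <- rbind(edges, cbind(src[hit], tgt[hit]))
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  lab[vox] <- igraph::components(g)$membership
  lab
}

#' Extract supra-threshold clusters from a statistic volume
#'
#' Thresholds the statistic at `+/- threshold`, labels 26-connected
#' components separately for the positive and negative tails, and drops
#' components smaller than `min_size` voxels.
#'
#' @param stat 3-D statistic array (BSR or z) or [parameter_map()].
#' @param threshold Positive threshold applied to both tails.
#' @param min_size Minimum cluster extent, voxels.
#' @return List with labeled arrays `positive` and `negative` (0 =
#'   background; clusters renumbered by decreasing size) and a size table.
#' @export
extract_clusters <- function(stat, threshold = 3, min_size = 30) {
  stopifnot(threshold > 0, min_size >= 1)
  sv <- if (inherits(stat, "parameter_map")) stat$values else as.array(stat)
  one_tail <- function(mask) {
    lab <- label_components_26(mask & !is.na(mask))
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_size)
    out <- array(0L, dim(lab))
    for (i in seq_along(keep[order(-sizes[keep])])) {
      cl <- keep[order(-sizes[keep])][i]
      out[lab == cl] <- i
    }
    out
  }
  pos <- one_tail(!is.na(sv) & sv > threshold)
  neg <- one_tail(!is.na(sv) & sv < -threshold)
  sizes <- list(positive = tabulate(pos), negative = tabulate(neg))
  list(positive = pos, negative = neg, sizes = sizes,
       threshold = threshold, min_size = min_size)
}
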