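#' Classify significant voxels as concordant or discordant
#'
#' Among voxels with a significant BOLD response, a voxel is *concordant*
#' when the BOLD change and the CMRO2 change share a sign, *discordant*
#' when their signs oppose, and *excluded* when the CMRO2 change is exactly
#' zero (its sign is undefined). Non-significant voxels carry `NA`. The
#' rule is exhaustive and mutually exclusive over significant voxels.
#'
#' @param dbold A [contrast_map()] carrying percent signal change and
#'   significance labels.
#' @param dcmro2 CMRO2 percent-change array or [parameter_map()] on the
#'   same grid.
#' @return Object of class `voxel_class_map`: character array with levels
#'   concordant/discordant/excluded (`NA` where not significant).
#' @export
classify_voxels <- function(dbold, dcmro2) {
  dm <- if (inherits(dcmro2, "parameter_map")) dcmro2$values
        else as.array(dcmro2)
  if (!identical(dim(dm), as.integer(dbold$grid$shape))) {
    stop("grid mismatch between contrast and CMRO2 change")
  }
  cls <- array(NA_character_, dbold$grid$shape)
  sig <- dbold$significance != "none" & is.finite(dm) &
    is.finite(dbold$psc$values)
  same <- sign(dbold$psc$values) == sign(dm)
  cls[sig & dm != 0 & same] <- "concordant"
  cls[sig & dm != 0 & !same] <- "discordant"
  cls[sig & dm == 0] <- "excluded"
  structure(list(class = cls, grid = dbold$grid),
            class = "voxel_class_map")
}

#' Cross-task conjunction classification
#'
#' On voxels significant in both tasks: `concordant-only` when concordant
#' in both, `discordant-only` when discordant in both, `mixed` when one of
#' each, `excluded` when either task excluded the voxel.
#'
#' @param class_task1,class_task2 [classify_voxels()] results.
#' @param conjunction_mask Logical array restricting the comparison
#'   (defaults to voxels classified in both tasks).
#' @return A `voxel_class_map` with conjunction levels.
#' @export
classify_conjunction <- function(class_task1, class_task2,
                                 conjunction_mask = NULL) {
  stopifnot(identical(class_task1$grid$shape, class_task2$grid$shape))
  c1 <- class_task1$class
  c2 <- class_task2$class
  if (is.null(conjunction_mask)) conjunction_mask <- !is.na(c1) & !is.na(c2)
  if (!any(conjunction_mask)) stop("empty conjunction mask")
  out <- array(NA_character_, dim(c1))
  on <- conjunction_mask & !is.na(c1) & !is.na(c2)
  out[on & (c1 == "excluded" | c2 == "excluded")] <- "excluded"
  both_c <- on & c1 == "concordant" & c2 == "concordant"
  both_d <- on & c1 == "discordant" & c2 == "discordant"
  mixed <- on & ((c1 == "concordant" & c2 == "discordant") |
                   (c1 == "discordant" & c2 == "concordant"))
  out[both_c] <- "concordant-only"
  out[both_d] <- "discordant-only"
  out[mixed] <- "mixed"
  structure(list(class = out, grid = class_task1$grid),
            class = "voxel_class_map")
}

#' Flow-metabolism coupling ratio
#'
#' `n = dCBF(%) / dCMRO2(%)`; values above 1 define the canonical
#' hemodynamic response. Undefined (NA) for zero metabolic change.
#'
#' @param dcbf_pct CBF change, percent.
#' @param dcmro2_pct CMRO2 change, percent.
#' @param digits Rounding used in printed summaries; `NULL` for full
#'   precision.
#' @return The ratio (vectorized), `NA` where the denominator is 0.
#' @export
n_ratio <- function(dcbf_pct, dcmro2_pct, digits = NULL) {
  out <- ifelse(dcmro2_pct == 0, NA_real_, dcbf_pct / dcmro2_pct)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Class counts across BOLD amplitude quartiles
#'
#' Within each response sign, quartile boundaries of |dBOLD| are computed
#' over the classified voxels, and concordant/discordant counts are
#' tabulated per quartile.
#'
#' @param dbold A [contrast_map()].
#' @param classes A [classify_voxels()] result.
#' @return Data frame with columns sign, quartile, concordant, discordant.
#' @export
quartile_distribution <- function(dbold, classes) {
  cls <- classes$class
  psc <- dbold$psc$values
  rows <- list()
  for (sgn in c("positive", "negative")) {
    sel <- which(dbold$significance == sgn & cls %in%
                   c("concordant", "discordant"))
    if (length(sel) < 4) stop("fewer than 4 classified voxels with ",
                              sgn, " response")
    amp <- abs(psc[sel])
    q <- stats::quantile(amp, c(0.25, 0.5, 0.75), names = FALSE)
    bin <- findInterval(amp, q, left.open = TRUE) + 1L
    for (k in 1:4) {
      rows[[length(rows) + 1L]] <- data.frame(
        sign = sgn, quartile = k,
        concordant = sum(bin == k & cls[sel] == "concordant"),
        discordant = sum(bin == k & cls[sel] == "discordant"))
    }
  }
  do.call(rbind, rows)
}

# Overlapping variance decomposition of an OLS fit: product measure
# (standardized beta x zero-order correlation, normalized by R^2) plus
# squared semi-partial correlations.
variance_shares <- function(y, X, strict = TRUE) {
  keep <- stats::complete.cases(cbind(y, X))
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  degenerate <- apply(X, 2, stats::sd) == 0
  if (any(degenerate)) {
    if (strict || all(degenerate)) stop("zero-variance predictor")
    # constant predictors explain nothing: share 0, refit without them
    sub <- variance_shares(y, X[, !degenerate, drop = FALSE], strict = FALSE)
    pad <- function(v) {
      out <- stats::setNames(rep(0, ncol(X)), colnames(X))
      out[names(v)] <- v
      out
    }
    sub$std_beta <- pad(sub$std_beta)
    sub$product_share <- pad(sub$product_share)
    sub$semipartial2 <- pad(sub$semipartial2)
    sub$zero_order_r <- pad(sub$zero_order_r)
    return(sub)
  }
  Xc <- scale(X, scale = FALSE)
  fit <- stats::lm(y ~ Xc)
  b <- stats::coef(fit)[-1]
  sdy <- stats::sd(y)
  std_beta <- b * apply(X, 2, stats::sd) / sdy
  r0 <- as.numeric(stats::cor(X, y))
  r2 <- summary(fit)$r.squared
  product_share <- std_beta * r0 / r2
  # squared semi-partial: R^2 drop when the predictor is removed
  sp2 <- if (ncol(X) == 1L) r2 else vapply(seq_len(ncol(X)), function(j) {
    r2 - summary(stats::lm(y ~ Xc[, -j, drop = FALSE]))$r.squared
  }, 0)
  names(product_share) <- names(sp2) <- names(r0) <- colnames(X)
  list(fit = fit, r2 = r2, coef = b, std_beta = std_beta,
       zero_order_r = r0, product_share = product_share,
       semipartial2 = sp2, n = length(y))
}

#' Baseline CMRO2 regression with variance partitioning
#'
#' OLS of baseline CMRO2 on mean-centered OEF, CBF and CBV over a voxel
#' set, reporting two overlapping variance decompositions per predictor:
#' the product measure (standardized beta times zero-order correlation,
#' normalized by R^2) and the squared semi-partial correlation.
#'
#' @param cmro2,oef,cbf,cbv [parameter_map()]s on one grid.
#' @param voxel_set Logical array selecting voxels (intersected with all
#'   validities).
#' @return List with the lm fit, R^2 and both share vectors.
#' @export
baseline_regression <- function(cmro2, oef, cbf, cbv, voxel_set = NULL) {
  keep <- cmro2$validity & oef$validity & cbf$validity & cbv$validity
  if (!is.null(voxel_set)) keep <- keep & voxel_set
  if (sum(keep) < 10) stop("fewer than 10 voxels in the regression set")
  variance_shares(cmro2$values[keep],
                  cbind(oef = oef$values[keep], cbf = cbf$values[keep],
                        cbv = cbv$values[keep]))
}

#' Per-class regression of metabolic on hemodynamic changes
#'
#' For each voxel class, OLS of dCMRO2(%) on mean-centered dOEF(%) and
#' dCBF(%) with the same variance decompositions as
#' [baseline_regression()]. In canonically coupled voxels the flow term
#' dominates; in discordant voxels the extraction term does.
#'
#' @param dcmro2,doef,dcbf Percent-change arrays or [parameter_map()]s.
#' @param classes A [classify_voxels()] result.
#' @param which_classes Classes to fit.
#' @return Named list of share results, one per class.
#' @export
delta_regression <- function(dcmro2, doef, dcbf, classes,
                             which_classes = c("concordant", "discordant")) {
  val <- function(x) if (inherits(x, "parameter_map")) x$values else
    as.array(x)
  y <- val(dcmro2); x1 <- val(doef); x2 <- val(dcbf)
  out <- list()
  for (cl in which_classes) {
    sel <- !is.na(classes$class) & classes$class == cl
    if (sum(sel) < 10) stop("class ", cl, " has fewer than 10 voxels")
    out[[cl]] <- variance_shares(y[sel],
                                 cbind(doef = x1[sel], dcbf = x2[sel]),
                                 strict = FALSE)
  }
  out
}

#' Summarize coupling per classified contrast
#'
#' @param classes A [classify_voxels()] result.
#' @param dcbf_pct,dcmro2_pct Percent-change arrays.
#' @return List with class counts, discordant fraction, median changes per
#'   class and the n-ratio of the class medians (one decimal).
#' @export
coupling_summary <- function(classes, dcbf_pct, dcmro2_pct) {
  cls <- classes$class
  counts <- table(factor(cls, levels = c("concordant", "discordant",
                                         "excluded")))
  medians <- lapply(c(concordant = "concordant", discordant = "discordant"),
                    function(cl) {
                      sel <- !is.na(cls) & cls == cl
                      c(dcbf = stats::median(dcbf_pct[sel]),
                        dcmro2 = stats::median(dcmro2_pct[sel]))
                    })
  nr <- vapply(medians, function(m) n_ratio(m[["dcbf"]], m[["dcmro2"]],
                                            digits = 1), 0)
  list(counts = counts,
       discordant_fraction = unname(counts["discordant"] /
                                      sum(counts[c("concordant",
                                                   "discordant")])),
       class_medians = medians, n_ratio = nr)
}
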