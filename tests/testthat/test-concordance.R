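test_that("voxel classification follows the sign rule and is exhaustive", {
  sh <- c(4, 1, 1)
  psc <- array(c(0.37, -0.29, 0.2, 0.5), sh)
  stat <- array(c(5, -4, 3, 0.5), sh)            # voxel 4 not significant
  cm <- make_contrast(psc, stat, threshold = 2.5)
  dcm <- array(c(3.1, 1.68, 0, 2), sh)
  cls <- classify_voxels(cm, dcm)
  expect_equal(cls$class[1, 1, 1], "concordant")  # +0.37% vs +3.1%
  expect_equal(cls$class[2, 1, 1], "discordant")  # -0.29% vs +1.68%
  expect_equal(cls$class[3, 1, 1], "excluded")    # dCMRO2 exactly 0
  expect_true(is.na(cls$class[4, 1, 1]))

  # exhaustive and mutually exclusive over random inputs
  set.seed(13)
  sh2 <- c(10, 10, 2)
  cm2 <- make_contrast(array(rnorm(200), sh2), array(rnorm(200, sd = 3), sh2))
  dcm2 <- array(sample(c(-2, 0, 1.5), 200, replace = TRUE), sh2)
  cls2 <- classify_voxels(cm2, dcm2)
  sig <- cm2$significance != "none"
  expect_true(all(!is.na(cls2$class[sig])))
  expect_true(all(is.na(cls2$class[!sig])))
  expect_true(all(cls2$class[sig] %in%
                    c("concordant", "discordant", "excluded")))
})

test_that("conjunction classification merges two task classifications", {
  sh <- c(5, 1, 1)
  g <- volume_grid(sh)
  mk_cls <- function(v) structure(list(class = array(v, sh), grid = g),
                                  class = "voxel_class_map")
  c1 <- mk_cls(c("concordant", "concordant", "discordant", "excluded", NA))
  c2 <- mk_cls(c("concordant", "discordant", "discordant", "concordant",
                 "concordant"))
  conj <- classify_conjunction(c1, c2)
  expect_equal(conj$class[1, 1, 1], "concordant-only")
  expect_equal(conj$class[2, 1, 1], "mixed")
  expect_equal(conj$class[3, 1, 1], "discordant-only")
  expect_equal(conj$class[4, 1, 1], "excluded")
  expect_true(is.na(conj$class[5, 1, 1]))       # unclassified in task 1
  expect_error(classify_conjunction(c1, c2,
                                    conjunction_mask = array(FALSE, sh)),
               "empty")
})

test_that("n-ratio reproduces the printed worked examples", {
  expect_equal(n_ratio(6.5, 3.1, digits = 1), 2.1)
  expect_equal(n_ratio(5.94, 3.54, digits = 1), 1.7)
  expect_true(is.na(n_ratio(1.5, 0)))
})

test_that("quartile distribution conserves counts and is flat under a null", {
  set.seed(29)
  sh <- c(20, 20, 10)
  n <- prod(sh)
  psc <- array(rnorm(n), sh)
  stat <- array(rnorm(n, sd = 4), sh)
  cm <- make_contrast(psc, stat, threshold = 2)
  dcm <- array(sample(c(-1, 1), n, replace = TRUE) * abs(rnorm(n)), sh)
  cls <- classify_voxels(cm, dcm)
  qd <- quartile_distribution(cm, cls)
  # conservation: table totals equal classified voxels per sign
  for (sgn in c("positive", "negative")) {
    sel <- cm$significance == sgn & cls$class %in%
      c("concordant", "discordant")
    expect_equal(sum(qd[qd$sign == sgn, c("concordant", "discordant")]),
                 sum(sel))
  }
  # class membership independent of amplitude: flat across quartiles
  tab <- as.matrix(qd[qd$sign == "positive", c("concordant", "discordant")])
  expect_gt(suppressWarnings(stats::chisq.test(tab))$p.value, 0.01)

  # degenerate case: a single class leaves the other column empty
  all_c <- cls
  all_c$class[!is.na(all_c$class)] <- "concordant"
  qd2 <- quartile_distribution(cm, all_c)
  expect_true(all(qd2$discordant == 0))
  expect_error(quartile_distribution(make_contrast(psc, array(0, sh)), cls),
               "fewer than 4")
})

test_that("variance shares reduce to r^2/R^2 for orthogonal predictors", {
  reps <- 25
  base <- as.matrix(expand.grid(oef = c(-1, 1), cbf = c(-1, 1),
                                cbv = c(-1, 1)))
  X <- base[rep(seq_len(8), reps), ]
  set.seed(41)
  y <- 3 * X[, 1] + 2 * X[, 2] + 0.5 * X[, 3] + rnorm(8 * reps, 0, 0.5)
  sh <- c(8 * reps, 1, 1)
  g <- volume_grid(sh)
  mk <- function(v, k) parameter_map(array(v, sh), k, g)
  res <- baseline_regression(mk(y, "cmro2"), mk(X[, 1], "oef"),
                             mk(X[, 2], "cbf"), mk(X[, 3], "cbv"))
  closed <- res$zero_order_r^2 / res$r2
  expect_equal(unname(res$product_share), unname(closed), tolerance = 1e-10)
  expect_equal(sum(res$product_share), 1, tolerance = 1e-10)
})

test_that("a CMRO2 field driven purely by OEF attributes all variance to OEF", {
  set.seed(43)
  n <- 2000
  sh <- c(n, 1, 1)
  g <- volume_grid(sh)
  oef <- rnorm(n, 0.39, 0.04)
  y <- 100 + 300 * oef
  mk <- function(v, k) parameter_map(array(v, sh), k, g)
  res <- baseline_regression(mk(y, "cmro2"), mk(oef, "oef"),
                             mk(rnorm(n, 44, 4), "cbf"),
                             mk(rnorm(n, 4.8, 0.3), "cbv"))
  expect_equal(unname(res$product_share["oef"]), 1, tolerance = 0.01)
  expect_lt(max(abs(res$product_share[c("cbf", "cbv")])), 0.01)
  # zero-variance predictor is an error in the baseline model
  expect_error(baseline_regression(mk(y, "cmro2"), mk(oef, "oef"),
                                   mk(rep(1, n), "cbf"),
                                   mk(rnorm(n, 4.8, 0.3), "cbv")),
               "zero-variance")
})

test_that("phantom baseline regression ranks OEF above CBF above CBV", {
  spec <- phantom_spec(n_subjects = 1, seed = 19)
  gt <- generate_ground_truth(spec, 1)
  m <- gt$conditions$ctrl
  res <- baseline_regression(m$cmro2, m$oef, m$cbf, m$cbv,
                             voxel_set = gt$masks$gm)
  sh <- res$product_share
  expect_gt(sh["oef"], sh["cbf"])
  expect_gt(sh["cbf"], sh["cbv"])
  expect_gt(res$r2, 0.9)
})

test_that("delta regressions separate flow-driven from extraction-driven classes", {
  # designed coupling with amplitude spread and light measurement noise
  set.seed(47)
  n <- 400
  sh <- c(2 * n, 1, 1)
  g <- volume_grid(sh)
  amp_c <- runif(n, 0.75, 1.25)
  amp_d <- runif(n, 0.75, 1.25)
  dcm <- c(3.1 * amp_c, 1.68 * amp_d) + rnorm(2 * n, 0, 0.05)
  dcb <- c(6.51 * amp_c, -0.47 * amp_d) + rnorm(2 * n, 0, 0.05)
  doe <- 100 * ((1 + dcm / 100) / (1 + dcb / 100) - 1)
  cls <- structure(list(class = array(rep(c("concordant", "discordant"),
                                          each = n), sh), grid = g),
                   class = "voxel_class_map")
  res <- delta_regression(array(dcm, sh), array(doe, sh), array(dcb, sh),
                          cls)
  expect_gt(res$concordant$product_share["dcbf"],
            res$concordant$product_share["doef"])
  expect_gt(res$discordant$product_share["doef"],
            res$discordant$product_share["dcbf"])

  # dOEF constant in a class: its share is zero, not an error
  doe0 <- doe; doe0[seq_len(n)] <- 0
  dcm0 <- dcm; dcm0[seq_len(n)] <- dcb[seq_len(n)]
  res0 <- delta_regression(array(dcm0, sh), array(doe0, sh),
                           array(dcb, sh), cls)
  expect_equal(unname(res0$concordant$product_share["doef"]), 0)
  small <- structure(list(class = array(c(rep("concordant", 5),
                                          rep(NA, 2 * n - 5)), sh),
                          grid = g), class = "voxel_class_map")
  expect_error(delta_regression(array(dcm, sh), array(doe, sh),
                                array(dcb, sh), small), "fewer than 10")
})

test_that("coupling summary reports class medians and their n-ratio", {
  sh <- c(6, 1, 1)
  g <- volume_grid(sh)
  cls <- structure(list(class = array(c(rep("concordant", 3),
                                        rep("discordant", 3)), sh),
                        grid = g), class = "voxel_class_map")
  dcb <- array(c(6.4, 6.5, 6.6, -0.4, -0.47, -0.5), sh)
  dcm <- array(c(3.0, 3.1, 3.2, 1.6, 1.68, 1.7), sh)
  cs <- coupling_summary(cls, dcb, dcm)
  expect_equal(unname(cs$n_ratio["concordant"]), 2.1)
  expect_equal(unname(cs$discordant_fraction), 0.5)
  expect_equal(unname(cs$counts["concordant"]), 3L, ignore_attr = TRUE)
})
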