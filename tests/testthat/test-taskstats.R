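test_that("block design discards 5 and analyzes 20 TRs per 30-s block", {
  d <- block_design(order = c("baseline", "task"), block_s = 30, tr = 1.2)
  expect_equal(d$n_tr, 50)
  expect_equal(sum(d$labels == "task"), 25)
  expect_equal(sum(d$analyze & d$labels == "task"), 20)
  expect_equal(sum(!d$analyze & d$labels == "task"), 5)
  expect_error(block_design(block_s = 30, tr = 0.9), "aligned")
  expect_error(block_design(discard_lead = 10, analysis_window = 24))
})

test_that("percent signal change recovers a planted plateau exactly", {
  d <- block_design(order = rep(c("baseline", "task"), 2))
  series <- matrix(1000, nrow = 3, ncol = d$n_tr)
  plateau <- d$labels == "task" & d$analyze
  series[2, plateau] <- 1004
  psc <- percent_signal_change(series, d)
  expect_equal(psc[1], 0)
  expect_equal(psc[2], 0.4, tolerance = 1e-12)
  series[3, ] <- 0                              # non-positive baseline
  expect_true(is.na(percent_signal_change(series, d)[3]))
  expect_error(percent_signal_change(series, d, task = "absent"), "label")
})

test_that("PLS singular values vanish for identical condition means and conserve inertia", {
  set.seed(3)
  ns <- 6; nv <- 12
  noise <- array(rnorm(ns * 2 * nv), c(ns, 2, nv))
  same <- noise
  same[, 2, ] <- same[, 1, ]                    # identical conditions
  res <- mean_centered_pls(same, nperm = 20, nboot = 20, seed = 1)
  expect_lt(max(res$singular_values), 1e-12)

  res2 <- mean_centered_pls(noise, nperm = 20, nboot = 20, seed = 1)
  expect_true(all(diff(res2$singular_values) <= 1e-12))
  expect_equal(sum(res2$singular_values^2), sum(res2$cond_mean_centered^2),
               tolerance = 1e-9)                # inertia conservation
  expect_error(mean_centered_pls(noise[, 1, , drop = FALSE], 10, 10, 1),
               "degenerate")
})

test_that("PLS flags a planted effect and agrees with a brute-force bootstrap oracle", {
  set.seed(11)
  ns <- 8; nv <- 20
  data <- array(rnorm(ns * 2 * nv, sd = 0.3), c(ns, 2, nv))
  data[, 2, 1:2] <- data[, 2, 1:2] + 1          # planted 2-voxel effect
  res <- mean_centered_pls(data, nperm = 200, nboot = 2000, seed = 5)
  # with 2 conditions the identity and global-flip label permutations tie
  # with the observed value, so the attainable p floor is ~2/2^8, not 1/nperm
  expect_lte(res$p_perm[1], 0.02)
  top2 <- order(-abs(res$bsr[, 1]))[1:2]
  expect_setequal(top2, 1:2)

  # independent oracle: direct bootstrap loop over the same estimator
  cond_mc <- function(x) {
    m <- apply(x, c(2, 3), mean)
    sweep(m, 2, colMeans(m))
  }
  sv_obs <- svd(cond_mc(data))
  set.seed(99)
  nb <- 2000
  boot <- matrix(0, nb, nv)
  for (b in seq_len(nb)) {
    vb <- svd(cond_mc(data[sample(ns, replace = TRUE), , ,
                           drop = FALSE]))$v[, 1]
    if (sum(vb * sv_obs$v[, 1]) < 0) vb <- -vb
    boot[b, ] <- vb
  }
  bsr_oracle <- sv_obs$v[, 1] / apply(boot, 2, sd)
  expect_gt(cor(bsr_oracle, res$bsr[, 1]), 0.95)
  expect_lt(max(abs(res$bsr[1:2, 1] / bsr_oracle[1:2] - 1)), 0.15)
})

test_that("permutation p of the first LV is uniform under the null", {
  set.seed(17)
  ps <- replicate(100, {
    x <- array(rnorm(6 * 2 * 8), c(6, 2, 8))
    mean_centered_pls(x, nperm = 99, nboot = 5,
                      seed = sample.int(1e6, 1))$p_perm[1]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("GLM z maps detect planted effects and hold the null rate", {
  set.seed(31)
  d <- block_design(order = rep(c("baseline", "task"), 4))
  resp <- convolved_regressor(d)
  nt <- d$n_tr
  n_eff <- 50; n_null <- 20000
  eff <- matrix(1000 * (1 + 0.01 * rep(resp, each = n_eff)), n_eff, nt) +
    rnorm(n_eff * nt, 0, 10)
  z_eff <- glm_zmap(eff, d)
  expect_true(all(abs(z_eff) > 2.5))            # 1% PSC at snr 100

  nul <- matrix(1000 + rnorm(n_null * nt, 0, 10), n_null, nt)
  z_null <- glm_zmap(nul, d)
  rate <- mean(abs(z_null) > 2.5)
  p0 <- 2 * pnorm(-2.5)                         # 1.24% two-sided
  expect_lt(abs(rate - p0), 4 * sqrt(p0 * (1 - p0) / n_null))

  flat <- matrix(7, 2, nt)
  expect_true(all(is.na(glm_zmap(flat, d))))
  expect_error(glm_zmap(nul[1:2, ], d, confounds = cbind(resp)), "rank")
})

test_that("cluster extraction respects extent and 26-connectivity", {
  sh <- c(12, 12, 6)
  bsr <- array(0, sh)
  bsr[2:6, 2:5, 2:3] <- 5                       # single 40-voxel blob
  cl <- extract_clusters(bsr, threshold = 3, min_size = 30)
  expect_equal(max(cl$positive), 1)
  expect_equal(sum(cl$positive == 1), 40)
  expect_equal(max(extract_clusters(bsr, 3, 1000)$positive), 0)

  # two cubes touching only at a corner join under 26-connectivity
  corner <- array(0, sh)
  corner[1:2, 1:2, 1:2] <- 5
  corner[3:4, 3:4, 3:4] <- 5
  cc <- extract_clusters(corner, threshold = 3, min_size = 1)
  expect_equal(max(cc$positive), 1)
  expect_equal(sum(cc$positive == 1), 16)

  # negative tail labeled separately
  neg <- array(0, sh); neg[8:10, 8:10, 4:5] <- -4
  cn <- extract_clusters(neg, threshold = 3, min_size = 10)
  expect_equal(max(cn$negative), 1)
  expect_equal(max(cn$positive), 0)
})
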