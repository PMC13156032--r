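test_that("canonical and discordant effects produce the designed coupling", {
  spec <- small_spec(n_subjects = 2, seed = 5, amp_jitter = 0)
  gt <- generate_ground_truth(spec, 1)
  can <- gt$labels == "canonical"
  dis <- gt$labels == "discordant"
  none <- gt$masks$gm & gt$labels == "none"
  expect_true(any(can) && any(dis) && any(none))

  # canonical: dCBF = n-ratio x dCMRO2 = 2.1 x 3.1 = 6.51%
  expect_equal(unique(gt$designed$dcbf_pct[can]), 6.51, tolerance = 1e-12)
  expect_equal(unique(gt$designed$dcmro2_pct[can]), 3.1, tolerance = 1e-12)
  # discordant: dOEF solves Fick: 1.0168/0.9953 - 1 = 2.160153%
  expect_equal(unique(gt$designed$doef_pct[dis]),
               100 * (1.0168 / 0.9953 - 1), tolerance = 1e-9)
  # zero-effect voxels: all deltas zero
  expect_true(all(gt$designed$dcbf_pct[none] == 0))
  expect_true(all(gt$designed$dcmro2_pct[none] == 0))
})

test_that("Fick and oxygenation identities hold exactly on ground truth", {
  spec <- small_spec(n_subjects = 1, seed = 2)
  gt <- generate_ground_truth(spec, 1)
  brain <- gt$masks$brain
  for (cond in c("ctrl", "task")) {
    m <- gt$conditions[[cond]]
    fick_err <- abs(m$cmro2$values[brain] -
                      m$oef$values[brain] * m$cbf$values[brain] * gt$cao2)
    expect_lt(max(fick_err), 1e-12)
    oxy_err <- abs(m$r2prime$values[brain] -
                     gt$c_const * (m$cbv$values[brain] / 100) *
                       m$oef$values[brain])
    expect_lt(max(oxy_err), 1e-12)
    # T2* never exceeds T2, so R2' is non-negative
    expect_true(all(m$t2star$values[brain] <= m$t2$values[brain] + 1e-12))
    expect_true(all(m$r2prime$values[brain] >= 0))
  }
})

test_that("generation is bit-reproducible under a fixed seed", {
  spec <- small_spec(n_subjects = 2, seed = 9)
  a <- generate_ground_truth(spec, 2)
  b <- generate_ground_truth(spec, 2)
  expect_identical(a$conditions$ctrl$cbf$values, b$conditions$ctrl$cbf$values)
  expect_identical(a$labels, b$labels)
  s1 <- simulate_multiecho(a, "se", snr = 50, seed = 4)
  s2 <- simulate_multiecho(b, "se", snr = 50, seed = 4)
  expect_identical(s1$data, s2$data)
})

test_that("designed BOLD signs match the designed labels exhaustively", {
  spec <- small_spec(n_subjects = 1, seed = 3)
  gt <- generate_ground_truth(spec, 1)
  can <- gt$labels == "canonical"
  dis <- gt$labels == "discordant"
  expect_true(all(sign(gt$designed$dbold_pct[can]) ==
                    sign(gt$designed$dcmro2_pct[can])))
  expect_true(all(sign(gt$designed$dbold_pct[dis]) !=
                    sign(gt$designed$dcmro2_pct[dis])))
})

test_that("effect layout and amplitudes are shared across subjects", {
  spec <- small_spec(n_subjects = 3, seed = 12)
  g1 <- generate_ground_truth(spec, 1)
  g3 <- generate_ground_truth(spec, 3)
  expect_identical(g1$labels, g3$labels)
  expect_identical(g1$designed$dcbf_pct, g3$designed$dcbf_pct)
  # but subject-level fields differ
  expect_false(identical(g1$conditions$ctrl$cbf$values,
                         g3$conditions$ctrl$cbf$values))
})

test_that("noiseless multi-echo signal follows the exponential decay", {
  gt <- uniform_gt(t2 = 80)
  sim <- simulate_multiecho(gt, "se", snr = Inf, seed = 1)
  # S(16 ms) = 1000 exp(-16/80) = 818.7308
  expect_equal(sim$data[1, 1, 1, 1], 1000 * exp(-16 / 80),
               tolerance = 1e-9)
  expect_equal(sim$data[1, 1, 1, 1], 818.7308, tolerance = 1e-4)
  # monotone decreasing in TE everywhere
  vox <- matrix(sim$data, ncol = length(sim$te_list))
  expect_true(all(apply(vox, 1, function(s) all(diff(s) < 0))))
  # very high snr converges to the noiseless curve
  hi <- simulate_multiecho(gt, "se", snr = 1e9, seed = 1)
  expect_equal(hi$data, sim$data, tolerance = 1e-5)
  expect_error(simulate_multiecho(gt, "se", snr = -1), "snr")
})

test_that("noiseless pCASL round trip restores true CBF through the x1.25 upscale", {
  gt <- uniform_gt(cbf = 44.5)
  sim <- simulate_pcasl(gt, snr = Inf, seed = 1)
  cbf <- quantify_cbf(sim[c("control", "label")], sim$m0, gt$grid)
  expect_equal(cbf$values[gt$masks$brain], rep(44.5, sum(gt$masks$brain)),
               tolerance = 1e-9)
  # zero flow yields a zero difference signal
  gt0 <- uniform_gt(cbf = 1e-12)
  sim0 <- simulate_pcasl(gt0, snr = Inf, seed = 1)
  expect_equal(max(abs(sim0$control - sim0$label)), 0, tolerance = 1e-6)
  # linearity: doubling CBF doubles the difference signal
  gt2 <- uniform_gt(cbf = 89)
  sim2 <- simulate_pcasl(gt2, snr = Inf, seed = 1)
  dm1 <- mean(sim$control - sim$label)
  dm2 <- mean(sim2$control - sim2$label)
  expect_equal(dm2 / dm1, 2, tolerance = 1e-9)
})

test_that("DSC bolus integral scales with CBV and recovers tissue contrast", {
  spec <- small_spec(n_subjects = 1, seed = 4)
  gt <- generate_ground_truth(spec, 1)
  sim <- simulate_dsc(gt, snr = Inf, seed = 1)
  cbv <- quantify_cbv(sim$data, gt$masks$wm, gt$grid,
                      te_dsc = sim$te_dsc, tr_dsc = sim$tr_dsc)
  brain <- gt$masks$brain
  tru <- gt$conditions$ctrl$cbv$values
  expect_lt(max(abs(cbv$values[brain] / tru[brain] - 1)), 1e-6)

  # noisy GM/WM contrast within 5% of truth at snr 100
  simn <- simulate_dsc(gt, snr = 100, seed = 2)
  cbvn <- quantify_cbv(simn$data, gt$masks$wm, gt$grid,
                       te_dsc = simn$te_dsc, tr_dsc = simn$tr_dsc)
  est_ratio <- mean(cbvn$values[gt$masks$gm & cbvn$validity]) /
    median(cbvn$values[gt$masks$wm & cbvn$validity])
  true_ratio <- mean(tru[gt$masks$gm]) / median(tru[gt$masks$wm])
  expect_lt(abs(est_ratio / true_ratio - 1), 0.05)
})

test_that("noiseless BOLD percent signal change equals the designed amplitude", {
  spec <- small_spec(n_subjects = 1, seed = 6, snr = noiseless_snr,
                     amp_jitter = 0)
  gt <- generate_ground_truth(spec, 1)
  design <- block_design(order = rep(c("baseline", "task"), 4))
  sim <- simulate_bold(gt, design, snr = Inf, seed = 1, drift_pct = 0)
  psc <- percent_signal_change(sim$data, design, grid = gt$grid)
  eff <- gt$labels != "none"
  expect_equal(psc$values[eff], gt$designed$dbold_pct[eff],
               tolerance = 1e-6)
  none <- gt$masks$gm & gt$labels == "none"
  expect_equal(max(abs(psc$values[none])), 0, tolerance = 1e-9)
  expect_error(block_design(block_s = 30, tr = 0.7), "aligned")
})
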