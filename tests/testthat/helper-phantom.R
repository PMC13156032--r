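# Uniform-field ground-truth object for direct forward-model tests: every
# brain voxel carries the same parameter values, OEF and CMRO2 derived so
# the oxygenation and Fick identities hold exactly.
uniform_gt <- function(shape = c(6, 6, 4), t2 = 80, r2prime = 5.3,
                       cbv = 4.8, cbf = 44.5, hct = 0.375, o2sat = 0.98,
                       davis = davis_params()) {
  g <- volume_grid(shape)
  brain <- array(TRUE, shape)
  phys <- subject_physiology(hct, o2sat)
  cc <- compute_c(phys)
  cao2 <- compute_cao2(phys)
  oef <- r2prime / (cc * cbv / 100)
  t2star <- 1000 / (1000 / t2 + r2prime)
  mk <- function(v, k) parameter_map(array(v, shape), k, g,
                                     validity = brain)
  cond <- list(t2 = mk(t2, "t2"), t2star = mk(t2star, "t2star"),
               r2prime = mk(r2prime, "r2prime"), cbv = mk(cbv, "cbv"),
               cbf = mk(cbf, "cbf"), oef = mk(oef, "oef"),
               cmro2 = mk(oef * cbf * cao2, "cmro2"))
  structure(list(grid = g, subject_index = 1L, physiology = phys,
                 cao2 = cao2, c_const = cc,
                 masks = list(brain = brain, gm = brain,
                              wm = array(FALSE, shape)),
                 conditions = list(ctrl = cond, task = cond),
                 labels = array("none", shape),
                 designed = list(dbold_pct = array(0, shape),
                                 dcbf_pct = array(0, shape),
                                 dcmro2_pct = array(0, shape),
                                 doef_pct = array(0, shape)),
                 effects = list(), davis = davis),
            class = "ground_truth")
}

# Compact phantom for fast tests.
small_spec <- function(...) {
  phantom_spec(grid = volume_grid(c(16, 16, 8)), ...)
}

noiseless_snr <- c(se = Inf, gre = Inf, asl = Inf, dsc = Inf, bold = Inf)

# Build a contrast_map from plain arrays (grid inferred).
make_contrast <- function(psc_vals, stat_vals, threshold = 2) {
  g <- volume_grid(dim(psc_vals))
  psc <- parameter_map(psc_vals, "psc", g)
  contrast_map(psc, stat_vals, threshold = threshold, source = "GLM-z")
}
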