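Package: mqbold
Title: Multiparametric Quantitative BOLD Mapping of Oxygen Metabolism and
    Neurovascular Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise estimation of brain oxygen metabolism from
    multiparametric quantitative fMRI. Fits T2 and T2* from multi-echo
    spin- and gradient-echo data, forms the reversible relaxation rate R2',
    quantifies cerebral blood flow from pseudo-continuous arterial spin
    labeling and cerebral blood volume from dynamic susceptibility
    contrast, and combines them into oxygen extraction fraction and CMRO2
    maps via Fick's principle. Includes the Davis calibrated-fMRI model
    (forward prediction, CMRO2 inversion, empirical alpha and M
    estimation), task contrasts (percent signal change, mean-centered
    partial least squares with permutation and bootstrap-ratio statistics,
    voxelwise GLM z maps, cluster extraction), classification of voxels
    into concordant and discordant flow-metabolism coupling, and a
    synthetic phantom that generates ground-truth parameter fields and raw
    signals so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
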