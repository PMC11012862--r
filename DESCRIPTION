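Package: gslsrm
Title: Wide-Targeted SRM Method Building and Semi-Quantitative Analysis for Acidic Glycosphingolipids
Version: 0.1.0
Authors@R: person("Analytical", "Lipidomics", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds selected reaction monitoring (SRM) transition lists for
    acidic glycosphingolipids (gangliosides and related sialylated antigens)
    by combinatorial enumeration of glycan headgroups and ceramide fatty-acyl
    chains, computing theoretical monoisotopic precursor m/z values and using
    the sialic-acid fragment ion (nominal m/z 290) as the common product ion.
    Also provides the downstream semi-quantitative workflow: chromatographic
    peak integration with baseline subtraction and a detection floor,
    area-ratio tables, matrix-factor and recovery calculations, calibration
    linearity, creatinine-corrected urinary biomarker evaluation with
    Mann-Whitney testing and ROC/AUC analysis, and seed-deterministic
    simulators for SRM chromatograms and two-group intensity cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
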