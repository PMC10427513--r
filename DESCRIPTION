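Package: airwayDixon
Title: Upper-Airway Dixon MRI Fat-Fraction Mapping and Volumetrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies intra-tissue fat and airway geometry from
    co-registered mDixon magnetic resonance volumes. Computes voxelwise
    fat-signal-fraction maps from fat- and water-saturated channels,
    restricts them to segmented tissue label masks, and derives per-structure
    volumes, intra-tissue fat volume and percentage, and voxel fat-fraction
    histograms. Subdivides the pharyngeal airway at axial landmarks into
    velopharynx, oropharynx and hypopharynx with per-slice cross-sectional
    areas and slice-span lengths. Includes paired baseline/follow-up cohort
    statistics (paired t-tests, repeated-measures Cohen's d with bootstrap
    confidence intervals) and a synthetic Dixon phantom generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
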