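Package: orseg
Title: Retinotopy-Informed Tractography and Segmentation of the Optic Radiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, phantom-validated pipeline for studying direct
    optic-radiation projections to striate and extrastriate visual cortex.
    Implements population receptive field (pRF) forward modeling and two-stage
    fitting with subject-level double-gamma HRF estimation, polar-angle-reversal
    delineation of visual areas V1-V3 (dorsal/ventral) plus a V3A control
    region, diffusion tensor fitting with FA/MD maps and a white-matter
    skeleton, probabilistic seed-to-target streamline tractography, heuristic
    anatomical streamline rejection, Boolean visual-field and hierarchy
    segmentation schemes with surface-area-normalized streamline counts and a
    control-region false-positive estimate, and within-subject statistics
    (paired t tests, Bonferroni correction, repeated-measures ANOVA).
    Ground-truth synthetic phantoms (retinotopic cortical sheets with simulated
    BOLD, nested C-shaped fiber-bundle tensor fields, labeled tractograms)
    make every stage testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
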