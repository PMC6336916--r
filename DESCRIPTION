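Package: fcdsurf
Title: Surface-Based Multimodal Detection of Focal Cortical Dysplasia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Vertex-wise detection of focal cortical dysplasia (FCD) lesions
    from multimodal neuroimaging sampled on cortical surface meshes.
    Implements triangle-mesh geometry primitives (curvature, geodesic
    neighborhoods, surface smoothing), readers and writers for FreeSurfer
    and GIFTI surface formats and NIfTI volumes, cortical depth sampling of
    T1, FLAIR and PET volumes, morphological, intensity and metabolic
    feature maps with interhemispheric asymmetry and local "doughnut"
    contrast, two-stage z-score normalization against a control cohort, a
    PCA plus feedforward neural-network vertex classifier with subject-level
    cross-validation and surface cluster detection, patient-level agreement
    statistics, and a synthetic cohort generator that plants lesions with
    the radiological signatures of FCD type II into phantom hemispheres.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    nnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
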