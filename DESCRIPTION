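Package: cytoatlas
Title: Probabilistic Cytoarchitectonic Maps and Stereological Volumetry of
    Paired Subcortical Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building probabilistic cytoarchitectonic maps and for
    stereological volumetry of paired subcortical nuclei (such as the medial
    and lateral geniculate bodies) from serial histological delineations.
    Provides a synthetic-cohort generator with analytic ground truth, serial
    coronal sectioning with sparse systematic sampling, Cavalieri volume
    estimation with tissue-shrinkage correction and brain-volume
    normalization, Monte-Carlo permutation tests for hemisphere and sex
    effects, 3D reconstruction of label volumes from sparse sections,
    superposition of subjects into 0-100 percent overlap maps with
    center-of-mass reporting, and closed-surface mesh extraction with
    normal-direction smoothing and mesh-volume computation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
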