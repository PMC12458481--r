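Package: leverctx
Title: Population Dynamics of Cued and Self-Paced Actions in Striatal Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis chain for two-photon calcium imaging of dorsolateral
    striatum during a head-fixed lever-press task with alternating cue-evoked
    and self-paced blocks. Provides a synthetic session generator with planted
    ground truth (behavioral event logs, lever kinematics, raw fluorescence and
    neuropil traces from action-timed, cue-locked and post-action response
    archetypes), fluorescence preprocessing (neuropil correction, windowed
    percentile baseline, dF/F, session z-scoring), behavioral quantification,
    peri-event tensors with hierarchical ensemble clustering (Ward, k = 3),
    PCA state-space trajectory divergence with a label-shuffle null, and
    time-resolved linear SVM decoding of initiation context with shuffled-label
    nulls, classifier weight axes and axis projections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
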