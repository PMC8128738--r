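Package: macscore
Title: Mesenteric Artery Calcium Scoring on CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Agatston-definition calcium scoring of the celiac, superior
    mesenteric, and inferior mesenteric arteries (the mesenteric artery
    calcium score, MACS) on CT/CTA volumes within operator-defined scoring
    regions, together with the statistical machinery needed to evaluate the
    score as a screening test for chronic mesenteric ischemia: interobserver
    intraclass correlation, ROC/AUC with cutoff selection, sensitivity,
    specificity and predictive values, group comparisons, and the exact sign
    test for paired scan protocols. A digital CT phantom generator with
    analytic ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    pROC,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
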