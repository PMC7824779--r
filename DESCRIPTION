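Package: grspanel
Title: Genetic Risk Scores for Candidate-Gene Case-Control Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combined-variant genetic risk score (GRS) analysis in
    case-control studies of candidate variant panels, built around a
    recurrent-pregnancy-loss panel of 12 variants across coagulation,
    hormonal, placental, folate and inflammatory pathways. Provides
    per-variant log-additive logistic association with Wald inference,
    weighted and unweighted risk scores with a per-person correction for
    missing genotypes, empirical ROC curves with trapezoid AUC, DeLong
    confidence intervals and the Youden best discriminating point, and a
    Hardy-Weinberg cohort simulator (frequency-matched and
    logistic-liability modes) with per-group missingness injection for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
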