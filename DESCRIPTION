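Package: lipokin
Title: Lipoprotein Kinetics Indicators and Cardiovascular Risk Reclassification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Steady-state population-balance modelling of ApoB-containing
    lipoprotein particles (VLDL through LDL) over a particle-size grid, with
    inverse fitting of production, lipolysis and hepatic-clearance parameters
    to NMR-style subclass concentration profiles.  Fitted kinetics yield
    dimensionless lipoprotein metabolism indicators, including the VLDL
    extrahepatic lipolysis indicator (VLDL_E) and the VLDL hepatic turnover
    indicator (VLDL_H).  The package also provides a synthetic cohort
    generator with Framingham-style risk-factor marginals and a configurable
    logistic 10-year outcome model, an L2-norm (squared-hinge) Gaussian-kernel
    support vector machine risk score with Platt calibration and grouped
    forward variable selection, and model-comparison statistics: ROC/AUC with
    DeLong standard errors and tests, net reclassification improvement (NRI)
    at 6%/20% risk cutoffs, integrated discrimination improvement (IDI), and
    intermediate-risk subgroup reclassification, with delimited report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
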