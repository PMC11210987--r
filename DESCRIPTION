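Package: ckdpheno
Title: Incident CKD Stage G3 Phenotyping and Competing-Risk Progression Analysis
Version: 0.1.0
Authors@R:
    person("ckdpheno", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Longitudinal laboratory-data analysis of incident chronic kidney
    disease (CKD) stage G3 from plasma creatinine time series: CKD-EPI
    creatinine eGFR equations (2009 and 2021), GFR and albuminuria staging,
    KDIGO acute-kidney-injury episode detection and exclusion, incident CKD
    stage G3 case-finding, classification of rapid progression (confirmed and
    potential), drop in GFR category and kidney failure, and Aalen-Johansen
    estimation of cause-specific cumulative incidence with death as a
    competing risk, including risk heat maps over sex, albuminuria, diabetes
    and hypertension/cardiovascular disease. A synthetic registry generator
    with known ground truth drives testing of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
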