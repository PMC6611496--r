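Package: iolml
Title: Machine-Learning Intraocular Lens Power Calculation with Vergence-Based Target Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for learning intraocular lens (IOL) power
    from preoperative biometry. Derives the per-eye ideal lens power from the
    implanted power and achieved refraction through a reversed thin-lens
    vergence model with an SRK/T effective lens position, cleans surgical
    cohorts with configurable clinical inclusion/exclusion rules, fits a
    polynomial-kernel support vector regression and a median ensemble of small
    Levenberg-Marquardt-trained neural networks, and evaluates prediction
    errors with the paired-test battery standard in refractive outcome studies
    (Wilcoxon, McNemar with Yates' correction, sign test, Bonferroni). A
    seeded synthetic cohort generator emulating a cataract-surgery population
    makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
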