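Package: spriming
Title: Simulation and Model Comparison for Syntactic Priming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements three competing cognitive models of syntactic
    priming -- transient declarative activation, associative spreading
    activation, and reinforcement-learning utility selection (plus a
    sequential-feedback variant) -- together with a simulation-based
    empirical likelihood, BIC grid-search fitting, and Group Bayes Factor
    model comparison. Includes trial-schedule builders for two
    prime-target production experiments (active/passive and
    double-object/prepositional-dative alternations), a calibrated
    synthetic participant-cohort generator with logit-normal individual
    differences, and descriptive priming-effect statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
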