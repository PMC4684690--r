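Package: illnessdeath
Title: Illness-Death Models Linking Prevalence, Incidence and Mortality of
    Chronic Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the irreversible three-state illness-death model
    (healthy, diseased, dead) used in chronic-disease epidemiology. Computes
    age- and calendar-time-specific prevalence from incidence and mortality
    hazards via Keiding's integral formula and, equivalently, by integrating
    the prevalence partial differential equation along characteristic lines,
    including the case where only general mortality and relative mortality
    are known. Inverts the relation to estimate age-specific incidence rates
    from two cross-sectional prevalence surveys, and ships a fully specified
    dementia simulation study as a worked benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
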