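Package: halleymort
Title: Halley-Pooled Mortality Age Trajectories and Congenital-Risk Frailty Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing age-specific mortality rate trajectories
    from WHO Mortality Database ICD-10 flat files by Halley pooling of deaths
    and populations across countries and calendar years, with detailed
    infant age resolution (first day, first week, first month, rest of the
    first year).  Fits the log-log model ladder for the childhood decline of
    mortality -- quadratic and linear log-log regressions, the
    single-parameter inverse-proportion hazard mu(x) = mu1/x with its
    closed-form estimator and bespoke coefficient of determination, nested
    F tests and residual diagnostics -- and the two-parameter bent hazard
    implied by a truncated reciprocal (log-uniform) distribution of
    congenital individual risk.  Includes a heterogeneous-frailty cohort
    microsimulator that emits synthetic data in the same WHO file dialect,
    closing the loop with parameter-recovery experiments, plus extreme-age
    rate ratio summaries and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
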