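Package: carproc
Title: Age- and Gender-Adjusted Statistical Indicators of Cardiac Autonomic Regulation
Version: 0.1.0
Authors@R: person("carproc", "developers", role = c("aut", "cre"),
    email = "carproc@example.org")
Description: Builds age-and-gender-adjusted percentile-rank indicators of
    cardiac autonomic regulation from short-term heart rate and blood
    pressure variability proxies.  Provides a synthetic cohort generator
    with planted latent structure, ordinary least-squares adjustment of
    the proxies for age and gender, maximum-likelihood exploratory factor
    analysis with varimax rotation to extract four autonomic domains
    (oscillatory, amplitude, pressure, pulse), construction of the
    composite autonomic nervous system index (ANSI) and of
    percentile-ranked baroreflex and body mass index variables, a
    nine-test non-parametric battery (Kruskal-Wallis, bootstrap median,
    kernel density equality, Jonckheere-Terpstra and
    Hettmansperger-Norton ordered-alternative tests) for body mass index
    group comparisons, and a six-level grading of the strength of the
    resulting empirical evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
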