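Package: cagerest
Title: Home-Cage Rest and Activity Analytics for Capacitance-Based Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving rest and activity phenotypes from capacitance
    home-cage monitoring systems (12-electrode boards sampled continuously under
    each cage). Converts raw capacitance traces into a graded per-minute
    activity index (activation density) and a per-second binary immobility
    series, computes the Regularity Disruption Index (sample entropy of the
    band-pass-filtered minute activity per 12-h light or dark phase),
    zero-activity and rest-bout analytics (percent zero activity per hour,
    least active consecutive hour, rest bouts of at least 40 s with
    time-weighted duration histograms), and rank-based longitudinal statistics
    (ANOVA-type tests for factorial designs with whole-plot and sub-plot
    factors, exact Wilcoxon post-hocs with Bonferroni correction). Includes a
    two-state semi-Markov synthetic cohort generator with circadian structure
    and group effects for power analysis and pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
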