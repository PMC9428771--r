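Package: ratetrends
Title: Bayesian Random-Walk Models for Disease Surveillance Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits first-difference (random-walk) Poisson and binomial
    time-series models to disease incidence counts by Markov chain Monte
    Carlo and derives posterior distributions for the quantities
    surveillance analysts report: annual, cumulative and average annual
    percent change; directly age-standardized rates; pairwise
    health-inequality measures (rate ratio, rate difference, attributable
    risk, excess cases); and the Theil inequality index with its
    between/within decomposition. Includes a reader for CDC-Wonder-style
    surveillance tables, split R-hat and Monte Carlo standard error
    diagnostics, and a synthetic-data generator for model checking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), rjags, coda, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
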