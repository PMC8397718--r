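Package: zipfbias
Title: Unbiased Power-Law Exponent Estimation for Rank-Frequency Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of Zipf and Zipf-Mandelbrot exponents from
    rank-frequency count data (word frequencies, species abundances).
    Implements the exact permutation-sum likelihood that accounts for the
    unknown mapping between empirical ranks and probability ranks, computed
    via the matrix permanent (Ryser's algorithm, tractable only for small
    event sets), alongside the leading-term maximum-likelihood estimators
    it corrects, and likelihood-free approximate Bayesian computation
    estimators (rejection, population Monte Carlo with the Wasserstein
    distance, and regression adjustment) that scale to realistic data.
    Includes exact samplers for bounded and unbounded Zipf and
    Zipf-Mandelbrot distributions, a text-to-counts pipeline, and
    bias/variance simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
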