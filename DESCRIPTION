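Package: tuneshape
Title: Model-Based and Model-Free Analysis of Neuronal Direction Tuning Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits parametric models of neuronal direction tuning curves
    (wrapped Gaussian, wrapped Cauchy, von Mises, symmetric Beta, wrapped
    generalized bell, and Fourier series of order 2-4) to trial-averaged
    firing rates by weighted least squares, with an exact singular-value
    decomposition solution for the Fourier families, goodness-of-fit
    probabilities from the chi-square tail or Monte-Carlo resampling, and
    AIC/AICc model selection.  Centrally, it also bypasses model fitting
    altogether: shape features (peak rates and positions, inter-peak
    minima, widths, bandwidths, skewness, circular variance) are extracted
    algorithmically from the sampled curve itself, so that tuning can be
    described and compared across experimental conditions without
    committing to any parametric form.  Includes nonparametric
    trial-ensemble comparison (Kruskal-Wallis feature tests,
    Kolmogorov-Smirnov specific effects) and a synthetic-data generator
    emulating direction tuning experiments with one or two moving stimuli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, minpack.lm
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr, knitr
Config/testthat/edition: 3
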