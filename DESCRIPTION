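Package: fnirsdyad
Title: Dual-Site fNIRS Hyperscanning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of two-person (dyadic) functional
    near-infrared spectroscopy recordings acquired at two laboratories with
    different optode montages and sampling rates. Provides a synthetic dyad
    generator with known ground truth; modified Beer-Lambert conversion,
    resampling, zero-phase band-pass filtering, global mean removal and
    channel quality control; Gaussian-kernel co-localisation of montages onto
    a common 134-channel mask with Brodmann-defined region-of-interest
    averaging; canonical-HRF general linear models on the HbDiff signal with
    group contrasts and FDR correction; residual-based inter-brain wavelet
    transform coherence with a shuffled-dyad permutation null and period-wise
    two-way ANOVA; and a socket handshake protocol for synchronising paradigm
    starts across laboratories with full event logging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
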