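Package: retivasc
Title: Quantitative Retinal Vasculature Analysis for Ultra-Widefield Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies retinal vascular morphology on ultra-widefield fundus
    photographs: region-of-interest covers (a centered oval general cover and
    per-image detached/attached partitions), channel-filter preprocessing and
    edge-detection vessel extraction, partition of the vessel map into short
    segments with minimum-enclosing-rectangle fits, and per-region vascular
    density, caliber, and five inter-segment-angle tortuosity statistics
    (unweighted, area-, length-, width-, and inversely-width-weighted).
    Includes the matching nonparametric group comparisons (Mann-Whitney U with
    mean ranks, paired Wilcoxon signed-rank with positive/negative mean ranks,
    proportion-based sample-size formula), radar-plot summaries, and a
    synthetic fundus cohort generator with known ground-truth vessel geometry
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
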