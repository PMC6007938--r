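Package: strandseg
Title: Non-Random DNA Strand Segregation and Somatic Mutation Rates from
    Single-Cell Mutational Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic model of somatic mutation accumulation in
    hierarchically organised tissues maintained by a constant pool of stem
    cells that may segregate DNA strands non-randomly (the immortal strand
    hypothesis). Provides closed-form moments of the single-cell mutational
    burden under a compound Binomial-Poisson law, an individual-based
    simulator of asymmetric, mixed symmetric/asymmetric, and
    division-independent (background) mutation dynamics, a synthetic-cohort
    generator emulating single-cell sequencing study designs, and
    method-of-moments inference of the strand-segregation probability and the
    per-division mutation rate from the age trends of the mean and variance of
    mutational burden, with plug-in or bootstrap error bounds and sensitivity
    scans over the stem-cell division rate. Ships the published per-tissue
    regression slopes for healthy human colon, small intestine, liver, skin
    and brain so the tissue-level estimates can be recomputed without access
    to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
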