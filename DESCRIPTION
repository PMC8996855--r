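Package: clonedyn
Title: Stochastic Simulation of Tumor Subclonal Evolution and Therapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, reproducible simulator of tumor subclonal dynamics under
    the clonal evolution theory. Subpopulations grow by a discrete-time
    birth-death process with a Gompertz-like competition constraint, drift
    through slightly deleterious passenger mutations, and branch into new
    subclones through rare driver events grouped into three cancer-hallmark
    categories. Four cytotoxic therapy operators (targeted, general, surgery,
    immunotherapy) act on the simulated tumor, and two intra-tumor
    heterogeneity metrics (dominant clone proportion and off-target
    probability) summarize states and trajectories. A replicated experiment
    harness regenerates therapy-timing, adjuvant-versus-neoadjuvant,
    heterogeneity-outcome and tumorigenesis studies as tidy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
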