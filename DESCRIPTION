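Package: fitnessnet
Title: Fitness Relationships Among Cancer Driver Genes from Expression and Network Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts directed "fitness relationships" among cancer driver
    genes by stochastic sampling of driver-induced modules (DIMs) on a
    background gene interaction network. Candidate modules are grown greedily
    around each driver seed to maximise a tumor-versus-normal Welch t score of
    module activity, filtered for enrichment of differentially expressed
    genes, and converted into weighted directed fitness networks over the
    driver set. Provides indegree-ratio based fitness-core detection,
    sample-coverage statistics, co-occurrence and mutual-exclusivity
    classification of edges against somatic alteration profiles,
    signaling-network continuity validation, consensus networks across
    background networks, and a synthetic-data generator with planted modules,
    mutation dependencies and signaling paths for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
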