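Package: elastiseq
Title: Elastic Cloud Pipeline Simulation for Parallel Sequence Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A self-contained framework for planning and simulating elastic
    cloud execution of parallel sequence-search workloads. A k-mer-profile
    runtime estimator predicts CPU-hours for a query set against a reference
    database, a partition planner splits multi-FASTA queries into work units
    sized to a target per-partition runtime, and a provisioning policy chooses
    instance counts under protocol floors and provider/user caps. A simulated
    cloud backend (virtual clock, boot latency, hourly billing, three-call
    provider API) hosts master/worker clusters with Grid-Engine-like queue
    slots, prolog/epilog data movement and peer-to-peer staging-directory
    mirroring, on which a seven-phase wrapper pipeline stages data, runs a
    pluggable worker workload and tears the cluster down. A bundled synthetic
    FASTA generator makes every experiment reproducible at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
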