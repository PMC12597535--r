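Package: seqcost
Title: Microcosting of Genomic Profiling Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bottom-up (microcosting) engine for diagnostic genomic
    profiling workflows. Resource line items (reagent kits, personnel
    tasks, amortized instruments, laboratory space, software licenses and
    data storage) are organized over a nine-step diagnostic workflow and
    costed per sample at any weekly batch size, distinguishing variable,
    fixed and step-fixed cost behavior. Equipment is annuitized with the
    equivalent annual cost method; a flat overhead markup is applied to
    all direct costs. Includes a declarative scenario layer (price
    discounts and surcharges, per-step weights, step exclusion, batch-size
    overrides, investment costs, alternate workflow variants), batch-size
    sweeps with personnel-capacity flags, report rendering with explicit
    rounding conventions, a calibrated example inventory, and a seeded
    synthetic-inventory generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
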