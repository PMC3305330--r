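Package: crowdgate
Title: Entropic Crowding Effects on Membrane-Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-mechanical model of protein crowding in biological
    membranes. Membrane proteins are represented as a two-dimensional mixture
    of hard disks; scaled-particle theory (and a simpler ideal-gas limit)
    yields the entropic surface and line tensions that the crowders exert on
    a conformationally switching channel such as the mechanosensitive channel
    MscL. The package computes crowding contributions to gating free energies,
    gating-tension shifts, and two-state open-probability curves in both the
    constant-area and constant-tension ensembles, converts transmembrane-helix
    abundance tables into disk-radius distributions, and validates the
    scaled-particle predictions against an independent hard-disk Metropolis
    Monte Carlo oracle with Widom test-particle insertion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
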