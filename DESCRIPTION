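Package: helixswitch
Title: Coarse-Grained Design of Two-State C3-Symmetric Helical Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing homotrimeric helical bundles
    with two divergent ground states: a compact "short" state in which mobile
    flipping helices fold back against the inner helices, and an extended
    "long" state in which they continue past the hinge and pack against each
    other. Provides Crick-parameterized backbone generation and fitting,
    ABEGO torsion-bin classification, construction of both states from a
    single architecture description, hydrogen-bond-network versus hydrophobic
    interface-layer enumeration and scoring, hinge ion-coordination-site
    checks, symmetry-aware RMSD state classification, and the solution
    observables used to discriminate the states (Debye scattering profiles,
    Guinier and normalized Kratky analysis, per-state profile fitting, and
    combined NMR chemical-shift deviations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
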