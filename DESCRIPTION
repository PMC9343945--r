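Package: hbmforge
Title: A Morphed Lineup Factory for Finite-Element Human Body Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to derive sex- and posture-variant finite-element human
    body models from a shared base model by landmark-driven radial-basis-
    function mesh morphing, and to run the quality-assurance machinery
    around such a lineup.  Includes a reader/writer for modular solver
    keyword decks in which all model variants share every include file
    except the node coordinates, hexahedral and shell element quality
    metrics with pass/fail classification, region-wise mass accounting
    with flesh-density calibration and explicit-timestep added-mass
    estimation, a blunt-impact validation catalog with deck emission,
    channel-class (CFC) signal filtering, deflection channels, and
    force-deflection corridor scoring.  A deterministic fixture generator
    produces small hex-meshed body-like models, landmark sets, morph
    targets, and synthetic time histories so the whole pipeline is
    testable without a commercial solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
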