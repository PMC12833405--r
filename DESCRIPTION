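Package: ukawear
Title: Adaptive Polyethylene Wear Simulation for Medial Unicompartmental
    Knee Arthroplasty
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulation of tibial-insert wear in fixed-bearing
    medial unicompartmental knee arthroplasty under ISO-14243-style gait
    loading. Articular surfaces are analytic height fields contacting
    through an elastic (Winkler) foundation; wear follows the Archard law
    with step-wise adaptive geometry updates. A two-compartment force and
    varus-valgus moment balance about the offset femoral load point lets
    progressive insert wear redistribute load onto the lateral tibial
    cartilage, whose stress trend is reported alongside gravimetric wear.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
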