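Package: floodAccess
Title: Flood-Conditioned Geographic Access to Maternal Health Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Couples monthly hydrodynamic flood fields (depth and velocity
    rasters) with two geographic access models for maternal healthcare on a
    seasonally flooded plain: a raster walking model built on 16-neighbour
    (knight's move) accumulated-cost surfaces from monthly impedance layers,
    and a vehicular emergency-referral model that applies depth/velocity
    speed rules to a classed road network and routes delivery-site to
    emergency-obstetric-care referrals with Dijkstra shortest paths. A
    population-weighted coupling joins the two models into monthly summaries
    of timely access, inaccessibility and referral coverage. Includes a
    seeded synthetic floodplain generator (parametric 13-month floodwave,
    classed road lattice with an elevated causeway, flagged facilities,
    clustered population) so the full pipeline runs end-to-end without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
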