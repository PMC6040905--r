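Package: emsclust
Title: Geospatial Clustering of Opioid-Related EMS Runs and Naloxone Site Modeling
Version: 0.1.0
Authors@R: person("ProEMS", "Analytics", email = "analytics@example.org",
    role = c("aut", "cre"))
Description: Spatial point-pattern analysis of opioid-related emergency
    medical services (EMS) runs at city scale: ingestion and deduplication of
    geocoded run records, clipping to a city boundary, global clustering
    inference via Ripley's K-function with isotropic edge correction and
    Monte-Carlo envelope tests, local hotspot discovery with DBSCAN,
    per-cluster characterization (area, centroid distances, demographics),
    and modeling of publicly deployed naloxone (PDN) coverage at candidate
    sites. Includes a synthetic city generator so the full pipeline is
    testable without confidential EMS records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
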