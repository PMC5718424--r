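Package: fwcomplement
Title: Complementarity Analysis of Agency and Citizen-Science Freshwater Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess how a citizen-science water-quality campaign
    complements a regulatory agency's monitoring network across a river
    catchment. Implements hexagonal-grid spatio-temporal coverage and overlap
    scoring, D8 flow accumulation with Strahler stream ordering and site
    pooling, Ramsar still-water size classification, harmonization of
    continuous and field-kit categorical nitrate readings onto a common
    category scheme, and a contingency-table association suite (Pearson
    chi-squared, Cramer's V, adjusted-residual post-hoc with Bonferroni
    correction, Mann-Whitney U). A synthetic catchment generator emulates two
    actors with different spatial, seasonal and waterbody-type sampling
    biases so the full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
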