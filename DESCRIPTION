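Package: dunbargraph
Title: Layered Egocentric Social Networks: Layer Detection, Effort
    Allocation and Diffusion on Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the layered ("Dunbar graph") model of egocentric
    social networks. Detects discrete layers in contact-frequency data by
    exact optimal one-dimensional partitioning (Jenks natural breaks,
    equivalently exact 1-D k-means) with automatic layer-count selection;
    computes descriptive layer statistics (annuli, scaling ratios, social
    effort shares, grouping-size summaries); implements the layered
    information-reach model with its 1/e optimal-community-size criterion;
    the one-parameter Bayesian urn model of effort allocation across
    relationship layers with its concave/convex phase transition; and a
    cultural-transmission simulator on a toroidal lattice with
    friend/friend-of-friend neighbour classes plus a mean-field variant.
    A synthetic-data generator emulates layered contact-rate distributions
    and small weighted community graphs so every component is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
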