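Package: voroscaffold
Title: Cube-Bounded 3D Voronoi Wireframes for Biomedical Scaffold Design
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates cube-bounded three-dimensional Voronoi wireframe
    structures from random generating points, relaxes them toward centroidal
    Voronoi tessellations with Lloyd iterations, and measures their structural
    parameters: vertex, edge and face counts, mean edge length and the Euler
    characteristic. Provides closed-form inverse design equations that predict
    the number of generating points needed to achieve a desired structural
    parameter, ensemble simulation and regression tools to refit the design
    coefficients, biomedical case studies (lymph-node niche, trabecular bone,
    kidney tumour), and export of printable wireframe meshes (OBJ, PLY,
    binary STL).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    withr,
    ggplot2,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
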