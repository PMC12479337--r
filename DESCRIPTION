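Package: periacinar
Title: Geometric Modelling of Peri-Insular Acinar Expansion and Pancreas Volume
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a geometric model of insulin's trophic action on
    peri-islet acinar tissue. Beta cells are modelled as spheres, islets as
    equivalent-volume spherical clusters, and insulin action as either a
    constant concentric shell or an exponentially decaying paracrine
    gradient around each cluster. The model maps beta-cell density, cluster
    size, insulin-action extent and acinar expansion magnitude to
    whole-pancreas volume, reproduces the predicted atrophy of the diabetic
    pancreas, and inverts observed pancreas volumes to beta-cell density
    estimates. Includes parameter-sweep utilities that emit tidy CSV tables,
    packaged sweep presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
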