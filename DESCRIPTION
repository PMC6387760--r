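Package: theroturn
Title: Mass Properties, Muscle-Force Proxies, and Phylogenetically
    Informed Turning-Agility Comparisons for Bipedal Dinosaurs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates body mass, centre of mass, and yaw rotational inertia
    of bipedal dinosaurs from digitized body-outline station tables, using
    superelliptical frusta and the parallel-axis theorem.  Computes
    muscle-force proxies (lateral ilium area and m. caudofemoralis longus
    cross-sections), relative turning-agility indices for planted-foot and
    en-pointe pivoting scenarios, and compares groups of taxa with
    phylogenetic generalized least squares, Pagel's lambda, grade-wise
    phylogenetic ANCOVA F-tests, and conditional error probabilities.
    Includes a synthetic-data generator producing analytic solids with
    closed-form mass properties, parametric theropod-like bodies, geometric
    scaling series, and traits simulated on time-calibrated trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
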