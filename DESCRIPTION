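Package: divmapr
Title: Spatial Mapping of Microsatellite Diversity with Circular-Neighborhood Re-Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the genetic diversity of georeferenced, diploid codominant
    (microsatellite) genotypes onto a geographic grid. Each tree is re-sampled
    into all 10-arcminute grid cells within a one-degree circular neighborhood,
    and per-cell diversity statistics are computed: allelic richness with
    hypergeometric rarefaction, locally common alleles, expected and observed
    heterozygosity, fixation index, and mean genotypic distance to a reference
    cultivar. Includes a climate-outlier (reverse-jackknife) coordinate screen,
    maximum-likelihood admixture clustering with Evanno delta-K model choice,
    ex situ genebank gap analysis based on private alleles, evaluation of
    modeled distribution surfaces (AUC, Cohen's kappa, sampling-coverage
    classes), and a synthetic-landscape generator with known truth for
    validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    mgcv,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
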