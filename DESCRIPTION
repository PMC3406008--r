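Package: bovrec
Title: Male Meiotic Recombination Analysis in Half-Sib Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects crossovers in three-generation paternal half-sib pedigrees
    genotyped with medium-density SNP arrays, deconvolves gamete crossover
    counts into meiotic chiasma-number distributions, builds normalized 60-kb
    window recombination maps with hot/cold window calls, quantifies crossover
    interference with a gamma-renewal composite likelihood, derives sire-level
    recombination phenotypes (genome-wide recombination rate, hot-window usage,
    interference level) with family-size bias correction and REML heritability,
    and maps recombination QTL with a haplotype-cluster mixed model and
    permutation thresholds. Includes a synthetic-data generator emulating a
    cattle-style study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
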