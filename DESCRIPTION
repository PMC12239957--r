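Package: genovuln
Title: Genetic Load, Genotype-Environment Association and Genomic Offset
    Analysis for Climate-Vulnerability Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess the genomic and ecological vulnerability of
    structured wild populations to climate change. Implements derived-allele
    genetic-load statistics (Rx/y ratios with block-jackknife errors,
    synonymous-normalised per-individual burdens, GERP-based masked and
    realized load), sliding-window Weir-Cockerham Fst and nucleotide-diversity
    selection scans with top-quantile outlier calling, a two-method
    genotype-environment association screen (constrained-ordination loading
    outliers and latent-factor regression) after variance-inflation pruning,
    gradient- and dissimilarity-based genomic offsets (local, forward under
    dispersal caps, and reverse) with RGB composite maps, and ensemble
    habitat-suitability modelling with AUC/TSS gating and an ecological
    vulnerability map. A forward Wright-Fisher simulator generates genotype,
    annotation and climate fixtures emulating two diverged populations, one
    recently bottlenecked, on an environmental gradient, so the whole pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vegan,
    rpart,
    geosphere,
    randomForest,
    e1071,
    mgcv,
    xgboost,
    pracma,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
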