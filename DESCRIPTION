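Package: radpopgen
Title: RAD-Seq Population Genomics: SFS Demographic Inference, Admixture
    and Differentiation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the demographic and admixture history
    of closely related populations from reduced-representation (RAD)
    genotype data. Implements the full inference chain from VCF-style
    genotype tables through depth, Hardy-Weinberg and linkage filtering to
    multidimensional site-frequency spectra (SFS); coalescent simulation of
    hierarchical demographic models with population splits, admixture
    pulses, migration and unsampled (ghost) demes; composite-likelihood
    model fitting, AIC model comparison, block-bootstrap confidence
    intervals and model-distinguishability analysis; ABBA-BABA D-statistics
    with block-jackknife errors, diagnostic-SNP panels and hybrid indices;
    windowed weighted FST, nucleotide diversity, absolute divergence and
    recombination rates; and permutation tests for genomic islands of
    differentiation. A synthetic-data module generates RAD-like
    multi-population cohorts under the packaged demographic models so that
    every stage of the pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
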