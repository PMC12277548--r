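Package: areascan
Title: Regional Gray-Matter Deficit Mapping with Genetic Association and
    Developmental Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for localizing case-control gray-matter
    volume deficits to cortical parcels (Brodmann-style areas) and linking
    them to genetic variation and developmental gene expression. Provides
    voxel-wise general linear model t-maps with cluster-extent thresholds
    and permutation-based family-wise error control, a subsample-ranking
    procedure that orders parcels by affected-voxel burden, single-case
    derivation of per-parcel case phenotypes, logistic SNP association
    scans with genotype quality control, clumping-and-thresholding
    polygenic risk scores with Nagelkerke pseudo-R-squared threshold
    selection, and areal expression statistics (positive-cell ratios,
    relative in situ hybridization intensities, areal pattern labels).
    A synthetic-data module generates parcellated gray-matter images,
    Hardy-Weinberg genotypes with planted causal variants, noisy discovery
    summary statistics and area-labeled expression fixtures so the whole
    pipeline runs reproducibly without access to a clinical cohort.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    Matrix,
    IRanges,
    S4Vectors,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
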