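Package: ncmhap
Title: Single-Individual Haplotype Assembly by Neutrosophic c-Means
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the two haplotypes of a diploid individual from
    aligned sequencing fragments restricted to heterozygous SNP sites.
    Fragments (rows over {0,1,-}) are first bipartitioned greedily on a
    weighted fuzzy conflict graph whose edge weights are overlap-normalized
    Hamming distances; the resulting cluster centers seed a neutrosophic
    c-means refinement that down-weights noisy and outlier fragments via
    indeterminacy and falsity memberships, and the refined centers are
    rounded into a complementary haplotype pair.  Includes readers for plain
    matrix and HapCUT-style fragment files, a Geraci-style benchmark
    instance simulator, minimum-error-correction (MEC) and reconstruction
    rate (RR) evaluation, and a command-line interface for phasing,
    simulation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
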