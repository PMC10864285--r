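Package: ovascreen
Title: Tissue-Enrichment Candidate Selection and RNAi Nondisjunction Screen Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for transcriptome-guided gene-discovery screens
    of female meiosis and fertility in Drosophila. Selects candidate genes from
    replicate tissue expression arrays (enrichment over whole body, Student's t
    test, present-call and probe-set filters, four-way tissue classification),
    scores germline RNAi crosses with the X-chromosome nondisjunction estimator
    2(XO + XXY)/[2(XO + XXY) + XX + XY] and the sterility / nondisjunction /
    small-brood positivity rules, aggregates line calls to gene-level Venn
    categories, and performs hypergeometric overrepresentation with
    Benjamini-Hochberg FDR plus confidence-thresholded protein-protein
    interaction subnetwork extraction. A synthetic-data generator with planted
    ground truth (tissue fold-changes, true nondisjunction egg fractions,
    sterile genes) makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
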