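Package: metashot
Title: Shotgun Metagenome Read Counting, Core-Pan Analysis and Enterotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for quantitative analysis of shotgun
    metagenomes against reference catalogues. Streams FASTQ reads through
    quality filtering, host-read removal and simultaneous counting against a
    gene catalogue and a genome catalogue; combines sequencing runs into
    samples; annotates counts to taxonomy and functional orthologs; performs
    rarefaction by multivariate hypergeometric subsampling; computes gene
    richness, Shannon diversity, core and pan species/gene curves; clusters
    genus profiles into enterotypes with Jensen-Shannon distance, partitioning
    around medoids and Calinski-Harabasz model selection; and builds
    non-redundant gene catalogues by greedy identity/coverage clustering with
    per-study provenance. A seed-deterministic synthetic-data generator
    produces multi-study cohorts with known ground truth so every pipeline
    stage can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    vegan,
    ape
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite
Config/testthat/edition: 3
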