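Package: annoqc
Title: Quality Control for Annotated Prokaryotic Genome Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes annotation-report measures (coding density, protein
    length statistics, hypothetical-protein and standard-start-codon ratios,
    rRNA/tRNA complements) for annotated prokaryotic genomes, evaluates the
    community minimal annotation standards (ribosomal RNA set, tRNA coverage
    for all amino acids, core conserved functions, protein naming), and lints
    features against INSDC feature-table conventions: structured /inference
    and /experiment evidence qualifiers, pseudogene annotation strategies,
    locus_tag format, and protein naming rules. Includes readers and writers
    for GenBank flat files, GFF3 (+FASTA) and the INSDC 5-column feature
    table, a cross-genome comparison layer (column scaling, linear
    regression, PCA, hierarchical clustering, z-score outlier flagging), and
    a deterministic synthetic-genome generator with known ground truth for
    testing every measure and rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
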