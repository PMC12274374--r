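Package: kdrseq
Title: Amplicon-Sequencing Genotyping and Bottle-Bioassay Analysis for
    Insecticide-Resistance Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end desk-scale toolkit for molecular surveillance of
    insecticide resistance in Aedes aegypti. Simulates dual-indexed amplicon
    sequencing panels targeting canonical resistance loci (vgsc, ace-1, rdl,
    GSTe2) with configurable allele frequencies, linkage structure, coverage
    and index-hopping; demultiplexes and quality-trims paired reads; assigns
    and aligns reads to panel amplicons with alternate-reference support;
    calls diploid genotypes with two independent callers intersected;
    annotates amino-acid consequences and resolves multi-SNP codons by
    read-backed phasing; produces genotype-count, allele-frequency and
    linkage-disequilibrium (EM r-squared) tables; and analyses CDC bottle
    bioassay mortality with WHO/CDC classification, pooling and an offset
    Poisson log-linear model with likelihood-ratio tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
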