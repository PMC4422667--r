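Package: famvar
Title: Candidate-Gene Discovery and Pathogenicity Classification for
    Familial Cancer Exome Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing rare germline coding variants in
    familial cancer cohorts. Parses HGVS coding-DNA (c.) variant
    nomenclature and annotates coding consequences (missense, nonsense,
    start-loss, canonical splice, exon-skip frameshift) against a
    transcript model; applies the exome filtration cascade used in
    candidate-gene discovery (database exclusion, heterozygous
    truncating/damaging retention, cross-case gene recurrence); classifies
    variants as pathogenic, neutral or of uncertain significance from an
    evidence bundle combining consequence class, in vitro helicase-assay
    activity, transcript analysis and case/control carrier counts;
    computes exact two-by-two carrier-burden statistics from first
    principles; quantifies DNA-unwinding assay replicates; and assesses
    tumor loss of heterozygosity from allele depths. A synthetic-data
    module generates a RECQL-like transcript model, case/control cohorts
    with planted pathogenic variants, assay replicates and allele-depth
    tables so the whole pipeline is exercisable and testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
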