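Package: methaplotype
Title: Methylation Haplotypes of Homologous Chromosomes from Bisulfite
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs paired methylation haplotypes of the two homologous
    chromosomes inside CpG-dense candidate regions from per-read bisulfite
    methylation calls (Bismark-style XM tags or a plain per-read call table),
    classifies CpG sites into methylation-homozygous and -heterozygous ones
    via joint read-pattern filtering with confidence-based conflict
    resolution, summarises each region's haplotype pair as a methylation
    haplotype mode, quantifies methylation and hypomethylation consistency
    between homologs, and calls differentially methylated regions between
    samples at haplotype resolution using the methylation haplotype
    difference statistic with a read-permutation test. Includes a simulator
    that generates paired-homolog read data with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    methods,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
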