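Package: pamtrack
Title: Tumor-Specific CRISPR PAM Discovery and Maintenance Across Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers somatic single-base substitutions that create novel
    NGG protospacer-adjacent motifs (PAMs) from matched tumor-normal variant
    calls, designs candidate sgRNA protospacers, classifies the zygosity and
    copy-number context of each target (heterozygous, truncal or private loss
    of heterozygosity), and quantifies how well truncal PAM targets are
    maintained across the metastases of a case (percent truncal, percent
    maintained, percent shared by all lesions). Builds UPGMA sample trees
    from binary PAM presence matrices and re-roots them at the least-derived
    primary sample. Includes a haplotype-resolved clonal-evolution simulator
    of rapid-autopsy cases so the entire pipeline can be exercised and
    validated without access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
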