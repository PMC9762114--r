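Package: ithescape
Title: Multi-Region Tumor Heterogeneity and Immune-Escape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-regional tumor/immune profiling of clear cell
    renal cell carcinoma cohorts. Computes intratumoral heterogeneity (ITH) scores over
    DNA (subclonal/clonal driver ratio), RNA (expected absolute log2 fold change), and
    T cell receptor (clonotype sharing) modalities; scores samples against gene
    signatures by single-sample gene-set enrichment (ssGSEA) with cohort Z-scores and
    median high/low splits; accounts for neoantigen depletion after checkpoint therapy
    and classifies immune elimination versus evasion (HLA loss of heterozygosity or
    expression loss), including HERV immunogenicity and editing; summarizes TCR
    repertoire diversity (Shannon entropy, Morisita-Horn overlap) and clonotype
    trajectories; discovers weighted co-expression modules via soft-thresholded
    topological overlap and derives a refined immune-escape gene signature; and
    stratifies survival by median signature score with Kaplan-Meier/log-rank and Cox
    models. A fully synthetic multi-regional cohort generator with known ground truth
    makes every stage testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
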