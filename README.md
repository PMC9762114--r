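# ithescape

Multi-region tumor heterogeneity and immune-escape analysis for clear cell
renal cell carcinoma (ccRCC) cohorts profiled before and after immune
checkpoint inhibition (ICI).

Spatially distinct regions of one ccRCC tumor can differ in their driver
mutations, transcriptional microenvironment, and T cell repertoire. This
package quantifies that intratumoral heterogeneity (ITH) per modality,
accounts for the fate of candidate neoantigens under therapy, discovers the
co-expression module most tied to neoantigen loss, and turns it into a gene
signature for survival stratification. It is aimed at computational
immuno-oncology analysts working with multi-regional WES/RNA-seq/TCR-seq
tables (expression matrices, MAF-like mutation calls, NetMHCpan-style %Rank
tables, AIRR rearrangement files).

## What it computes

**ITH scores.**

- RNA ITH: after per-gene median centering of log2 expression, the
  per-patient score is the median over genes of the median absolute pairwise
  difference between regions — the expected |log2 fold change| of a random
  gene between two regions of that tumor.
- DNA ITH: `#subclonal / #clonal` driver alterations, where an alteration is
  subclonal iff present in fewer than half of the patient's regions.
- TCR ITH: `1 − |shared| / |union|` of clonotypes (CDR3β amino-acid sequence
  + V gene) across regions.
- Patients cluster into ITH-high/low on binary genomic features (VHL, PBRM1,
  SETD2, BAP1, HLA LOH, CDKN2A/B loss), with per-feature Fisher exact tests
  and a Fisher's-method combination across modalities. Region trees are
  built by neighbor joining on alteration presence vectors.

**Immunoediting.** Candidate neoantigens are the 8–11-mer windows of a
mutant 17-mer covering the mutant residue (32 windows for a central
mutant), detected when the supporting mutation is called and the best MHC-I
%Rank is ≤ 2, expressed when source-gene TPM > 1. The depletion fraction of
a treated region is |pre \ post| / |pre|. Each depleted neoantigen is
classified with purity-corrected fold changes FC =
(TPM_post/purity_post) / (TPM_pre/purity_pre):

| condition | class |
|---|---|
| presenting allele lost (HLA LOH) | `evasion_LOH` |
| no LOH, log2 FC < −1 | `evasion_expression` |
| no LOH, log2 FC ≥ 0 | `elimination` |
| no LOH, −1 ≤ log2 FC < 0 | `ambiguous` |

HERV loci whose expression correlates positively with TIL abundance at
BH FDR < 0.05 are "immunogenic"; HERV editing is the median log2 change of
those loci after therapy, with iterated Grubbs flagging of outlying samples.

**Repertoire.** Shannon entropy (natural log), richness, clone counts,
Morisita-Horn overlap matrices, and trajectory tracking of dominant clones.

**Escape modules.** WGCNA-style pipeline: filter genes (expressed in ≥ 5% of
samples, sd(log2 TPM) > 1, protein-coding), pick the soft power β by
scale-free fit (R² ≥ 0.8), adjacency |cor|^β, topological overlap
TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij), average-linkage
modules with a static cut, PC1 eigengenes, Spearman trait annotation (the
module most correlated with the fraction of neoantigens depleted is the
immune-escape module), and greedy refinement to a signature whose pairwise
Spearman ρ is ≥ 0.6 throughout. The package ships the published 12-gene
immune-escape signature (TIMP1, PXDN, COL15A1, OLFML2B, COL5A2, DLX5,
SOX11, KLHDC8A, UNC5A, ADAMTS14, MMP11, FN1).

**Survival.** ssGSEA signature scores with cohort Z-scores, median
high/low splits, Kaplan-Meier/log-rank, and univariate Cox (Efron ties).

**Synthetic cohort.** `simulate_cohort()` generates a fully synthetic
multi-regional cohort with known ground truth — planted co-expression
modules and trait links, clonal/subclonal drivers, neoantigen depletion
with a configured editing mix, Zipf clonotype abundances with controlled
sharing, exponential survival with a configured hazard ratio — so every
stage is testable without controlled-access patient data.

## Worked example

```r
library(ithescape)

co <- simulate_cohort(cohort_config(seed = 17))
co
#> Synthetic multi-regional cohort
#>   16 patients, 101 samples (77 tumor)
#>   expression: 1500 genes x 77 samples
#>   1883 mutation calls, 864 neoantigen records, 30300 clonotype rows
#>   survival: 200 subjects, HR 1.50

# ITH per modality
ri <- rna_ith(co$expression, co$sheet)
di <- dna_ith(co$mutations, co$sheet, drivers = names(co$config$driver_genes))
round(di$patient[1:4], 2)
#> P01 P02 P03 P04
#> 0.5 0.0 1.0 0.0

# neoantigen depletion for one treated patient
det <- detect_neoantigens(co$neoantigens, co$mutations)
sh <- co$sheet
pre  <- det$neo_id[det$detected & det$sample == "P01_BX"]
post <- lapply(setNames(nm = sh$sample[sh$patient == "P01" & sh$timepoint == "post" &
                                       sh$tissue == "tumor"]),
               function(s) det$neo_id[det$detected & det$sample == s])
depletion_fraction(pre, post)$patient
#> [1] 0.3

# escape-module discovery against the planted depletion trait
traits <- data.frame(depletion = co$truth$expression$traits$depletion,
                     row.names = colnames(co$expression))
em <- discover_escape_modules(co$expression, traits, coding = co$coding)
em$annotation$escape_module   # module labeled immune escape
#> [1] 1

# Cox fit of the simulated two-group survival table
fit <- cox_univariate(co$clinical)
round(fit$hr, 2)
#> [1] 1.62
```

The printed numbers above are what the code produces at seed 17: patient
P01's drivers split one subclonal to two clonal (DNA ITH 0.5), the planted
30% per-region depletion is recovered exactly, the depletion-linked module
is labeled immune escape, and the Cox fit estimates a hazard ratio of 1.62
against the simulated 1.5 (a 200-subject table; the calibration study in
`scripts/acceptance.R` uses 1000 subjects).

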