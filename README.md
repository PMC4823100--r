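# aerlnc

Estrogen receptor alpha (ERα) does more than transduce estrogen: in
hormone-deprived luminal breast-cancer cells the *unliganded* (apo)
receptor sustains the basal transcription of genes that maintain the
epithelial phenotype. Silencing the receptor in such cells changes the
expression of a specific set of long non-coding RNAs — a set that is
largely distinct from the estrogen-responsive program and that behaves
as a luminal-subtype signature. `aerlnc` implements, as a tested and
reusable R pipeline, the computational workflow that defines such a
catalog and characterizes it, for computational biologists working on
receptor-dependent transcription and lncRNA biomarkers.

## What the package computes

**Catalog construction.** A minimal negative-binomial Wald test per gene
(median-of-ratios size factors *ŝⱼ*, moment dispersion φ̂ stabilized
across genes, Var = μ + φμ²), integrated across callers by a consensus
rule — significant at BH-adjusted *p* < α in ≥ *k* tables with
concordant fold-change sign — then filtered to lncRNA biotypes with
longest transcript ≥ 200 bp and no blacklist membership, and quantified
as RPKM = *n̂* / (kb × million reads).

**Cis-regulation.** Distances |TSS − summit| to the nearest binding
site, capped at 1,000 kb; enrichment is judged against 1,000 random gene
sets matched exactly on biotype composition, with a one-sided Wilcoxon
rank-sum test and an exactly calibrated empirical median *p*-value.
Binned ChIP signal (±1 kb, 50 bp bins, 200 bp read extension, CPM)
yields promoter/enhancer calls from the H3K4me3/H3K4me1 mean-CPM ratio.

**Signature selection and evaluation.** Per-gene merit = cross-validated
χ² of discretized expression against subtype labels (10 stratified
folds, equal-frequency bins); the signature is merit > 15. It is
evaluated by 10-fold cross-validated single-hidden-layer perceptron
classification, Ward (`ward.D2`) clustering with purity, and PCA.

**Downstream screens.** Guilt-by-association Pearson screening
(|r| ≥ 0.7 and *p* < 0.001, *t* = r√((n−2)/(1−r²))), and two-run qRT-PCR
harmonization: ΔCt series are aligned through paired log-scale
quantiles, a standardized-major-axis line with 200-iteration bootstrap
(min out-of-bag MSE) estimates the location/scale batch map, and group
differences are tested by Wilcoxon with Shapiro–Wilk reported alongside.

A synthetic-data module (`sim_config()`, `gen_annotation()`,
`gen_counts()`, `gen_binding_sites()`, `gen_panel()`, `gen_chip_tags()`,
`gen_ct()`) generates every input with planted ground truth, so the
whole pipeline runs and is testable offline.

## Worked example

```r
library(aerlnc)
res <- run_demo(seed = 1, outdir = "demo_out")
str(res$summary)
#> List of 10
#>  $ catalog_size            : int 60
#>  $ n_down                  : int 35
#>  $ n_up                    : int 25
#>  $ distance_wilcoxon_p_down: num 1.54e-16
#>  $ promoter_fraction       : num 1
#>  $ signature_size          : int 47
#>  $ classifier_accuracy     : num 1
#>  $ cluster_purity          : num 1
#>  $ n_coexpressed           : int 3
#>  $ qpcr_wilcoxon_p         : num 1.18e-07
```

Reading the output: from a simulated 600-gene knockdown experiment the
consensus catalog retains 60 lncRNAs (35 down-, 25 up-regulated on
receptor knockdown, echoing the down-dominant planting). Down-regulated
catalog genes sit much closer to planted binding sites than 200
biotype-matched random sets (Wilcoxon p ≈ 1.5e-16); all profiled TSS
regions are called promoter-like (high H3K4me3/H3K4me1 ratio); 47 panel
genes exceed merit 15, and that signature classifies the 55-sample panel
into its four subtypes without error (10-fold cross-validated accuracy
1.0) and clusters it into pure subtype groups (purity 1); the
harmonized two-run qRT-PCR
series separates ER-positive from ER-negative samples
(p ≈ 1.2e-07). Every output file under `demo_out/` carries a provenance
header (version, seed, parameters) and is listed with its MD5 checksum
in `manifest.tsv`; re-running with the same seed reproduces the manifest
bit for bit. A command-line wrapper for the same demo is provided at
`inst/scripts/demo.R`.

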