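# fasterx

Selection analyses for X-linked and autosomal genes on young sex
chromosomes.

## What this package is for

On recently evolved sex chromosomes, many X-linked genes keep a functional
Y-linked gametolog and so are not hemizygous in males. Comparing selective
pressure between such X-linked genes and autosomal genes — and between
hemizygous and non-hemizygous X genes — asks whether elevated X-linked
dN/dS (the "faster-X" pattern) reflects faster adaptation or relaxed
purifying selection driven by the X's smaller effective population size
(N_eX/N_eA = 3/4 under equal sex ratios, visible as π_X/π_A ≈ 0.75 at
neutral sites).

`fasterx` provides the complete analysis layer for a six-species design
with a three-species dioecious (foreground) clade:

* **Codon models** (`fit_model`, `fit_branch_two_ratio`, `lrt`,
  `pairwise_dnds`, `ancestral_reconstruct`): a 61-state dN/dS likelihood
  engine with rate matrices

  `q_ij ∝ π_j · κ^[transition] · ω^[nonsynonymous]` (single-nucleotide
  changes only, mean rate 1/codon site),

  pruning likelihoods in compiled code, and the standard model families —
  M0, two-ratio branch (foreground vs background ω, df = 1), M1a/M2a and
  M7/M8 site models (df = 2), branch-site model A against its fixed-ω null
  (df = 1) — plus marginal ancestral reconstruction.
* **Gene-tree conflict filter** (`fourfold_columns`, `build_supermatrix`,
  `gtr_gamma_site_lnl`, `sh_test`, `bh_fdr`, `filter_gene_trees`):
  four-fold-degenerate-site supermatrices (columns with >50% missing data
  dropped), per-site GTR+Γ log-likelihoods on fixed topologies, the
  two-topology Shimodaira–Hasegawa test with RELL resampling, and BH-FDR
  keep/drop decisions at 5%.
* **Codon usage** (`enc`, `fop`, `count_pu_changes`, `fisher_2x2`):
  Wright's effective number of codons (ENC ∈ [20, 61]), frequency of
  optimal codons, and lineage-specific preferred⇔unpreferred synonymous
  change counts against reconstructed ancestors with Fisher exact
  comparisons.
* **Silent-site diversity** (`read_diploid_fasta`, `silent_site_mask`,
  `nucleotide_diversity`, `tajimas_d`, `diversity_summary`): π and
  Tajima's D per gene from diploid FASTA with IUPAC-coded heterozygotes,
  at four-fold-degenerate third positions of the reference.
* **Synthetic data** (`simulate_codon_alignment`, `simulate_gene_set`,
  `simulate_population`, `simulate_expression`): every input the pipeline
  needs, including a coalescent for polymorphism in which X/autosome
  ploidy enters only through copy counts and transmission rules, so the
  3/4 diversity expectation is an emergent property.
* **Comparisons** (`classify_genes`, `female_bias_flag`, `chi2_2x2`,
  `distribution_tests`, `run_scan`): per-gene LRT scans with count tables
  at raw 5%/1% significance stratified as X (all) / X hemizygous /
  X female-biased / autosomal, Δω = ω_fore/ω_back reports, and the
  class-wise statistical tests.

## A worked example

```r
library(fasterx)

tree <- silene_species_tree()
cfg <- simulation_config(n_autosomal = 6, n_x_nonhemizygous = 3,
                         n_x_hemizygous = 1, n_par = 0, L = 200, seed = 1)
meta <- simulate_gene_set(cfg)
aligns <- attr(meta, "alignments"); names(aligns) <- meta$gene

scan <- run_scan(aligns, tree, meta, dioecious_taxa(),
                 models = "branch", seed = 1)
subset(scan$summary, stratum %in% c("x_all", "autosomal"))
#>     test   stratum n_genes sig_05 pct_05 sig_01 pct_01
#> 1 branch     x_all       4      0      0      0      0
#> 4 branch autosomal       6      0      0      0      0

head(scan$delta_omega[, c("gene", "stratum", "delta_omega")], 3)
#>       gene   stratum delta_omega
#> 1 gene0001 autosomal   0.3025093
#> 2 gene0002 autosomal   0.9557333
#> 3 gene0003 autosomal   0.7650469
```

The summary table counts genes whose two-ratio/one-ratio LRT is significant
at raw p < 0.05 and p < 0.01 per stratum (no multiple-testing correction,
matching the published table layout); at this toy size (10 genes of 200
codons) none of the per-gene shifts reaches significance, as expected.
`delta_omega` is each gene's fitted foreground/background dN/dS ratio —
values above 1 mean the gene's protein evolution sped up after the
transition to dioecy. A PAR gene, had we simulated one, would be excluded
from all X/autosome contrasts and logged.

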