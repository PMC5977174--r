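---
title: "Comparing selective pressures on X-linked and autosomal genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing selective pressures on X-linked and autosomal genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasterx)
```

## The scientific problem

On young sex chromosomes many X-linked genes still have functional Y-linked
gametologs, so they are not hemizygous in males and recessive mutations can
hide in heterozygotes just as on autosomes. Whether such genes show the
classic "faster-X" pattern — elevated dN/dS relative to autosomes — and
whether that pattern is driven by faster adaptation or by relaxed purifying
selection (the X has ~3/4 the autosomal effective population size under
equal sex ratios) are questions this package is built to ask, on a
six-species design: a dioecious clade of three species (the foreground, with
shared sex chromosomes) and three non-dioecious relatives (the background).

`fasterx` implements the full analysis layer: codon substitution models and
their likelihood ratio tests, a gene-tree conflict filter, codon usage
statistics, silent-site diversity, and a synthetic data generator that
reproduces the statistical structure of such a study so the whole pipeline
can be validated without any external data.

## The codon model engine

The core is a 61-state codon substitution model. The instantaneous rate
from codon $i$ to codon $j$ is

$$ q_{ij} = \begin{cases}
0 & \text{more than one nucleotide change} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\omega \kappa \pi_j & \text{nonsynonymous transition,}
\end{cases} $$

scaled to one expected substitution per codon site, with $\omega = dN/dS$
the selection parameter. Likelihoods come from Felsenstein pruning over the
tree (implemented in compiled code; transition matrices through the
symmetric eigendecomposition that reversibility affords), with missing
codons marginalised over all 61 states. The model families are the standard
set:

* **M0** — one $\omega$ everywhere; also used to estimate branch lengths.
* **Two-ratio branch model** — separate $\omega$ for the foreground
  (dioecious) clade and the background; LRT against M0 with df = 1. The
  foreground is every branch whose descendant tips all belong to the
  declared clade, including its stem.
* **M1a/M2a and M7/M8 site models** — among-site $\omega$ variation;
  M2a/M8 add a positive-selection class; LRTs with df = 2. The M7/M8 beta
  law is discretised into 10 equal-probability categories (category means
  via the incomplete beta function); the count is configurable.
* **Branch-site model A** and its null with the foreground
  $\omega_2$ fixed at 1; LRT with df = 1. Class proportions follow the
  standard parameterisation $p_{2a} = (1-p_0-p_1)\,p_0/(p_0+p_1)$,
  $p_{2b} = (1-p_0-p_1)\,p_1/(p_0+p_1)$.

A note on degrees of freedom: the two-ratio model adds exactly one free
parameter to M0, so its LRT uses df = 1 (reports of df = 2 for this
comparison sometimes appear in summary tables; the parameter count is
decisive).

### Parameters, bounds and optimisation

All fits are bounded quasi-Newton (BFGS on transformed parameters):
$\kappa \in [0.05, 50]$, $\omega \in [10^{-4}, 999]$ (purifying-class
$\omega_0 \in [10^{-4}, 1]$, positive-class $\omega_2 \in [1, 999]$), beta
shapes in $[0.005, 99]$, proportions through stick-breaking logits, branch
lengths and the branch scale on the log scale. Multi-start with seeded
jitter (3 restarts by default); alternative models are started from their
null's estimates with $\omega_2$ just above 1, which keeps fitted
likelihoods ordered across nested pairs to within optimiser tolerance.
Convergence and boundary conditions (e.g. an invariant alignment collapsing
the branch scale to its lower bound) are reported on every fit, never
silently dropped.

Branch lengths are estimated once per gene under M0 (full per-branch
optimisation, `branch_lengths = "full"`); every other model then
re-optimises a single multiplicative scale on that tree. This mirrors
common practice and keeps per-gene runtimes in seconds. Full per-branch
re-optimisation is available for any family via the same flag. When an
input tree already carries trusted branch lengths (e.g. simulation truth),
the scale-only default applies them directly.

Codon equilibrium frequencies default to F3x4 (position-specific nucleotide
frequencies with a half-count prior against absent bases); F1x4 and equal
frequencies are options. Stop codons in input alignments are an error
naming the taxon and codon site, because surfacing data errors beats silent
masking; `mask_stops = TRUE` converts them to missing. A codon containing
any gap or ambiguous base is treated as missing as a whole.

Marginal ancestral reconstruction runs an inside–outside pass at the MLEs,
reports the argmax codon per internal node and site with its posterior, and
breaks posterior ties toward the lowest codon index, flagging the tie.

## The gene-tree conflict filter

Four-fold-degenerate third positions are extracted under a conservative
all-taxa rule: a codon column contributes only if every non-missing codon
in it belongs to a four-fold family (a per-reference-taxon mode exists
behind a flag). The supermatrix concatenates these columns and drops those
with strictly more than 50% missing data. Per-site log-likelihoods under
GTR+$\Gamma$ (4 categories) on a fixed topology come from the phangorn
likelihood engine; the Shimodaira–Hasegawa test is implemented in its
two-topology special case with RELL resampling (1000 replicates by
default, centred per topology, one-sided for rejection of the species
tree), and Benjamini–Hochberg FDR at 5% decides which genes are kept. Gene
trees may be supplied, or are computed internally by neighbour joining —
full ML tree search is deliberately out of scope; the topology is an input.

## Codon usage

ENC uses Wright's small-sample homozygosity
$\hat F = (n\sum \hat p^2 - 1)/(n-1)$ per amino acid, averaged within the
2-, 3-, 4- and 6-fold degeneracy classes (six-fold families are their own
class), and $ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
clamped to $[20, 61]$. Amino acids observed fewer than twice, or with
$\hat F \le 0$, do not enter their class average; a class with no usable
amino acid is imputed from the nearest observed classes by degeneracy (the
3-fold class, when absent, is the mean of the 2- and 4-fold averages).
Genes below 100 codons are flagged rather than summarised. FOP is the
fraction of codon occurrences that are optimal among occurrences of amino
acids that have an optimal codon; the optimal-codon list is an input file.
The list shipped under `inst/extdata/` is a synthetic 21-codon placeholder
with the size and shape of a real species-specific table, for tests and
examples only.

Preferred/unpreferred change counting compares a reconstructed ancestor
with a modern sequence codon by codon and counts only synonymous,
single-nucleotide changes (P→U and U→P); codons differing at two or more
positions have an ambiguous substitution path and are tallied as excluded
rather than path-averaged.

## Silent-site diversity

Diploid consensus sequences with IUPAC-coded heterozygotes are expanded to
two allele copies per individual per site ("silent sites" are resolved
strictly as four-fold-degenerate third positions of the reference CDS; an
all-synonymous-positions mode exists behind a flag). Per usable site (at
least 4 non-missing allele copies), diversity is the unbiased pairwise
heterozygosity $2\sum_{i<j} c_i c_j / (k(k-1))$ — note this estimator is
deliberately the unbiased one, so duplicating every individual rescales it
by an exact, known factor rather than leaving it fixed. Tajima's D uses
the standard constants at the modal allele count; genes whose usable allele
count varies by more than 2 across sites are flagged, and D is reported as
undefined (never as 0) when there are no segregating sites. Per-gene and
pooled summaries are both available, since either convention may be wanted
when averaging across genes.

## The synthetic study design

The generator produces every input the pipeline needs, with the statistical
structure the analysis assumes:

* **Codon alignments** on the six-taxon tree, evolved branch by branch from
  the stationary distribution with per-site rate classes; foreground
  branches can use a distinct $\omega$. The default species tree uses two
  branch-length values (tips 0.05, internals 0.025 substitutions/codon),
  a stylised shallow divergence in the range expected for a genus-level
  comparison; repeated lengths also let transition matrices be shared
  across branches.
* **Gene classes** default to 45 autosomal, 8 non-hemizygous X, 2
  hemizygous X and 1 PAR gene — ~18% X-linked with 80% of X genes
  non-hemizygous, the proportions of the motivating design. Foreground
  $\omega$ multipliers default to 2 for non-hemizygous X, 0.5 for
  hemizygous X and 1 elsewhere (the "shift up / shift down" pattern the
  branch analysis is meant to detect), applied to a per-gene background
  $\omega_0$ drawn log-normally around 0.15. Female-bias labels are drawn
  at 41% on the X versus 15% on autosomes, reflecting X enrichment of
  female-biased expression. Each gene gets a child seed by stable hashing
  of its id, so truth is order-independent; truth columns are written next
  to the data and no analysis stage reads them.
* **Polymorphism panels** come from a neutral coalescent in which ploidy
  enters only through copy counts and transmission rules: autosomal copies
  pick either parent; an X copy in a male comes from his mother, in a
  female from either parent. The stationary holder-sex distribution and the
  per-generation pair-coalescence probability are solved from those rules,
  never hard-coded, so the 3/4 expectation for $\pi_X/\pi_A$ at equal sex
  numbers is an emergent check — with strongly female-biased sex ratios the
  same bookkeeping sends the ratio toward 9/8. Infinite-sites mutations are
  placed on the silent mask only, with the per-generation rate set to
  $\theta / (2 C_A)$ ($C_A$ the autosomal copy number) in both modes —
  equal mutation rates on X and autosomes, with $\pi_A \approx \theta$ at
  equal sex numbers. Sampled individuals are females (two X copies), as in
  the motivating design.
* **Expression matrices** are log-normal over 23 males and 34 females by
  default, with a female multiplier for the biased fraction.

## Validation design and problem sizes

The test suite validates against independent oracles (exhaustive
enumeration over ancestral states, a refining grid search, hand-evaluated
constants, hypergeometric enumeration) and then runs the pipeline-scale
checks at sizes chosen for a desk machine:

* the ploidy ratio uses 1000 replicate loci per mode of 1500 codons (~780
  silent sites); the X and autosomal locus of a pair share a child seed, so
  genealogical Monte-Carlo noise cancels in the ratio (common random
  numbers) and the remaining mutational-sampling error is ~1%;
* parameter recovery uses 20 replicates of 1000 codons. The one-ratio and
  two-ratio experiments run on the default tree; the M2a experiment uses a
  deeper tree (tips 0.15, internals 0.08) and a strong-selection regime
  (60% of sites at $\omega_0 = 0.1$, 25% neutral, 15% at $\omega_2 = 5$),
  because at shallow divergence the positive-selection class is not
  identifiable (see limitations) and a recovery experiment is only
  informative where the information exists. Recovery is asserted on each
  family's principal parameter: the M0 $\omega$, the two branch-model
  ratios, and M2a's purifying-class $\omega_0$ — the quantity the
  downstream X/autosome comparisons consume;
* LRT calibration uses 100 null replicates per family at 120 codons; the
  boundary nulls (M1a/M2a, model A) are expected to be conservative, and
  the check asserts the empirical 5% rejection stays at or below 10%
  rather than pretending the boundary chi-squared is exact;
* neutral popgen checks use 200 loci of 900 codons for the Tajima's D
  centring and the linear scaling of $\pi$ with $\theta$.

What passing these checks does **not** show about real data: the generator
has no recombination within genes, no demography, no linked selection, no
codon-frequency bias (alignments are simulated at equal codon
frequencies), and no alignment error; real transcriptome-derived
alignments violate all of these to some degree.

## Known limitations

* $\omega_2$ (the positive-selection $\omega$ in M2a/M8/model A) is weakly
  identified at desk scale: once the class is near saturation the
  likelihood is almost flat in $\omega_2$, and on shallow trees the MLE can
  absorb the class into the neutral one entirely. The LRTs remain
  calibrated, but point estimates of $\omega_2$ should be treated with
  caution — this matches long-standing experience with these models.
* The SH-test is implemented only for the two-topology case (gene tree vs
  species tree), with standard centring; its tail convention and replicate
  count are documented assumptions, not inferred from any external
  default.
* No Bayes Empirical Bayes site identification; the "proportion of sites
  switched to positive selection" reported by the scan is the MLE class
  proportion $p_{2a} + p_{2b}$.
* Pearson's 2×2 test is used without continuity correction by default
  (this reproduces the published worked example); Yates' correction is a
  flag. "Student's test" defaults to the Welch unequal-variance form, with
  the classic equal-variance version behind a flag, since equal variances
  are rarely defensible for these comparisons.

## A worked micro-example

```{r example, eval = FALSE}
tree <- silene_species_tree()
cfg <- simulation_config(n_autosomal = 6, n_x_nonhemizygous = 3,
                         n_x_hemizygous = 1, n_par = 0, L = 200, seed = 1)
meta <- simulate_gene_set(cfg)
aligns <- attr(meta, "alignments")
names(aligns) <- meta$gene
scan <- run_scan(aligns, tree, meta, dioecious_taxa(),
                 models = c("branch", "m1m2"), seed = 1)
scan$summary      # LRT counts at 5% and 1% per stratum
scan$delta_omega  # foreground/background omega per gene
```

The same functions scale to the full design; `run_scan()` writes
`fits.tsv`, `lrt_summary.tsv`, `lrt_counts.tsv`, `delta_omega.tsv` and
`exclusions.tsv` when given an output directory, and a failing gene lands
in the exclusions table without aborting the scan.
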