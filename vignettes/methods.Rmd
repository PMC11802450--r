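---
title: "Mapping polygenic GWAS signal onto cell types: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping polygenic GWAS signal onto cell types: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celltypescan)
```

# The question the package answers

A polygenic phenotype spreads its heritability over thousands of loci, so no
single association points at a mechanism. If, however, a particular cell
type preferentially *uses* the genes that carry association signal, the
aggregate of weak per-gene signals becomes a testable statement about that
cell type. `celltypescan` implements the full chain of that argument:

1. **Specificity scoring** — summarise a cluster-labeled single-cell (or
   single-nucleus) count matrix into, per gene and cell type, the fraction
   of the gene's expression found in that cell type.
2. **Gene-level association** — collapse GWAS summary statistics into one
   LD-adjusted p-value per gene.
3. **Gene-property regression** — regress gene association z-scores on each
   cell type's specificity column, with covariates, under LD-correlated
   errors; one-sided test, Bonferroni control across cell types.
4. **Conditional selection** — prune the significant cell types to a set
   whose associations are relatively independent of one another.
5. **Robustness machinery** — permutation nulls, cell downsampling,
   power-versus-sample-size curves, and export of genome annotations built
   from specifically expressed genes.

Every stage is also exercised end-to-end on synthetic data with planted
ground truth, which is what the package's test suite does.

# Specificity

Counts are transformed by $\ln(1+x)$ — the usual variance-compressing
transform for overdispersed count data — *before* averaging within
clusters, and the mean transformed expression $m_{gc}$ is turned into the
specificity

$$ s_{gc} = \frac{m_{gc}}{\sum_{c'} m_{gc'}}, $$

so each gene's row sums to one and a gene expressed evenly across $C$ cell
types scores $1/C$ everywhere. Averaging transformed values (not
transforming the average) matters: the two orders differ for skewed count
distributions, and the mean-of-transform is the one implemented.

Genes are filtered before scoring: only protein-coding genes are kept;
genes without annotation or without a unique external-id mapping, genes
with non-unique symbols, genes overlapping the MHC interval
(chr6:25,000,000–34,000,000 by default; the interval is configurable since
it is genome-build dependent), and unexpressed genes are removed. "Any
overlap" with the MHC interval removes a gene, coordinates being 1-based
inclusive. Each removed gene is counted under the first rule that fires,
so the removal counts always reconcile with input minus output. The MHC is
excluded because its extreme long-range LD makes gene-level attribution in
that region unreliable.

No per-cell depth normalisation is applied before the transform by
default. Whether the depth should be normalised first is genuinely open
for this scoring scheme; the package keeps the un-normalised default and
treats normalised input as the caller's choice, since cluster means over
many cells largely average library-size variation out.

`downsample_clusters()` caps every cluster at a maximum cell count (the
experiments in the package use the 3,400 / 340 / 34 ladder), sampling
uniformly without replacement under a seed, to probe how scoring degrades
when cell types are represented by few cells.

# Gene-level association

SNPs map to a gene when they fall within 35 kb upstream to 10 kb
downstream of the gene body. Windows are strand-aware — upstream of a
minus-strand gene lies to its right — inclusive at both ends, and clipped
at position 1; genes without strand information are treated as plus-strand.
A SNP may belong to several overlapping genes.

Per gene, SNP p-values become z-statistics via $z = \Phi^{-1}(1-p)$
(clamped to $[10^{-300}, 1-10^{-16}]$ so the transform stays finite), and
the gene statistic is $T = \sum_i z_i^2$. Under the null, with SNP
correlation matrix $R$ estimated from a reference panel, $T$ is distributed
as $\sum_j \lambda_j \chi^2_1$ where $\lambda_j$ are the eigenvalues of
$R$. Eigenvalues are clipped at zero and components below $10^{-4}$ of the
leading eigenvalue are dropped (their count is kept as an effective-test
diagnostic).

The mixture tail probability is computed by Imhof's numeric inversion of
the characteristic function. Numerically, a finite upper integration limit
with a generous subdivision budget proved far more accurate than R's
infinite-interval transformation; the limit grows as the number of mixture
components shrinks (the integrand decays like $u^{-(k/2+1)}$). Equal
weights short-circuit to the exact $\chi^2_k$ survival function, and the
far tail (or a failed integration) falls back to the Kuonen saddlepoint
approximation, recorded in the result's `method` attribute. P-values are
floored at $10^{-300}$ so the probit of the gene p-value stays finite.

Covariates carried per gene: SNP count, gene density (retained eigenvalue
count over SNP count — an effective-test ratio), inverse mean minor-allele
count, mean GWAS sample size, and natural logs of each. With a constant
GWAS sample size the latter two are constant and are dropped automatically
at design time, since they are collinear with the intercept. The gene
density covariate has no authoritative closed form to copy; it is defined
as above and validated behaviourally through the null-calibration tests
rather than numerically.

## Correlation between gene statistics

Adjacent genes share or border the same LD, so their statistics correlate.
For jointly normal z-scores the null covariance of two sum-of-squares
statistics is exactly $2\sum_{i\in g, j\in h} r_{ij}^2$, and the variance
is $2\lVert R_g\rVert_F^2$, giving

$$ \mathrm{corr}(T_g, T_h) =
   \frac{\sum_{i\in g,\, j\in h} r_{ij}^2}
        {\sqrt{\lVert R_g\rVert_F^2\,\lVert R_h\rVert_F^2}}. $$

This reduces to the mean-square cross-LD over $\sqrt{n_g n_h}$ when
within-gene SNPs are independent, and equals 1 exactly for duplicated
genes whatever their internal LD — the property the simpler normalisation
violates. Pairs farther than 5 Mb apart (or on different chromosomes) are
set to zero, keeping the matrix sparse and banded; 5 Mb is comfortably
beyond the LD range the block generator (or a human panel) produces. If
clipping ever leaves the matrix indefinite it is ridge-repaired (add
$(|\lambda_{\min}|+10^{-8})I$, rescale to unit diagonal).

# Gene-property regression

For each cell type $c$ separately,

$$ Z = \beta_0 + P_c \beta_1 + C\beta_2 + \varepsilon,
   \qquad \varepsilon \sim \mathcal{N}(0, \sigma^2 V), $$

with $Z$ the gene z-scores $\Phi^{-1}(1-P_g)$, $P_c$ the cell type's
specificity column, $C$ the covariates, and $V$ the gene-gene correlation
above. The system is whitened by the Cholesky factor of $V$ and solved by
QR least squares; the test of interest is one-sided on $\beta_1 > 0$ (the
premise is that trait-associated cell types *over*-use trait-associated
genes; an under-use signal is not the hypothesis), with
$t = \hat\beta_1/\mathrm{SE}$ on $G - (k+2)$ degrees of freedom and
Bonferroni control at $\alpha / C$ across the $C$ cell types.

Outliers are damped before fitting: gene z-scores are clamped
asymmetrically at $[\mu - 3\sigma,\ \mu + 6\sigma]$ (association signal is
expected on the high side, so more room is left there), specificity
columns symmetrically at $\mu \pm 5\sigma$. The clamp statistics are
computed once on the raw vector, without iteration. A consequence worth
stating: when a clamp actually binds, re-truncating the output would clamp
further (the sd shrinks), so "truncation" here means exactly one pass.

The gene universe is the inner join of GWAS-side and expression-side
genes; nothing is imputed. Exact collinearity between a specificity column
and the covariates is an error naming the offending column, not a silent
drop.

# Conditional analysis and forward-stepwise selection

For two cell types $c_1, c_2$ the conditional model adds both specificity
columns:

$$ Z = \beta_0' + P_{c_1}\beta_1' + P_{c_2}\beta_2' + C\beta_3'
   + \varepsilon. $$

Writing $P_{c_1,c_2}$ for the conditional p-value of $c_1$ given $c_2$ and
$P_{c_1}$ for its marginal p-value, the *proportional significance*

$$ \mathrm{PS}_{c_1,c_2} = \frac{-\log P_{c_1,c_2}}{-\log P_{c_1}} $$

measures how much of $c_1$'s significance survives conditioning (the ratio
is log-base invariant). Selection proceeds forward from the most
marginally significant Bonferroni-significant cell type; each next
candidate $c$ (ascending marginal p, ties broken by cell-type id) is
compared against every member $s$ of the selected set $S$ and added only
if, for all $s$:

* **Rule 1** — $\mathrm{PS}_{c,s} \ge 0.8$ and $\mathrm{PS}_{s,c} \ge 0.8$:
  the two associations are independent; or
* **Rule 2** — both PS values lie in $[0.5, 0.8)$ and the candidate's
  *conditional* p-value given $s$ is at most $0.05$: partially overlapping
  but mostly independent signal.

The bound in rule 2 is read as the conditional p-value: every candidate is
Bonferroni-significant marginally, so a marginal reading could never bind
and the rule would be vacuous. The marginal reading remains available as a
switch (`rule2_p = "marginal"`) for sensitivity analysis.

A **reversal rule** covers the rare case where an earlier-selected member
is explained by the candidate and not vice versa
($\mathrm{PS}_{s,c} < 0.2 \le \mathrm{PS}_{c,s}$): the pair's selection
order is reversed — the candidate takes the member's place and the member
is marked explained. Candidates failing both rules against any member are
excluded immediately and not revisited, the usual forward-selection
semantics; PS values in $[0.2, 0.5)$ therefore exclude. Near-duplicate
specificity columns (absolute correlation above 0.9999) cannot be
distinguished by the conditional model and are flagged as such rather than
fitted. Every pairwise comparison, with both conditional p-values, both PS
values, and the rule that fired, lands in an audit table.

# Robustness machinery

**Permutation null.** Gene labels of the gene-analysis table are permuted
— each gene's z-score travels with its covariates, because they are
properties of the GWAS-side record — which preserves both marginals while
breaking the gene-to-specificity link. One shuffle is shared by the whole
cell-type scan within a permutation, then the scan is rerun. Expected
chance counts are analytic: $n_{\mathrm{perm}} \times C \times \alpha$. At
the reference design of 1,000 permutations over 461 cell types that is
23,050 expected at $\alpha = 0.05$ and 50 at the Bonferroni threshold
$0.05/461 = 0.0001$.

One subtlety is worth knowing: permuting gene labels destroys the
gene-gene correlation that the scan's error model assumes, so the
permuted reruns are fitted under an intentionally mis-specified $V$ —
that is what the design tests. When $V$ carries sizable entries (few
genes, dense LD) this mis-specification visibly perturbs the empirical
type-I rate; with genes in linkage equilibrium ($V \approx I$) the
permutation null is calibrated essentially exactly, and the package's
calibration tests cover both regimes at their appropriate scales.

**Effective sample size.** For case-control GWAS,
$n_{\mathrm{eff}} = 4 / (1/\mathrm{cases} + 1/\mathrm{controls})$ — the
balanced-design equivalent, equal to the total when balanced.

**Cell-count association.** `significance_vs_cellcount()` reports the
Pearson correlation (with two-sided p) between $-\log_{10} P$ of the scan
and the number of cells per cell type — a check that significance is not
an artifact of cluster size; it is reported, never thresholded.

**SEG annotations.** Per cell type, the top decile of genes by specificity
($\lceil 0.10\,G \rceil$ genes, ties broken by gene id) is expanded by
100-kb flanks, clipped at position 1, merged where overlapping
(IRanges), and exportable as 0-based half-open BED — the annotation input
format of stratified-heritability tools. Running such tools is out of
scope.

**Power curves.** `power_curve_harness()` reruns the full synthetic
pipeline over an increasing grid of GWAS sample sizes with the planted
truth structure held fixed, counting significant and selected cell types —
the desk-scale analogue of rerunning the analysis on successive GWAS
releases, where detection grows with power and then plateaus once the
planted signal is saturated.

# The synthetic-data generator

The generator produces every input the pipeline consumes, with planted
ground truth, under one root seed (per-stage streams are derived from it,
so each stage is independently reproducible).

**Reference panel.** Haplotypes follow a Gaussian copula: within each LD
block latent variables are equicorrelated, thresholded at the
allele-frequency quantile to alleles; genotypes are the sum of two
haplotypes, giving Hardy-Weinberg `{0,1,2}` counts. Thresholding
attenuates the latent correlation, so the latent value is inflated to
$\sin(\tfrac{\pi}{2} r)$ — exact at MAF 0.5, mildly short below it; the
realized genotype LD, not the latent value, is what every downstream stage
consumes, so the attenuation does not bias the analysis. MAFs are uniform
on $[0.1, 0.5]$; positions are evenly spaced and strictly increasing.
Blocks are independent. This is deliberately simpler than coalescent
simulation: the analysis consumes only block-level LD spectra, not
recombination maps.

**Expression.** Cluster mean profiles live on a binary tree: a child's
log-mean profile is its parent's plus Gaussian noise scaled by
$(1-\rho_{\mathrm{tree}})$, so sibling clusters are correlated — exactly
the structure the conditional stage must disentangle. Counts are negative
binomial with dispersion 0.5 (size 2) around cluster means, with lognormal
($\sigma = 0.3$) per-cell library factors, reproducing the overdispersion
and zero inflation that motivate the $\ln(1+x)$ transform. Causal genes'
means are multiplied by the enrichment effect inside causal clusters. A
variant of the truth shares one causal gene set between two clusters, the
construction behind the shared-signal selection experiments.

**GWAS.** SNP z-scores are drawn block-wise from a multivariate normal
whose covariance is the *realized* panel genotype correlation, so the
LD adjustment downstream — which estimates LD from the same panel — sees a
self-consistent null; p-values are two-sided normal tails. Null gene-level
p-values are then uniform by construction. The planted per-gene
noncentrality is `gwas_effect_scale * gwas_n` — linear in sample size, as
for a fixed per-SNP effect-size variance — and two generator-semantics
choices make that number mean what it says:

* the signal is planted along the *leading LD eigenvector* of the gene's
  member SNPs (a causal signal spread through LD), so the noncentrality
  lands on the mixture component that dominates the null tail; splitting
  it equally across correlated SNPs would silently deliver much less
  effective signal;
* the analysis folds z-scores through the two-sided p-value
  ($\tilde z = \Phi^{-1}(1 - 2\Phi(-|z|))$), which attenuates a planted
  mean, so each coordinate is inflated by numerically inverting
  $\mathbb{E}[\tilde z(X)^2] = 1 + \delta$, $X \sim \mathcal{N}(\mu, 1)$
  (a one-time monotone grid inversion).

**What the generator does not emulate.** Realistic human LD maps and
recombination hotspots, ancestry structure, sex chromosomes, imputation
quality, cell-type proportions varying across donors, batch effects, and
ambient RNA. Passing tests on this generator therefore demonstrate that
the *statistical machinery* is correct and calibrated under the model's
assumptions — not that any particular real dataset satisfies those
assumptions.

# Problem sizes and numerical choices

The package's own experiments run at desk scale, chosen so the full suite
exercises every stage end-to-end: the default study is 500 genes on 5
chromosomes, 5,000 SNPs in 5-SNP blocks (latent $r = 0.8$), 1,000 panel
individuals, 20 clusters of 50 cells, one causal cluster with 10-fold
enrichment and per-gene noncentrality ≈ 30 at the default GWAS sample
size. Recovery and calibration experiments use 200-gene / 2,000-SNP
variants with 20 replicates; the permutation calibration uses 100
permutations over 20 cell types (2,000 test instances). At reference
scale (461 cell types, 1,000 permutations) the expected-count arithmetic
is unchanged — those numbers appear in the acceptance outputs directly.

Numerical details fixed by design: Imhof integration at absolute tolerance
$10^{-13}$ with component-dependent truncation; p-value floor
$10^{-300}$; eigenvalue clipping at 0 and pruning at $10^{-4}$ of the
maximum; Cholesky whitening (never explicit inversion) for GLS; ties in
marginal p broken by cell-type id; `ceil` for the SEG top-decile count.
Degenerate inputs error loudly: zero-variance truncation inputs warn and
pass through, all-zero gene rows are an error at specificity time (they
must have been filtered), empty gene intersections and rank-deficient
designs are errors that name the problem.

# Known limitations

* The gene-gene correlation transfers the *statistic*-scale correlation to
  the z-score scale; this is the standard approximation and is validated
  by calibration, not exactness.
* The mixture null for the folded (two-sided) z-scores uses the genotype
  correlation eigenvalues; the fold slightly perturbs the joint law of the
  squared statistics. The permutation and null-uniformity tests bound the
  practical effect.
* Forward selection is pairwise-conditional only; a cell type masked only
  by a *combination* of selected types is not modelled.
* The reversal rule replaces the explained member immediately; the
  displaced member is not re-queued for later reconsideration.
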