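---
title: "Methods: mapping mutant-histone occupancy onto transcriptional output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping mutant-histone occupancy onto transcriptional output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncohist)
```

# The scientific problem

A cancer-associated point mutation in a core histone (an "oncohistone",
here modeled on an H2B glycine-to-aspartate substitution) can loosen the
contact between nucleosomal DNA and the histone octamer and thereby alter
transcription. To show that such a mutant histone acts *directly* on its
target genes, three independent observations have to be tied together on a
per-gene basis:

1. **Expression changes** — differential mRNA abundance between mutant and
   wild-type clones (RNA-seq).
2. **Transcription changes** — differential engaged-polymerase density
   (PRO-seq), separating transcriptional from post-transcriptional effects.
3. **Occupancy of the mutant histone itself** — CUT&RUN coverage of the
   FLAG-tagged mutant histone, normalized against a CUT&RUN track for total
   H2A as an internal control.

`oncohist` implements this integration as a reusable, testable pipeline:
differential calls for both count assays, mutant-specific occupancy peaks,
a shuffled-null test of where those peaks fall in the genome, per-gene
*locus-wide* occupancy scores, and a GSEA running-sum permutation test
asking whether concordantly upregulated genes are the ones the mutant
histone occupies. A synthetic-data generator with planted ground truth
stands in for sequencing data, so every stage is exercised end-to-end with
no external downloads.

# Models and procedures

## Differential counts (RNA-seq and PRO-seq)

Both assays are treated identically at the count-matrix level (gene x
sample integer counts, two genotype groups).

* **Normalization** is median-of-ratios: for sample $s$,
  $f_s = \mathrm{median}_g \, c_{gs} / (\prod_t c_{gt})^{1/n}$ over genes
  positive in every sample. This is the standard size-factor estimator for
  RNA-seq count data; identical libraries get identical factors and the
  factors of a normalized matrix are all 1 (a fixed point the tests
  assert).
* **Dispersion** is estimated per gene by method of moments on normalized
  counts, $\alpha_g = (\mathrm{var}_g - \mu_g)/\mu_g^2$, with the variance
  pooled within genotype groups and floored at $10^{-8}$. With only two
  samples per group the per-gene estimate has two degrees of freedom and is
  individually worthless: plugged into a Wald test it inflates the type-I
  error to ~0.15 at a nominal 0.05. The default therefore averages the raw
  moment estimates across genes within deciles of the gene mean before
  flooring. This is the same variance-pooling idea used for occupancy bins
  (below) and restores calibration (empirically 0.04-0.07 across dispersion
  regimes, including the Poisson limit). The unpooled estimator remains
  available (`pool = "none"`).
* **Testing** is a Wald test on the log2 ratio of pseudocounted normalized
  group means (pseudocount 0.5, which stabilizes genes with zeros):
  $\widehat{\mathrm{lfc}} = \log_2 \frac{\bar{x}_M + 0.5}{\bar{x}_W + 0.5}$,
  with the delta-method standard error
  $\mathrm{se}^2 = \sum_{k \in \{W,M\}}
  \frac{\bar{x}_k + \alpha \bar{x}_k^2}{n_k (\bar{x}_k + 0.5)^2 \ln^2 2}$
  and a normal reference. Swapping group labels flips the sign of the fold
  change and leaves p unchanged.
* **Calling**: Benjamini-Hochberg adjustment across genes; a gene is "up"
  when $q < \alpha$ and $\mathrm{lfc} \ge$ `min_abs_log2fc`, "down"
  symmetrically. Defaults $\alpha = 0.05$, `min_abs_log2fc = 1` — the
  thresholds are conventions, configurable, and the exact numbers of genes
  called on any particular dataset are dataset properties, not contracts of
  the method.

Deliberate non-goals: dispersion shrinkage toward a fitted mean-dispersion
trend, GLM covariates, exact tests, and independent filtering. The
decile-pooled moments estimator is the minimal stabilization that makes a
2-vs-2 Wald test honest.

## Occupancy mapping (CUT&RUN with an internal control)

Coverage is processed on a fixed bin grid (default 100 bp — fine enough to
resolve sub-gene structure, coarse enough that a 2-vs-2 comparison has
estimable noise; the last bin of a chromosome is truncated, never dropped).

* **Internal-control normalization.** Per sample, both tracks are scaled to
  counts per million of their own totals, and the per-bin signal is
  $r = \log_2 \frac{\mathrm{cpm}_{FLAG} + pc}{\mathrm{cpm}_{H2A} + pc}$
  with the pseudocount `pc` (default 0.5) expressed in CPM units. Because
  the pseudocount lives on the depth-normalized scale, multiplying a
  sample's FLAG and H2A tracks by any common constant leaves every $r$
  value exactly unchanged — sequencing depth cannot masquerade as
  occupancy. (A pseudocount in raw-count units would break this exact
  invariance, which is why the CPM parameterization was chosen.) Equal
  signal at matched depth gives $r = 0$.
* **Differential windows.** Per bin,
  $\Delta r = \overline{r}_{MUT} - \overline{r}_{WT}$. The within-group
  variance of a single bin over 2+2 samples is hopeless, so pooled
  within-group variances are averaged across all bins in the same decile of
  mean raw coverage, and $z = \Delta r / \sqrt{s^2_{decile}(1/n_M + 1/n_W)}$
  is referred to the normal distribution, BH-adjusted across bins. With the
  many thousands of bins in a decile the pooled variance is effectively
  known, which is what justifies the normal reference.
* **Peak assembly.** Significant bins ($q < 0.05$) separated by at most
  `max_gap` (default 1) non-significant bins are merged; runs with fewer
  than `min_bins` (default 2) significant members are dropped. Peak
  $\Delta r$ is the width-weighted mean over member bins; peak p is the
  Fisher combination of member-bin p-values; q is BH across peaks. Peaks
  with positive $\Delta r$ and $q < \alpha$ are the mutant-specific
  ("G53D-specific") set — only mutant-elevated occupancy counts, matching
  how such peaks are used downstream.

One systematic effect of pure CPM scaling is worth knowing: when the mutant
samples carry strong planted (or real) enrichment, those regions consume a
share of the FLAG library, so the background $r$ of mutant samples sits
slightly *below* the wild-type background (about $-0.1$ log2 units at the
default simulation settings). The positive-direction filter and the
moderated test absorb this at the default effect sizes; a spike-in style
correction is out of scope.

## Peak annotation and the shuffled null

Peaks are classified as **promoter** (overlapping a strand-aware window
$[\mathrm{TSS} - 1000, \mathrm{TSS} + 1000)$), else **gene body**, else
**intergenic** — precedence makes the categories mutually exclusive, like
the pie-chart categories such figures report. The promoter extent is a
convention (configurable); genome annotations do not define "promoter".

The null distribution of category counts comes from shuffled peaks: each
shuffle keeps every peak's length and chromosome and redraws its start
uniformly over valid positions. Shuffled peaks may overlap each other (the
pure uniform null; a rejection-sampling disjoint mode exists behind a
flag). Expected counts are the mean over 1,000 shuffles rescaled to the
observed total, compared by $\chi^2 = \sum (O-E)^2/E$ with $k-1$ degrees of
freedom. Keeping shuffles on their original chromosome preserves
per-chromosome composition — the conservative reading of a
"same lengths, random positions" null. Whether the reference protocol
pooled shuffles or used a per-shuffle empirical null is not specified
anywhere; mean-over-shuffles was chosen and is what the calibration test
validates (rejection rate 2-8% at nominal 5% under uniform placement).

Co-localization with ATAC open-chromatin peaks counts any >= 1 bp overlap,
overall and per category, and the promoter/expression cross-tabulation
reports how many genes with a mutant-specific promoter peak are also
transcriptionally upregulated.

## Locus-wide enrichment and the GSEA permutation test

The central biological claim this pipeline supports is that *locus-wide*
occupancy of the mutant histone — not a promoter peak alone — is what
elevates transcription. Per gene, the locus window runs from 1 kb upstream
of the TSS to the TES, strand-aware ("upstream" of a minus-strand gene
extends toward larger coordinates), clipped at chromosome edges and
flagged. The locus score is the width-weighted mean of $\Delta r$ over the
window: a constant field of value $c$ scores exactly $c$, and mirror-image
genomes score identically (both are asserted as invariants).

* **Significant locus-wide genes**: per gene, a two-sample z test on
  per-sample locus-mean $r$ values, with variances pooled across genes in
  the same decile of locus-window width (again the 2+2 problem), BH across
  genes, keeping $q < \alpha$ with positive mutant excess. The set grows
  monotonically in $\alpha$.
* **GSEA running sum**: genes are ranked by locus score (descending,
  ties broken lexicographically so the ranking is reproducible and
  input-order independent). Walking down the ranking, members of the query
  set add $|s|^w / \sum_{hits} |s|^w$ and non-members subtract $1/(N-N_h)$;
  the enrichment score is the signed extremum of the walk by absolute
  value. $w = 1$ (classic weighted GSEA) is the default; $w = 0$ is
  supported and analytically clean (the walk ends exactly at 0 and
  $|ES| \le 1$).
* **Permutation null**: the ES of `n_perm` (default 10,000) uniformly drawn
  random gene sets of the same size, with
  $p = (1 + \#\{|ES_{null}| \ge |ES_{obs}|\})/(n_{perm}+1)$ — the add-one
  estimator, bounded below by $1/(n_{perm}+1)$, never exactly zero.
  Membership permutation was chosen over sample-label permutation
  deliberately: with two clones per genotype there are only
  $\binom{4}{2} = 6$ label splits, which cannot support a 10,000-draw null;
  random same-size gene sets can. The permuted quantity is therefore "is
  this set unusually concentrated at the top of the ranking", conditional
  on the observed ranking.

The package's ES implementation is cross-checked in the test suite against
an independent step-by-step walk and against `fgsea::calcGseaStat`, and the
permutation p-values are checked to be uniform for randomly drawn sets.

## Concordance

RNA-seq and PRO-seq differential tables are integrated over the
intersection of their gene universes (dropped genes are reported). Genes
are cross-classified by both `call` fields into disjoint buckets — up in
both, down in both, changed in one assay only, discordant (up/down), and
unchanged — which partition the shared universe (a counting identity the
tests assert). Discordant genes get explicit buckets rather than being
folded into "changed in one assay". Fold-change agreement is summarized by
Pearson correlation with the t-transform p-value. The concordantly
upregulated set is intersected with the locus-wide enriched set — the
pipeline's final candidate list of directly activated targets — and
user-supplied gene sets can be tested for over-representation among any
hit list by upper-tail hypergeometric tests with BH across sets (no
pathway database is bundled: versioned databases would break
reproducibility).

# The synthetic-data generator

The generator emulates the study design the pipeline targets: **two
wild-type and two mutant clones, RNA-seq in duplicate** (eight RNA
columns, four PRO columns), 2,000 genes on a 4 x 5 Mb toy genome.

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes placed without overlap |
| `gene_length_range` | 2-8 kb | gene lengths, uniform |
| `min_gene_gap` | 2.5 kb | minimum intergenic distance |
| `nb_mean_range` | 20-200 | baseline expected counts, log-uniform |
| `nb_dispersion` | 0.05 | shared NB dispersion |
| `frac_up`, `frac_down` | 0.05 | planted differential genes |
| `effect_log2fc` | 2 | planted expression effect |
| `frac_flag_enriched_of_up` | 0.4 | up-genes also FLAG-enriched |
| `flag_enrichment_log2` | 3 | planted occupancy effect |
| `bin_size` | 100 bp | track resolution |
| `flag_mean`, `h2a_mean` | 20 | baseline counts per bin |
| `clone_sigma` | 0.1 | per-clone log-normal scale factor |

Counts are negative-binomial with a single shared dispersion — the minimal
count model whose recovery properties are analyzable; no mean-dispersion
trend is simulated. Tracks are emitted pre-binned (bedGraph at bin
resolution): the pipeline's unit of computation is the bin, and read-level
simulation (fragment lengths, GC bias, alignment artifacts) is explicitly
out of scope. H2A is Poisson background everywhere; FLAG equals background
except over the locus windows of the planted target genes in mutant clones,
scaled by $2^3$ (bins partially covered by a window are scaled
proportionally). ATAC peaks sit at every promoter plus 200 random
background intervals, so the co-localization fraction has a non-degenerate
denominator. Clone-to-clone variability is a per-clone log-normal factor
(multiplicative on expected counts); per-sample depth factors exist but
default to 1, since nothing specifies library-size imbalance.

Two generator choices deserve justification:

* **Minimum intergenic gap (2.5 kb).** Locus windows extend up to 1 kb
  beyond each gene end (2 kb of facing extensions in the worst strand
  configuration). Without a buffer, the planted enrichment over one gene's
  window genuinely covers part of a neighbor's window, and the neighbor is
  *correctly* detected as enriched — yet counts as a false discovery
  against the planted truth, making precision against ground truth
  ill-posed. The buffer makes the planted truth identifiable. Real genomes
  do contain interleaved and overlapping regulatory windows; what passing
  recovery tests show is that the statistics find what was planted, not
  that neighboring-locus ambiguity is solved.
* **Placement by gap sampling.** Within a chromosome, gene positions are
  drawn by sampling the inter-gene free space uniformly (order statistics
  of the gaps), which guarantees non-overlap in one pass; chromosome
  assignment is proportional to length with bounded retries, and placement
  fails cleanly when the requested genes cannot fit.

Every generator output is a pure function of `(config, seed)`; the fixture
writer emits a JSON manifest of MD5 checksums, and byte-identical re-runs
are part of the test suite.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: mappability and blacklist artifacts,
fragment-length and antibody-efficiency effects in CUT&RUN, spike-in
normalization, mean-dispersion trends, correlated biological replicates,
and any coupling between expression level and occupancy beyond the planted
effects.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere in memory and on disk;
  conversion to the 1-based closed convention of `IRanges` happens in a
  single function.
* bedGraph values are resampled onto the bin grid by coverage-weighted
  mean (uncovered bases count as zero), which preserves signal mass up to
  grid effects; writers emit run-length-merged records and omit zero runs.
* The minus-strand TSS is `end - 1`; promoter and locus windows mirror
  exactly, and strand-reflection invariance is asserted in the tests.
* Ties in the GSEA ranking break lexicographically by gene id; the ES
  extremum takes the first position attaining the maximal absolute value.
  Two walk positions can tie in absolute value to floating-point
  precision, in which case the sign of the ES is convention-dependent —
  the oracle tests compare magnitudes on such instances.
* All-zero genes get the dispersion floor and are flagged; empty peak sets
  propagate as empty data frames; a zero expected category count in the
  chi-square test is an error instructing more shuffles rather than a
  silent Inf.
* p-values from permutation use the add-one estimator; Fisher combination
  clamps member p at `1e-300` to avoid `log(0)`.

# Problem sizes

The test suite and the acceptance script run entirely on generated data at
the study-design scale the package targets: 2,000 genes, 200,000 bins
across 20 Mb, 2+2 clones, 10,000 GSEA permutations and 1,000 peak
shuffles. The full pipeline completes in well under a minute on one CPU;
calibration checks use 500 replicate datasets at reduced per-replicate
sizes (200-shuffle nulls, 199-permutation p-values), chosen so each
replicate's discreteness is negligible relative to the tolerance being
asserted.

# Known limitations

* The Wald test with decile-pooled moments is honest at 2-vs-2 but has no
  dispersion shrinkage toward a trend; with many samples per group a
  dedicated DE framework is preferable.
* CPM-based internal-control normalization transfers a small share of
  library mass from background to strongly enriched regions (see above);
  absolute occupancy levels are not interpretable, only relative ones.
* The shuffled null conditions on peak lengths and chromosome assignment
  but not on mappability or accessibility structure.
* Membership-permutation GSEA conditions on the observed ranking; it does
  not propagate uncertainty in the locus scores themselves.
* PRO-seq is analyzed as gene-level counts; pause-site versus gene-body
  signal separation is out of scope.
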