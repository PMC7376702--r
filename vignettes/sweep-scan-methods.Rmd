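---
title: "Methods: windowed Fst/pi sweep scans and their supporting statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed Fst/pi sweep scans and their supporting statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `sweepscan`, the
choices made where several defensible definitions exist, and what the
package's synthetic-data validation does and does not demonstrate about
real resequencing data.

## The sweep-scan model

The scan contrasts two population groups of diploid individuals
genotyped at biallelic SNPs: `group1`, the putatively selected
population (e.g. black-skin chicken breeds), and `group2`, a reference
panel.  Three signals are combined.

**Per-SNP Fst.**  With alternate-allele frequencies $p_1$ and $p_2$
estimated from the non-missing genotypes of each group,

$$F_{ST} \;=\; 1-\frac{p_1(1-p_1)+p_2(1-p_2)}
{(p_1+p_2)\left[1-(p_1+p_2)/2\right]}
\;=\;\frac{(p_1-p_2)^2}{(p_1+p_2)(2-p_1-p_2)}.$$

This is a Hudson-style estimator built purely from the two group
frequencies: the average within-group heterozygosity relative to the
heterozygosity of the pooled (equal-weight) frequency.  It is **not**
the Weir–Cockerham variance-components estimator: it has no sample-size
correction, so with $n$ sampled chromosomes per group its null
expectation is of order $1/(2n)$ rather than 0, and it weights both
groups equally regardless of their sizes.  We implement this exact
form deliberately — it is the definition the scan is built around —
and we document the bias rather than correcting it, because thresholds
are empirical quantiles of the same statistic, which absorbs a uniform
bias.  Sites where both groups are fixed for the same allele
(denominator zero) are undefined and excluded from window means; the
algebraic identity above guarantees $0 \le F_{ST} \le 1$ whenever
defined, with 1 exactly at a fixed difference.

**Windowed statistics.**  Windows of `window_bp` (default 10 kb) slide
in steps of `step_bp` (default 5 kb) from coordinate 0 of each
chromosome; all internal coordinates are 0-based half-open, converted
from/to 1-based VCF positions at the I/O boundary.  Window Fst is the
unweighted arithmetic mean of the per-SNP values — deliberately not a
ratio-of-sums estimator, to match the "average Fst per window"
definition.  Nucleotide diversity per group is

$$\pi \;=\; \frac{1}{L}\sum_{\text{SNPs}} 2p(1-p)\,\frac{n}{n-1},$$

the unbiased per-site expected heterozygosity summed over SNPs and
divided by the window span $L$ in bp.  Dividing by span (rather than
SNP count) is the convention of windowed genome scans; `pi_denominator
= "snps"` switches to the per-SNP average for comparison with tools
that report it.  Missing genotypes reduce the per-site chromosome
count $n$; they are never imputed, which keeps the frequency estimates
unbiased.  Sites with $n < 2$ in a group contribute zero and are
tallied in a warning.  Monomorphic sites contribute zero diversity but
are excluded from Fst only in the 0/0 case where the formula is
genuinely undefined.

**Dual-threshold calling.**  A window is a candidate when
`fst_mean` strictly exceeds the Fst cutoff *and* the pi ratio
$\pi_1/\pi_2$ lies strictly beyond a tail cutoff.  Two policies are
provided.  The default `quantile` mode derives all three cutoffs from
the scan itself: the top 5% of window Fst and the 5%/95% empirical
quantiles of the pi ratio, using R's type-7 (linear interpolation)
quantile.  The `fixed` mode takes literal values (defaults: Fst
> 0.17, ratio < 0.05 or > 0.95).  Quantile mode is the package default
because the Fst criterion is intrinsically a top-tail criterion and a
fixed ratio cutoff of 0.95 is only meaningful relative to a particular
diversity distribution; both modes are recorded in the run metadata so
a scan is always interpretable.  Ties at a cutoff are excluded (strict
inequalities).  Windows with no SNPs, undefined Fst, or an undefined
pi ratio ($\pi_2 = 0$) are dropped from ranking and can never be
flagged.  The *low* tail — diversity reduced in group1 — is the
signature of positive selection in that group; the high tail is
reported symmetrically but labelled separately.  Flagged windows on
the same chromosome and tail merge when they overlap or are separated
by at most `max_gap_bp` (default 0), and merged regions are
intersected with gene annotation (GFF3 or BED, normalized to 0-based
half-open) reporting every gene with ≥ 1 bp overlap.

## Supporting statistics

**LD.**  Pairwise linkage disequilibrium is the squared Pearson
correlation of unphased dosage vectors over pairwise-complete samples
(the Rogers–Huff composite measure); no phasing or haplotype EM is
attempted because genotype dosage correlation is the standard unphased
surrogate.  Decay curves bin mean $r^2$ by pair distance (defaults
300 kb range, 1 kb bins; both exposed because published decay figures
rarely state their binning).  Pruning follows the greedy PLINK
`--indep-pairwise 50 5 0.2` scheme: pairs inside a 50-SNP window are
examined in position order, the downstream site of any pair with
$r^2 > 0.2$ is removed, and the window slides by 5 SNPs to the end of
the chromosome (windows shrink at the end so the guarantee — no
retained pair sharing a window with $r^2$ above threshold — holds
exhaustively).  Removing the downstream site is deterministic;
`victim = "maf"` removes the lower-MAF member instead, as PLINK does.

**Distances and trees.**  The individual-level distance is the
allele-sharing p-distance, the mean of $|d_i - d_j|/2$ over
pairwise-complete sites; the whole-genome identity score is defined as
its complement, $IS = 1 - d$ (an interpretation we state explicitly —
several IS variants exist in the literature).  Nei's (1972) standard
genetic distance over group allele frequencies is available for
population-level trees; the individual tree uses p-distance because
Nei's distance is a population quantity.  Neighbor joining is the
canonical Saitou–Nei algorithm (Q-criterion, closed-form branch
lengths, matrix reduction, final three-way join).  On additive
matrices it provably recovers the generating tree exactly, which the
tests exploit as an oracle; `ape::nj` serves only as an independent
cross-check, never as the implementation.  Negative branch lengths on
non-additive input are clamped to zero with the total deficit recorded
as an attribute.  Newick output orders the children of every node by
their lexicographically smallest descendant leaf, so serialization is
a deterministic function of the unordered tree.  Bootstrap support
resamples SNP sites with replacement under a caller-supplied seed.

## The synthetic-data generator

`simulate_dataset()` draws, per site, an ancestral frequency from a
symmetric Beta (shape 0.2, giving the U-shaped spectrum of
drift-dominated standing variation), then group frequencies from the
Balding–Nichols model $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ with
$F$ the background divergence; genotypes are binomial draws and a
small missingness mask (2%) is applied.  Inside a sweep interval the
group1 frequency is replaced by the value that drives the *alternate*
allele towards fixation while scaling expected heterozygosity to
`diversity_reduction` times the background expectation — a hard-sweep
caricature: strong differentiation plus diversity loss, without
linkage structure.  The default configuration **is** the validation
design used throughout: two groups of 10 samples, one 5 Mb chromosome
at 1 SNP / 500 bp, $F = 0.05$, and one 100 kb sweep retaining 10% of
group1 diversity with a target interval Fst of at least 0.4.  These
sizes keep a full replicate under a few seconds while giving every
window ~20 SNPs, enough that window means are stable; the tests run 20
seeded replicates of this design for recovery and 20 for null
calibration, 50 random 6-taxon trees for NJ, and 100-SNP fixtures for
pruning.  A feasibility check rejects configurations demanding
complete differentiation alongside non-zero retained diversity.

What passing these tests shows: the estimators match their algebraic
and brute-force oracles exactly; the calling rule finds a strong
planted sweep with high base-pair recall and stays calibrated on null
data.  What they do not show: performance under linked selection,
demographic confounding (bottlenecks, migration), soft sweeps, or
realistic LD — the generator draws sites independently, so LD-decay
behaviour is validated only on purpose-built copy-with-error panels,
and power on real data will differ from power on this idealized model.

## Numerical and degenerate-input conventions

* Quantiles: R type 7 (linear interpolation) everywhere.
* All threshold comparisons strict; identical-valued windows therefore
  never self-select in quantile mode.
* Terminal windows keep their full nominal span (the span denominator
  does not shrink); the last window on a chromosome ends at the last
  SNP position rounded up to a window boundary, since VCF headers
  without contig lengths cannot anchor the true chromosome end.
* Multiallelic sites and non-SNP records are dropped, not split, and
  counted in the reader's exclusion tally; per-site missingness above
  20% (configurable) also excludes a site.
* NJ joins break ties by the first (row-major smallest-index) minimal
  Q entry; pruning breaks ties by removing the downstream site.
* The 32-bit FNV-1a hash of the serialized configuration is embedded
  in scan metadata so byte-identical reruns are verifiable.

## Known limitations

The Fst estimator's small-sample bias (order $1/2n$) makes *fixed*
absolute cutoffs comparable only between designs of similar sample
size; quantile mode is immune.  The simulator's independence across
sites means pi-ratio noise is slightly optimistic relative to linked
data.  LD pruning is greedy and order-dependent by design (it mirrors
the de-facto standard tool); it does not find a maximum independent
set.  Identity scores depend on the allele-sharing definition stated
above and are not comparable across packages using frequency-weighted
variants.
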