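---
title: "Methods: pool-seq bulked-segregant mapping with bsamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq bulked-segregant mapping with bsamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

# The model

`bsamap` implements the statistics of bulked-segregant analysis (BSA)
for a fully penetrant (or nearly so) autosomal recessive locus
segregating in an F2 intercross. Two DNA pools are built by phenotype —
mutant-like animals in one, wild-type-like in the other — and sequenced
as pools, so only per-site read counts per pool are observed, never
individual genotypes.

Two complementary window statistics localize the locus:

* **Allele-frequency differentiation (dAF).** At a biallelic site the
  pools' alternate-read frequencies are compared,
  `dAF = |p_mut - p_wt|`. Under recessive inheritance the mutant pool is
  fixed for the causal allele (expected frequency 1) while a
  phenotypically wild-type F2 animal is hom-ref with probability 1/3 and
  het with probability 2/3, giving an expected wild-type-pool frequency
  of 1/3 and an expected causal-site dAF of 2/3 (`expected_pool_daf()`;
  the 3/4 obtained by weighting the two carrier classes equally is
  exposed as a labeled alternative because that figure is sometimes
  quoted for this design, but it is not the F2 phenotype-conditional
  expectation).

* **Pooled heterozygosity (Hp).** Per window and pool,
  `Hp = 2 * sum(nMAJ) * sum(nMIN) / (sum(nMAJ)+sum(nMIN))^2` over each
  SNP's major/minor read counts. Recessive-affected F2 animals are
  identical by descent (IBD) around the causal locus, so the mutant
  pool's Hp collapses toward its sequencing-error floor there while the
  wild-type pool stays near 0.44. The ratio
  `(Hp_wt + eps)/(Hp_mut + eps)` with `eps = 1e-4` is finite and
  rankable even when a pool is fully fixed; orientation is a flag
  because the two possible conventions both appear in the literature.

Windows are defined by **SNP rank**, not base pairs: 5,000 SNPs stepped
every 1,000, dropping windows under 4,000 SNPs (truncated end-of-
chromosome spans are kept down to that minimum). At the emulated marker
density of 5 SNPs/kb a window spans ~1 Mb. A boundary consequence of
the rule worth knowing: a chromosome holding exactly 5,000 SNPs yields
two windows — the full span and the truncated 4,000-SNP span starting
at rank 1,001, which meets the minimum exactly.

# Interval calling

The empirical "top 1%" of a window statistic is a genome-wide notion.
Because the simulation is single-chromosome (for desk-scale runtime),
the focal chromosome's windows are combined with an **unlinked
background**: 94 non-overlapping windows of unlinked sites are
simulated and each stands for 99 genome windows, reproducing the ~9,400
windows of a mammalian genome at this geometry. The threshold is the
smallest value among the `ceiling(0.01 * N)` largest; flags use `>=`
so ties are included. Flagged focal windows are merged
(`GenomicRanges::reduce`, overlapping or book-ended spans) into the
coarse candidate interval. Around a recessive locus this interval is
deliberately broad — IBD produces a plateau of elevated values, exactly
as a real scan reports tens of megabases.

The filtering cascade then searches the **refined region** where the Hp
ratio is at least 100-fold, mirroring how an extreme-heterozygosity
region is carved out of the broader interval in practice. Two numerical
choices matter here. First, sub-window gaps between >=100-fold windows
are bridged and the merged region is padded by half a window span:
a window-rank scan localizes boundaries only to about one window, and
without smoothing a single recombinant-clipped window can split or
shift the region by bad luck. Second, when no window reaches 100-fold
the cascade falls back to the coarse interval rather than returning
nothing.

# The filtering cascade

Filters are pure row intersections, so the final candidate set is
order-independent (a property the tests verify by permutation); the
report lists survivors per stage in the conventional order: interval,
quality >= 200 and biallelic, per-pool depth at most 2x that pool's
genome-wide mean (strictly greater is discarded; collapsed repeats
accumulate such depths), impact class in {MODERATE, HIGH} (consequence
labels are consumed from input annotation — re-implementing effect
prediction is out of scope; the SnpEff-style term-to-class map is an
editable table), dAF strictly greater than 0.5, and zero
alternate-allele observations in the reference panel (positions missing
from the panel count as unobserved, and are logged). Survivors are
ranked by dAF descending, position ascending on ties.

# What the generator emulates — and what it does not

`cross_design()` defaults are the stated experimental world: 52 F2 from
a single mutant-strain x wild-type founder pair, pools of 12
mutant-phenotype and 40 wild-type-phenotype animals, mean depths
37.6X/36.5X, and a 2/14 probability that a homozygous mutant is
phenotyped wild-type (phenotyping at ~4 weeks misses subtle cases; the
two discordant animals in such a cross motivate the default).
Recombination is Haldane — crossover counts Poisson in map length,
positions uniform, no interference — on a uniform 1 cM/Mb map; no map
was specified for the organism and locus-scale linkage decay does not
require more. Depth is Poisson around the pool mean; sequencing error
is a symmetric per-read allele flip at 0.001 (Q30-class), with no indel
errors. Every SNP is a fixed founder difference, so the marker map is
fully informative; density is 5 SNPs/kb so that a 5,000-SNP window
spans ~1 Mb, matching a genome-wide callset of ~10M markers with a
median window near 1 Mb.

The reference panel (20 unrelated samples, emulating a 14 + 6 panel of
wild populations and other breeds) carries the wild-type allele at the
causal site by construction and is polymorphic elsewhere with allele
frequencies uniform on [0.1, 0.5]: fixed differences between two
domestic lineages are overwhelmingly common variants in the wider
species. Under this choice a non-causal variant escapes the panel with
probability ~9e-4, so about one simulated cross in ten contains some
impact variant that is panel-absent by chance — real noise that the
prioritization tests deliberately retain.

Amplicon reads are `barcode + adapter + template` with symmetric
substitution errors on the template only; the error-free prefix is a
construction convenience (demultiplexing failure is exercised in tests
by mutating prefixes explicitly). No indel errors, no quality strings
with information, no chimeras: a green mixture-recovery test
establishes that junction classification is accurate under substitution
noise at nanopore-like rates, not that it survives every nanopore
artifact.

What a green end-to-end test does **not** establish: performance under
segregation distortion, under markers informative in only one founder,
under multi-chromosome backgrounds with varying recombination, or under
structural variation (explicitly out of scope).

# Splice-consequence and isoform modules

Gene models are 1-based inclusive exon coordinates (GFF convention)
plus genomic sequence; minus-strand genes are reverse-complemented into
transcript orientation before any scanning, and intron offsets are
0-based. A donor is disrupted when position +1 or +2 of the intron is
changed away from G/T; reference introns not starting `GT` are flagged
non-canonical rather than rejected. `scan_cryptic_donors()` reports
every `GT` offset (overlapping included) with no strength model — the
analysis this package supports invokes none, so selecting biologically
used donors is the caller's choice. Retaining `k` intronic nucleotides
is frame-preserving iff `k %% 3 == 0`; premature-stop status is
computed by translating the spliced sequence with the standard nuclear
code (a stop inside the retained segment or anywhere in a shifted
downstream frame counts). An in-frame retention of 15 nt without a stop
inserts exactly 5 residues.

Junction signatures are contiguous 30-nt windows (15 nt each side of
the **novel** junction, i.e. the retained-segment end / downstream-exon
start). A non-contiguous "both ends of a long retention" signature was
considered and rejected: it cannot be aligned semi-globally against a
read that contains the full retention. All retention isoforms share the
upstream exon/retained-start junction, so the novel junction is the
discriminating one; contiguous windows keep classification a single
alignment. Classification accepts the minimal-distance isoform when
that distance is at most 20% of the signature length (nanopore-class
tolerance; configurable) and reports ties as unassigned. Abundances
are proportions over assigned reads, with unassigned counts reported
separately, never silently renormalized away.

Demultiplexing is exact: the first 17 bases must equal
barcode (7 nt) + adapter overhang (10 nt). Stringency is the point —
with high-error long reads, exact prefix matching trades yield for
near-zero cross-sample contamination.

# Numerical and degenerate-input choices

* Zero-depth sites get `NA` dAF and are counted per window
  (`n_excluded`), never imputed; whether a real pipeline excluded or
  imputed such sites is unknowable from the outside, and exclusion with
  accounting is the conservative reading.
* All-zero count windows give `NA` Hp and propagate `NA` ratios.
* `empirical_top_fraction()` requires at least one finite value and
  errors otherwise; NAs are never flagged.
* Exact binomial segregation tests use the minimum-likelihood two-sided
  convention (`stats::binom.test`); with n ~ 52 an asymptotic
  chi-square would be less accurate and no specific test is mandated by
  the analysis this emulates.
* Determinism: every `simulate_*` function derives its RNG stream from
  the design seed (restoring global RNG state on exit), so identical
  seeds give bit-identical output across the whole pipeline.

# Known limitations

* The acceptance-scale world is one 25-Mb chromosome; genome-wide
  context enters only through the unlinked-background multiplier.
* The Hp fold-change at the causal window is itself stochastic: in
  roughly 1 in 20 simulated crosses a recombinant chromosome in the
  mutant pool clips every window containing the causal SNP and the
  observed fold-change falls below 100 even though the statistic is
  computed correctly. Likewise the causal site's observed dAF falls
  below the 0.5 filter threshold in ~4% of crosses from read sampling
  alone (expected dAF 2/3, read-noise SD ~0.09 at 37X). These are
  properties of the experimental design being emulated, not of the
  implementation; the acceptance report therefore quotes a median over
  5 replicates for the fold-change target.
* Relative isoform abundance by read classification is an estimand
  substitute for coverage-based quantification at shared positions; the
  two agree on relative transcript abundance but are not numerically
  identical procedures.
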