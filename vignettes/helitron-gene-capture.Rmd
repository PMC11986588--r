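---
title: "Detecting and profiling Helitron gene capture in an allopolyploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and profiling Helitron gene capture in an allopolyploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helicap)
```

## The problem

Helitron transposable elements replicate by a rolling-circle
("peel-and-paste") mechanism that can copy fragments of host gene exons
into the element without disrupting the donor gene. In an allotetraploid
such as *Brassica napus* (AnAnCnCn), these captured fragments sit at the
crossroads of two regulatory systems: the 24-nt siRNAs that direct DNA
methylation onto the TE (RdDM) are homologous to the donor gene's exon,
so silencing the element can spill over onto the gene ("siRNA
crosstalk"). `helicap` implements the full analysis: detecting capture
events from annotation and sequence, characterizing them, estimating
selective pressure on homoeologous gene pairs, and quantifying siRNA
abundance, CG/CHG/CHH methylation and expression of donor genes and
gene-capturing TEs across an allopolyploidization series — an in-silico
1:1 parental "hybrid" (AC), a resynthesized allotetraploid (RAC) and the
natural allotetraploid (NAC), each with three replicates.

Because the real inputs are genome-scale sequencing libraries, the
package ships a first-class synthetic-data generator that
reproduces the statistical structure the analysis assumes, so every
stage is testable end to end on a desk-scale fixture.

## Capture detection

Genes and TEs that physically intersect in the genome are removed first
(both members of every overlapping pair; intervals are 0-based
half-open, so abutting features do not overlap). Each remaining TE
sequence is then locally aligned against every remaining gene exon
sequence with an affine-gap Smith–Waterman kernel (match +1, mismatch
−2, gap open −5, gap extend −2 by default; a gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{extend}$; `N` always scores as a
mismatch). Raw scores $S$ are converted to bit scores and E-values with
Karlin–Altschul statistics,

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad E = m\,n\,2^{-S'},$$

where $\lambda$ is the unique positive root of
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ (solved to a residual below
$10^{-9}$), $K = 0.621$ for the default scheme (tabulated; other schemes
use a flagged $H/\lambda$ approximation), $m$ is the TE length and $n$
the summed exon length — a database-search expectation that makes the
strict screen $E < 10^{-40}$ meaningful. A shared 11-mer prefilter skips
hopeless pairs; it is exact-match based and can be disabled, in which
case the scan is exhaustive (the test suite asserts both routes give
identical hit sets).

Hits on one TE are clustered into capture loci by ≥1 bp overlap of
their TE-local intervals (transitively). Within a locus the gene with
the highest bit score is the donor; several genes with identical bit
score and E-value are all retained and flagged as ties, and a TE hitting
two exons of the same gene at one locus yields a single event. TEs with
one locus are *single* gene-capturing TEs, those with two or more are
*multiple*. A *captured* gene is any gene with a passing hit before
donor resolution; a *donor* gene wins at least one locus; everything
else is *free*.

```{r detect, eval = FALSE}
cfg <- sim_config(seed = 1)
genome <- generate_genome(cfg)
planted <- plant_captures(genome)
catalog <- detect_captures(planted$genome)
catalog
```

## Characterization

Captured fragments are typed UTR/CDS by base-wise intersection with the
donor gene's subfeatures; a fragment is called one kind when at least
80% of its attributed bases agree (configurable), otherwise *mixed* —
reported separately so a binary proportion can be recomputed either way.
Events are placed in four positional groups using the closest-edge gap
between TE and gene: within 2 kb on one chromosome (NEAR), farther on
the same chromosome, different chromosomes of one subgenome, or
different subgenomes; features on unplaced scaffolds are excluded and
counted. Per-Mb density tracks bin features by midpoint (boundary
midpoints fall rightward), pseudogene overlap is any ≥1 bp intersection
of a capturing TE with a pseudogene interval, GC content excludes `N`
from the denominator, and donor genes are compared with an equally sized
seeded random sample of free genes by two-sided Wilcoxon tests on exon
lengths and counts. Chromosome-level counts of donor genes and capturing
TEs are correlated with chromosome length by Pearson's $r$ (a recorded
design choice; rank-based alternatives are easy to apply downstream).

## Ka/Ks of homoeologous pairs

Pairs are split into *donor pairs* (at least one donor gene) and *free
pairs* (both free). For each pair the CDS sequences are aligned
codon-aware — translations aligned globally, the protein alignment
back-threaded onto the nucleotides, gap codons dropped — and Ka/Ks is
computed with the Nei–Gojobori (1986) method: per-codon synonymous site
fractions from the standard genetic code (changes to stop codons count
as nonsynonymous), multi-position codon differences averaged over all
equally weighted substitution pathways excluding those through stop
codons (re-weighting the rest; if every pathway is blocked the
unrestricted average is used), and the Jukes–Cantor correction
$d = -\tfrac34\ln(1 - \tfrac43 p)$ applied to both proportions. Ks = 0
and $p \ge 3/4$ are flagged rather than silently dropped. The
implementation is checked exactly against a brute-force
pathway-enumeration oracle and against a neutral simulation whose mean
Ka/Ks must fall in [0.85, 1.15].

## Epigenetic profiling

24-nt reads are retained after removing other lengths and anything
overlapping a structural-RNA exclusion BED. The AC "hybrid" library is
built by downsampling the larger parental library to the smaller one's
size (seeded, without replacement) and concatenating, so both parents
contribute equally. Feature siRNA abundance is RPM with a
midpoint-containment rule by default (an any-overlap rule is a flag);
methylation levels are *weighted*: $\sum m / \sum t \times 100$ over the
cytosines of one context in the interval, undefined (not zero) without
coverage — robust to depth variation, and invariant under pooling of
any partition of the interval. Gene/TE metaprofiles split the upstream
2 kb, body and downstream 2 kb into 20 bins each (body bins
length-proportional; minus-strand features reversed so bin 1 is 5′).
Histograms use ten equal groups over 0–100% with the last bin closed.
For each capture event the TE-local interval is mapped back to genomic
coordinates (reflected for minus-strand TEs) and both sides of the
fragment are profiled, giving the paired donor-gene vs TE comparison at
single-fragment resolution. Expression is TPM-normalized
(length-corrected rates scaled to $10^6$ per sample).

## Differential calling

The three contrasts are RAC vs AC, NAC vs RAC and NAC vs AC. DEGs use
the package's negative-binomial Wald test at $|\log_2 FC| \ge 1$,
$P \le 0.001$; DML and DEsiRNA use the two-sided pooled-variance
Student's t-test at $P < 0.05$ on per-replicate feature levels (a Welch
variant is available). No multiple-testing correction is applied by
default, matching the raw-threshold procedure; a BH option exists in
`p.adjust` form downstream if users want it. Proportions of calls are
summarized within donor vs free genes and capturing vs free TEs, split
by direction.

The NB test normalizes by median-of-ratios size factors, estimates the
NB dispersion per feature by a per-group method of moments (the
dispersion is shared across groups even when means differ, so each
group's $\hat\alpha=(s^2-\bar x)/\bar x^2$ is df-weighted and floored at
$10^{-8}$), and — in the matrix route — shrinks these 80% toward a
mean–dispersion lowess trend fitted across features (plain local mean,
no robustness iterations, which would bias the trend low under the
skewed sampling distribution of moment estimates). The Wald standard
error is evaluated at the pooled mean (a null-referenced, score-like
choice). These three choices are what keep the test simultaneously
calibrated (null type-I within Monte-Carlo error of nominal at
$\alpha=0.05$ with 3 vs 3 replicates) and powerful (≥0.8 on planted
4-fold changes) — a pure per-feature moment estimator with a normal
reference is anticonservative at this replicate number, and a
$t_4$ reference destroys power at $P \le 0.001$. The test is a
self-contained approximation of shrinkage-based NB packages, not a
reimplementation of any of them; it omits outlier handling and
fold-change shrinkage.

## Homoeolog analysis

Pairs are partitioned by where their donor genes lie (An only, Cn only,
both, neither — a total partition). Pairs with exactly one donor side
enter the six "genotype × donor-subgenome" classes; within each class
the donor-side genes are compared with the non-donor-side genes by a
two-sided unpaired Wilcoxon test on per-gene replicate means (matching
group box plots; a paired signed-rank variant is a flag), with
significance stars at 0.05/0.01/0.001.

## The synthetic study system

`sim_config()` defines the fixture: two subgenomes × 2 chromosomes
whose lengths vary 0.7–1.3× around 500 kb (so count-vs-length
statistics are non-degenerate), 200 genes with Poisson exon counts
(mean 4), Gaussian exon lengths (250 ± 80 bp), 30% of exonic bases in
UTRs and stop-free CDS; 40% of An genes have a Cn homoeolog at 3%
divergence (CDS mutations avoid stops); 300 Helitron-like TEs of
0.5–3 kb placed outside genes, half inside pseudogene intervals; and 60
planted captures with fragments of 100–600 bp at 5% per-base divergence,
~35% of capturing TEs carrying multiple non-overlapping fragments. The
donor gene is left untouched (peel-and-paste semantics), and fragments
are written in the TE's reading orientation.

The epigenomes are phenomenological level shifts, not a mechanistic RdDM
simulation — the pipeline only needs inputs with the claimed statistical
signatures. Per-context baselines are gene body 40/10/5, TE 85/65/15 and
intergenic 20/10/5 percent (CG/CHG/CHH); donor genes sit
`crosstalk_delta` = 20 points above the gene baseline in *every*
genotype, their captured fragment region sits 20 points above the *TE*
baseline (so fragment pairs show the crosstalk offset directly; note CG
saturates at 100%, which is why offset-magnitude checks use CHG), and in
RAC only, donor genes and capturing TEs are multiplied by
`rac_relaxation` = 0.7 — reproducing the "drop then recover" trajectory
across AC → RAC → NAC. Read sampling is binomial at Poisson depth 30.
siRNA libraries place 70% of 100k reads on TEs (length-weighted), 5% on
donor fragments (the crosstalk share), the rest uniformly; the RAC
relaxation factor also scales the capturing-TE and crosstalk weights, so
DEsiRNA contrasts carry signal. The AC libraries are built from separate
An-side and Cn-side parental libraries mixed 1:1 through
`make_in_silico_hybrid()`. Expression counts are negative binomial
(mean 100, dispersion 0.1) with a donor fold ladder (1, 1.5, 2) across
AC/RAC/NAC.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequencing error and bisulfite-conversion
failure, multi-mapping reads, Helitron terminal structure, non-uniform
substitution processes (so Ka/Ks is near-neutral rather than purifying),
population structure among replicates, and genome-scale search spaces
(the fixture's feature counts are orders of magnitude below a real
allopolyploid genome's).

## Numerical conventions and degenerate inputs

All internal coordinates are 0-based half-open; GFF3 converts at the
I/O boundary (an involution asserted by round-trip tests). Multi-isoform
genes use the longest transcript. CX context tokens go through a strict
dialect table ({CG, CpG} → CG); unknown tokens are errors. Uncovered
cytosines are kept but contribute nothing to weighted levels. Zero-depth
features, all-zero count columns, zero-variance statistics inputs and
Ks = 0 ratios are flagged (NA or `degenerate`), never silently replaced.
Ties are broken deterministically everywhere (documented sort keys in
donor assignment; smallest-subject-end rule in the alignment kernel),
and every stage derives its RNG stream from the single config seed, so a
rerun of `run_pipeline()` is byte-identical.

Problem sizes used by the shipped tests: unit tests run on a 1
chromosome/subgenome × 100 kb fixture (30 genes, 40 TEs, 10 captures);
the acceptance tests use the default fixture above. These sizes were
chosen so the whole pipeline completes in minutes on one CPU while every
statistical check retains adequate resolution.

## Limitations

Detection is forward-strand only (the simulator plants fragments in
matching orientation); donor resolution at one locus assumes the
highest-scoring gene is the biological donor, which a recently diverged
paralog could violate; the NB test has no outlier handling; and the
Karlin–Altschul K for non-default schemes is an approximation (flagged
in the scheme object).
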