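---
title: "Methods: assembly QC, decontamination, and molecular adaptation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly QC, decontamination, and molecular adaptation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aviadapt)
```

# Scope

`aviadapt` packages the desk-side computations of a de novo avian genome
project — the statistics and decision rules that sit *between* the heavy
external tools (assemblers, aligners, taxonomic classifiers, codon-model
optimizers), all of which are represented by their tabular outputs and never
executed here. Every stage is paired with a seeded synthetic-data generator
that plants a known signal, so the whole chain is testable offline on a
single CPU.

# Assembly summary statistics

For a length multiset sorted descending with total $T$, the Nx is the length
at which the cumulative sum first reaches $x\%$ of $T$ and Lx is the number
of sequences needed to get there. Both are computed on the set that survives
a `min_length` filter (contig tables conventionally use 300 bp, scaffold
tables 1,000 bp); the mean length is computed on the same filtered set (the
unfiltered alternative can be had by setting `min_length = 0`).

GC content is reported under two conventions because assemblies carry large
N-gap tracts: the headline value divides G+C by the unambiguous A+C+G+T
total, and `gc_with_ambiguous` divides by all bases. Both appear in the
`AssemblyReport` so the reader can see how much the choice matters for a
given assembly.

Per-base coverage uses exact interval stacking (`IRanges::coverage()`), and
depth quantiles are type-1 order statistics — reproducible integers, never
interpolated. Gene-element means (span, CDS, exon, intron) are *pooled*
means across all elements, not per-gene averages of averages; with skewed
gene structures the two differ, and pooling is the convention that matches
"average bp per exon" phrasing.

The annotation acceptance rule is a conjunction with inclusive boundaries:
identity $\ge$ 0.30, alignment length $\ge$ 80 bp, e-value $\le$ 10^-5^.

# The contamination screen

Input is a best-hit-per-read BLAST table (tabular format with a staxids
column). Ties in the best-hit reduction are broken deterministically:
lowest e-value, then highest bitscore, then file order. Multi-taxid cells
resolve to the first listed taxid, with a log message; taxids missing from
the user-supplied taxon table are kept as `unknown`, non-avian, so an
incomplete table can only make the screen more conservative upstream of the
species-count rule. Avian status comes from that table, not from a live
taxonomy service — the package never downloads anything.

The cascade is applied in a fixed order with literal boundary semantics:

1. keep reads with alignment length $\ge$ 100 bp (inclusive);
2. drop reads matching an avian species (self-hits to the sequenced clade);
3. drop reads whose species has $<$ 50 surviving reads (a species at exactly
   50 is kept) — rare species are treated as spurious matches;
4. flag scaffolds carrying $>$ 20 surviving reads (a scaffold at exactly 20
   is kept).

Species tallies in stage 3 are computed *after* the avian drop; the
pre-avian tallies are also attached to the output, because the alternative
ordering is defensible and a reader may want both. The screen is idempotent
(rerunning on its cleaned output removes nothing) and monotone in all three
thresholds; both properties are asserted by tests.

# Pairwise codon statistics and dN/dS

The pairwise method is Nei–Gojobori (1986) counting, the field-standard
choice when only an aligned pair is available. Sites: each codon
contributes 3 sites, split by the synonymous fraction of its nine
single-base mutants (mutations to stops count as nonsynonymous), averaged
over the two sequences. Differences: codons differing at $d$ positions are
resolved over all $d!$ minimal pathways with equal weight; pathways that
traverse a stop codon are excluded, and in the degenerate case where every
pathway is blocked, all pathways are used with stop-traversing steps counted
nonsynonymous so that $N_d + S_d$ always equals the number of differing
positions. Proportions $p_N = N_d/N$, $p_S = S_d/S$ are corrected with
Jukes–Cantor, $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, and
$\omega = d_N/d_S$. When $d_S = 0$ or a proportion saturates
($p \ge 3/4$), $\omega$ is flagged undefined rather than reported as a
number.

Codon columns containing a gap in either sequence are removed pairwise
before counting; ambiguous and stop-containing codons are skipped with a
warning. Nucleotide identity is computed over all mutually non-gap columns,
amino-acid identity over gap-free codon columns translated with the
standard code.

The implementation is checked against an independent pathway-enumeration
oracle on exhaustive single-codon pairs and random multi-codon pairs, and
against parameter recovery from the codon-process simulator. Recovery runs
use branch length $t = 0.05$ per lineage: the JC correction is exact for a
uniform single-nucleotide process but only approximate for a codon process,
and at larger divergences ($t \gtrsim 0.15$ per lineage) the estimator is
visibly biased downward for $\omega > 1$ — a known property of counting
methods, not a defect of this implementation, which is why the recovery
conditions stay short of saturation.

# Branch-site LRT post-processing and FDR

The package consumes per-gene log-likelihoods of the null (foreground
$\omega$ fixed at 1) and alternative branch-site models and computes
$\Lambda = \max(0, 2(\ln L_1 - \ln L_0))$, with negative differences —
optimizer noise — clamped to zero with a warning. The default reference
distribution is $\chi^2_1$, the conservative convention for this test; the
50:50 point-mass/χ² mixture is available via `mixture = TRUE`. Adjustment
uses Benjamini–Hochberg (via `stats::p.adjust`), with genes called selected
at $q < 0.05$; the test suite verifies the adjustment against the exhaustive
step-up closed form $q_i = \min_{j \ge i} \min(1, p_{(j)} m / j)$.

# Enrichment with an empirical permutation p

Per category, the observed statistic is the upper hypergeometric tail
$P(X \ge k)$ for $k$ selected genes in a category of $K$ among $N$ universe
genes with $n$ selected. The empirical p ranks that statistic within a null
of $B$ equal-size gene sets drawn uniformly without replacement from the
same universe:
$$p_{\mathrm{emp}} = \frac{1 + \#\{b : p_b \le p_{\mathrm{obs}}\}}{B + 1}.$$
Three conventions are deliberate: the add-one correction keeps
$p_{\mathrm{emp}} > 0$ with resolution $1/(B+1)$; ties count against
significance; and the ranking is per category (a global rank across
categories would answer a different question). The sampling frame is the
same annotated universe as the observed test. `exactPermutationP()`
enumerates the full subset space when it is small and is the oracle the
Monte-Carlo routine is tested against. The Bonferroni variant
(`min(1, p·m)`) is provided for pathway-style analyses, and `slimRollup()`
aggregates significant categories into slim bins.

Because the hypergeometric statistic is discrete, the attainable tail
levels are a step function and a nominal 0.05 test is mildly conservative.
Under the generator's default conditions (universe 1,000; 40 categories of
40 genes; 100 selected) the largest attainable level below 0.05 is
$\approx 0.039$, so the null calibration test expects the realized type-I
rate near that value, inside the 0.05 ± 0.02 band. Category size 40 was
chosen as a realistic mid-size functional term.

# Ortholog families and supermatrices

`familyMatrix()` tabulates per-cluster, per-species gene counts (CAFE-style
output available); `singleCopy()` selects clusters with exactly one gene in
every declared species. `concatenateAlignments()` builds a supermatrix by
concatenating per-gene alignments in the *same* order for every species —
the order itself defaults to lexicographic gene id, which is deterministic;
any fixed order is equally valid, consistency across species is what
matters. The partition table uses 1-based inclusive coordinates (the
RAxML-style output convention), while all internal interval arithmetic in
the package is 0-based half-open.

# Synteny filtering and inversions

A block is `reverse` when query and subject coordinates run in opposite
directions — the reverse-complement alignments that mark inversions.
Filter boundary semantics follow the wording they implement: the dot-plot
filter is inclusive ("at least": block $\ge$ 3 kb, scaffold span $\ge$
0.25% of the chromosome), the chord filter strict ("greater than":
scaffold $>$ 500 kb, block $>$ 10 kb). The 0.25% rule is ambiguous about
its denominator; the default reads it as the chromosome's full length, with
the aligned-portion reading available via `fraction_of = "aligned"`. The
span predicate is recomputed from the post-length-filter block set, so the
filter is stable under upstream subsetting. Per-chromosome identity is the
alignment-length-weighted mean of block identities; coverage merges
overlapping subject intervals before counting, so it can never exceed the
chromosome length.

# The synthetic-data generators

Each generator is a pure function of a master seed: sub-streams are derived
by fixed per-generator offsets, so adding a generator never changes
existing fixtures, and every generator restores the caller's RNG state.
Truth tables are returned alongside each dataset and are consumed only by
tests.

* **Assembly** — log-normal scaffold lengths (the long tail typical of
  short-read assemblies) and i.i.d. bases at a target GC. It does *not*
  emulate repeats, N-gaps, or coverage-correlated composition; tests that
  pass on it validate the statistics' arithmetic, not robustness to real
  assembly artefacts.
* **Contamination** — planted scaffolds receive at least twice the scaffold
  cutoff in screen-eligible reads from one abundant non-avian species
  (defaults: 60 reads each, species total well above twice the species
  cutoff), while clean scaffolds receive only noise designed to die at each
  cascade stage (short alignments, avian self-hits, a rare species).
  Real contamination is messier — partial scaffolds, shared k-mer space —
  so perfect recall here demonstrates the decision rules, not classifier
  power.
* **Codon pairs** — a per-codon Gillespie process: each position mutates to
  each alternative base at rate 1/3, times `kappa` for transitions, times
  `omega` for nonsynonymous changes; stop codons are rejected. Under this
  scaling the per-synonymous-site rate is 1 and the per-nonsynonymous-site
  rate is `omega`, so NG86 recovers `omega` directly when `kappa = 1` (the
  NG86 assumption; transition bias would bias the counting estimator, which
  is why recovery tests fix `kappa = 1`).
* **Enrichment** — categories of fixed size drawn uniformly; the selected
  set is drawn with weight `odds` on the planted category's members,
  `odds = 1` giving an exactly null dataset.
* **Synteny** — collinear blocks along a virtual chromosome with planted
  coordinate flips and identities uniform in a configurable band.

# Problem sizes

The default test and verification runs use: 1,000 random length multisets
for Nx/Lx; exhaustive 61-codon site checks plus ~1,300 exhaustive
single-codon and 60 random three-codon pairs against the pathway oracle;
20 replicates of 2,000 codons per omega level for recovery; 100 seeded
null enrichment datasets at B = 1,000 plus the six-gene fixture at
B = 10,000; 10 replicate screens of 50 scaffolds; 10,000 random p-vectors
for the FDR check; and 10 replicate synteny sets of 80 blocks. These sizes
give stable medians and rate estimates while keeping a full run in well
under a minute.

# Known limitations

* NG86 with JC correction underestimates high $\omega$ at larger
  divergences; for saturated pairs a ML codon model is the right tool, and
  this package deliberately only post-processes such models' outputs.
* The empirical-p routine holds the full gene-by-category membership matrix
  in memory; it is sized for annotation maps of thousands of genes and
  hundreds of categories, not genome-scale GO DAGs with propagation (out of
  scope by design).
* The contamination screen trusts its inputs to be best-hit-per-read and a
  correct taxon table; it has no notion of alignment quality beyond length.
* `consensusSubstitutions()` computes support over all non-focal sequences,
  so non-focal gaps reduce support; with the default `min_support = 1` a
  column with any non-focal gap can never be called.
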