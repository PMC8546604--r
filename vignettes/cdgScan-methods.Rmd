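---
title: "Methods: motif-based activity calling and census statistics in cdgScan"
author: "cdgScan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-based activity calling and census statistics in cdgScan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdgScan)
```

# The biological problem

Cyclic di-GMP is a near-universal bacterial second messenger. It is
synthesized from two GTP molecules by diguanylate cyclases (DGCs) carrying a
GGDEF domain, degraded to pGpG/GMP by phosphodiesterases (PDEs) carrying an
EAL (or HD-GYP) domain, and sensed by effectors such as the PilZ domain.
Many genomes encode dozens of GGDEF/EAL proteins, but a substantial fraction
of these domains are *degenerate*: the fold is recognizable while one or
more catalytic residues are substituted, and the protein is presumed
enzymatically inactive (it may still act as a receptor or a structural
partner). A meaningful genome census of c-di-GMP signaling therefore needs
an activity layer on top of domain presence.

cdgScan implements that activity layer as spacing-constrained motif
matching, plus the downstream statistics a census study typically reports:
per-genome component tallies, upstream-intergenic GC content of cyclase
genes versus replicon baselines (relevant because the zinc-finger repressor
MucR prefers low-GC targets), and RPKM-based expression summaries with a
two-way ANOVA variance partition.

# The activity motifs

Each motif is an ordered alternation of *essential residue classes* (a set
of allowed amino acids at one position) and *anonymous spacers* of fixed or
ranged width:

* GGDEF (DGC activity): `D x(7) N x(8) D x(21) R x(1) [GSA] G [DE] E F` —
  46 residues end to end; the terminal `[GSA] G [DE] E F` block is the
  active (A) site.
* EAL (PDE activity):
  `E x(55,58) N x(31) E x(1) x(1) E x(26) D x(20) K x(35) E` —
  176–179 residues.
* PilZ (c-di-GMP binding):
  `R x(1) x(1) x(1) R x(20,30) [DN] x(1) [SA] x(1) x(1) G` — 31–41
  residues.

A domain is called **ACTIVE** when the full motif matches anywhere in the
domain sequence and **DEGENERATE** when at least one essential residue of
the best attainable alignment fails its class. The best alignment is the
one maximizing the number of matched essentials over every start position
and every admissible combination of ranged-spacer widths; ties are broken
by earlier start, then smaller total spacer width, which makes the
diagnostics deterministic. The mismatch report names the failing essential
indices and the observed residues — this is what distinguishes "degenerate
at the I-site arginine" from "missing the whole A-site".

GGDEF domains additionally carry an allosteric inhibition site (I-site),
an `RxxD` submotif upstream of the A-site that mediates product inhibition.
cdgScan reports `iSitePresent` when the terminal D of an `RxxD` lies
exactly 5 residues before the first residue of the A-site block of a full
motif match (or of the best partial alignment for degenerate domains).

## Notation decisions

Three points of the motif notation are genuinely open, and the package
fixes them as follows:

* **Spacer widths are exact.** `x(7)` means exactly seven residues; only
  spacers written as ranges (`x(55,58)`, `x(20,30)`) are flexible. The two
  notations are distinguished deliberately in the source material for these
  motifs, so the exact reading is the faithful one. The consequence is that
  real domains with small indels inside a long spacer (alignments of real
  GGDEF domains do show occasional gaps) can be under-called ACTIVE; on
  synthetic data this cannot happen by construction.
* **The EAL `E_XX_E` segment** is read as E, two one-residue spacers, E
  (`E x(1) x(1) E`), consistent with the X-as-spacer convention used
  everywhere else in the motif.
* **The I-site anchor** is the start of the A-site block, not the motif's
  R: "five residues upstream" is measured from the first residue of
  `[GSA]G[DE]EF` to the D of `RxxD`. The rule is positional and exact —
  offsets of 4 or 6 do not fire, which the tests check explicitly.
* **The ambiguity letter X** in an input protein never satisfies any
  residue class (conservative calling), but passes freely through spacers.

The scanner itself compiles each spacer-width combination to a fixed-width
regular expression evaluated with a zero-width lookahead, so overlapping
matches at every start position are enumerated. The test suite checks this
implementation against an independent positional brute-force oracle —
every (start, width) pair verified residue by residue — exactly, on 1,000
random sequences per motif.

# Domain location

Activity classification presupposes a located domain. cdgScan takes domain
locations from an external hit table (hmmscan `--domtblout`, or a generic
five-column TSV), filtered at a configurable E-value threshold (default
`1e-5`; census publications rarely state the cutoff used by web services,
so this is explicit and adjustable). Domain names map to canonical types
through a user-extensible alias table (CDD and Pfam names drift). When no
table is available — notably for synthetic fixtures — a heuristic locator
places a domain wherever the motif's best partial alignment reaches a
minimum fraction of matched essentials (default 0.6, deliberately
permissive so degenerate domains still surface for classification; about a
quarter of GGDEF proteins in a typical rhizobial genome lack the full
motif), padded by a 15-residue flank.

Overlapping same-type hits are resolved greedily by score (lowest E-value,
or highest match fraction; ties by earlier start), which selects the
lexicographically best non-overlapping subset — the tests verify this
against exhaustive subset enumeration for random hit sets. Overlaps between
*different* types are kept: GGDEF-EAL tandem proteins are the norm, not an
artifact.

# Census semantics

Per protein, each domain type is ABSENT (no hit), ACTIVE, or DEGENERATE;
a protein with several same-type hits is ACTIVE if any instance is (one
functional catalytic site suffices biologically, and censuses count
proteins, not domains). The four panel categories are:

* DGC-only: GGDEF ACTIVE and EAL not ACTIVE — this includes proteins with
  a *degenerate* EAL domain, matching the experimentally observed pattern
  of active cyclases carrying dead PDE domains;
* PDE-only: EAL ACTIVE and GGDEF not ACTIVE;
* bifunctional: both ACTIVE;
* PilZ-like: PilZ ACTIVE, tallied independently (it may intersect the
  catalytic categories, as census figures plot it as a separate series).

Both the activity-filtered layer and raw domain-presence totals
(`ggdef_total`, `eal_total`, `pilz_total`) are reported, because published
per-strain counts do not always say which layer they use; with both
recorded, either reading is recoverable. Panel summaries use the sample
standard deviation (n−1); a single genome reports `NA`.

# Upstream intergenic GC

The upstream intergenic region of a gene is the maximal run of positions
immediately 5′ of its translation start (on its own strand) not covered by
any other annotated gene on either strand — "intergenic" is taken literally
as *between annotations*, so shared divergent promoters are included. No
maximum length is imposed; none is stated for this statistic in census
practice. Circular replicons wrap across the origin, and the tests verify
wrap handling by rotating the replicon so the same region becomes
contiguous and re-extracting. A neighbor that abuts or overlaps the start
yields a zero-length region, which is excluded from group statistics.

GC content is `100 * (G + C) / (A + C + G + T)` — N bases are excluded from
both numerator and denominator so draft-genome ambiguity does not bias the
percentage. Baselines are computed over the *full* nucleotide sequence of
the genome or one replicon (not averaged over genes).

The comparison of a gene group against a baseline is a one-sample,
two-sided t-test of the group's per-gene values against the fixed constant.
A two-sample reading (per-window genome values versus group values) is
possible in principle; the one-sample form matches comparing a set of genes
to a single quoted replicon average and is the package default. Degenerate
inputs (n &lt; 2, or values constant to machine precision) are reported as
not-available rather than as spurious infinities.

# Expression summaries

RPKM is computed per cell as
`count / ((length_bp / 1000) * (library_total / 1e6))`. The library total
defaults to the column sum of the supplied count table: once counting is
restricted to annotated protein-coding genes, totals beyond those genes are
no longer recoverable downstream, so the column sum is the honest default
(a per-library override is available). A zero-total library yields an
all-NA column with a warning. Note that because RPKM rescales each library,
a condition effect shared equally by all genes is normalized away; only
differential structure across genes survives, which is the intended
behavior of a within-library unit.

The variance partition is the classical two-factor factorial decomposition
`SS_gene + SS_condition + SS_interaction + SS_residual = SS_total`,
computed via `stats::aov` on a balanced complete design (the same replicate
count r ≥ 2 per condition; unbalanced input is rejected with advice to
subsample rather than silently switching to a Type-II/III decomposition).
Percentages are `100 * SS_x / SS_total`; for balanced designs they sum to
100 exactly, and the suite verifies the components against a term-wise
summation oracle. The ANOVA response is the expression value as given
(RPKM untransformed) by default — no transform is assumed — with a
`log2(x + 1)` option for users who prefer variance stabilization.

Pairwise gene comparisons use the pooled residual mean square
(`t = (m_i - m_j) / sqrt(MSE * 2/r)`, residual df), Bonferroni-corrected
with one family per condition: all gene pairs *within* one condition form a
family, and families are corrected independently. The alternative —
multiplying by pairs × conditions — is stricter; the per-condition family
is the reading consistent with comparisons performed "under each
condition", and is what the package implements.

# The synthetic-data generator

The generator exists so every pipeline stage is testable offline with known
truth:

* `makeProtein()` plants one motif instance (ranged-spacer widths drawn
  uniformly) in a uniform-random background of the 20 standard amino
  acids; listed essentials are mutated to uniformly chosen disallowed
  residues. Uniform background maximizes the detectability of accidental
  matches in tests; a genome-like composition can be supplied instead.
  Rejection sampling (capped at 1,000 attempts) guarantees clean truth
  labels: no accidental full-motif match in the background, the planted
  alignment is the best partial alignment within its span with exactly the
  planted mismatch set, and the I-site flag reflects the plan rather than
  background luck. Masking the background was rejected as an alternative
  because it distorts residue composition.
* `makeGenome()` lays out genes separated by intergenic spacers of
  controlled length (default 500 bp, matching the scale at which GC
  recovery is tested) and base-wise Bernoulli GC content; coding sequences
  are deterministic reverse-translations (bacterial code, table 11, TAA
  stop) of the planted proteins, written identically as GenBank and as
  GFF3 + FASTA.
* `makeCounts()` draws negative-binomial counts around cell means
  `exp(grand + gene + condition + interaction)` in a balanced design with
  r replicates per condition (defaults emulate the scale of a
  three-condition, three-replicate bacterial RNA-seq comparison of eight
  cyclase genes).

What passing the planted-truth tests shows — and what it does not: because
the generator itself rejects backgrounds that would confuse the labels, the
planted-truth criteria validate the *pipeline plumbing* (location,
sub-sequence extraction, classification, tallying) rather than the
scanner's correctness on arbitrary input. The scanner's correctness is
established independently by the exhaustive brute-force oracle and the
boundary tests. Equally, synthetic genomes have no overlapping genes, no
indels inside motif spacers, no pseudogenes, and uniform spacer lengths;
recovery rates of 100% here say nothing about sensitivity on real
proteomes, where the exact-spacer reading is conservative by design.

# Numerical and scale choices

* Protein coordinates are 1-based inclusive throughout (the hmmscan
  convention); genomic coordinates are 1-based forward-strand.
* Sequences shorter than 10 residues cannot be meaningfully classified and
  raise an error; sequences of 10 up to one below the motif's minimal
  width are classified (necessarily DEGENERATE).
* Zero total SS in the ANOVA (a constant table, detected at a relative
  tolerance of 1e-10) yields NA percentages with a warning.
* The test suite runs the scanner-oracle comparison at 1,000 random
  sequences of 200–400 aa per motif, planted-truth recovery at 500
  proteins per motif with 0–3 mutations, censuses on 20-gene two-replicon
  genomes, and GC recovery on 600-bp spacers — sizes chosen to exercise
  every ranged-spacer width and wrap case many times over while keeping
  the default check fast.

# Known limitations

* No probabilistic scoring: matching is exact set membership, not a PSSM
  or profile HMM, so near-miss residues score identically to distant ones.
* HD-GYP phosphodiesterases are not modeled (no activity motif is defined
  here for them).
* Compound (join) CDS locations in GenBank input — origin-spanning genes —
  are skipped with a warning rather than normalized.
* The heuristic domain locator reports at most one domain instance per
  motif per protein (the best alignment); tandem same-type domains require
  an external hit table.
* MucR binding is characterized only through the %GC statistic; no binding
  motif model is included.
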