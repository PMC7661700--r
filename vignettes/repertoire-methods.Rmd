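---
title: "Methods: simulating and annotating single-cell IgG heavy-chain repertoires"
author: "scIgRep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and annotating single-cell IgG heavy-chain repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scIgRep)
```

## The problem

Antibody heavy chains are assembled somatically by V(D)J recombination: one
each of the germline IGHV, IGHD and IGHJ gene segments is joined, the joined
ends are trimmed by exonucleases, and non-templated N nucleotides are inserted
at the V--D and D--J junctions. The resulting junction, read as the third
complementarity-determining region (CDR3), is effectively unique per clone, so
identical junctions in different cells indicate a shared clonotype. After
antigen exposure, activation-induced deaminase (AID) introduces somatic
hypermutation (SHM), preferentially at the degenerate hotspot motifs RGYW and
WRCY (R = A/G, Y = C/T, W = A/T) and concentrated in the CDRs.

Studies of immunoglobulin expression outside B cells -- here, kidney proximal
tubular epithelial cells profiled one cell at a time by nested PCR, colony
cloning and Sanger sequencing -- ask whether such cells carry genuine
rearrangements and how their repertoire differs from the B-cell baseline:
segment usage bias, clonal sharing across individuals, SHM structure, CDR3
length diversity. `scIgRep` implements that entire analysis as reusable,
tested code, together with a repertoire simulator that generates synthetic
single-cell data with the same statistical structure, so every stage can be
validated without access to sequencing data.

## The germline reference

All simulation and annotation happens against a `GermlineReference`: a
`DNAStringSet` of segments plus per-segment metadata (class, family, genomic
order along the IGH locus, region boundaries). Coordinates are 0-based
half-open throughout; conversion to 1-based happens only at report
boundaries. Region delimitation is IMGT-like: V segments carry FR1/CDR1/FR2/
CDR2/FR3 starts plus the position of the conserved second-Cys codon; CDR3
runs from the codon after that Cys to the codon before the conserved J-segment
Trp, with both anchors excluded from the CDR3 string itself. Genomic order is
encoded as an integer rank with 0 = most 3' (JH-proximal), which is what the
locus-position statistic below consumes.

The packaged set (28 V across families VH1--VH7, 15 D across DH1--DH7,
IGHJ1--6, one allele per gene) uses IMGT-style names and real-locus ordering,
but its sequences are synthetic: they are generated deterministically with the
IMGT architecture (no stop codons through FR1..FR3, Cys/Trp anchors in place,
family members ~6% diverged from a family backbone). Public germline
databases cannot be redistributed here, and gene-level analyses only need a
consistent, well-formed reference; the `germline_synthetic.*` filenames and
documentation flag this explicitly. Allelic variation is not modeled because
the analyses are gene-level.

## The simulator

`simulateRepertoire()` emulates the data a single-cell colony-sequencing assay
produces. Per cell it draws 1--3 distinct rearrangement patterns
(probabilities 0.868/0.110/0.022 under the epithelial preset, 0.972/0.028/0
under the B-cell preset) and 4--8 cloned colony sequences, each colony an
exact copy of its pattern (an optional per-base colony error rate exists and
defaults to 0, because identical colony sequences are what the pattern
deduplication assumes).

A new clone is assembled as

```
V[0, |V|-v_trim3) + n1 + D[d_trim5, |D|-d_trim3) + n2 + J[j_trim5, |J|)
```

with segments drawn from the preset usage vectors, trims uniform on
0..`trimMax` (default 5 nt, a typical exonucleolytic scale), and N-region
lengths geometric with mean 6 nt (no junction-length distribution is published
for this assay; the geometric default is a deliberately minimal engineering
choice, uniform over ACGT, no P-nucleotides). The D--J insert is padded by
0--2 bases so the conserved J Trp lands in the V reading frame, and junctions
that would create an in-frame stop are resampled -- segment identities are
kept across those retries so rejection cannot bias usage frequencies.

A configured fraction of rearrangements (5.8% epithelial preset, 3.9% B-cell
preset) is then deliberately made nonfunctional, half by replacing an in-frame
codon between FR2 and the J end with a stop, half by shifting the D--J
N-region length by one base. Stop-codon substitutions are recorded as
mutation records so the truth table always reconstructs the emitted sequence
exactly -- that reconstruction is a tested invariant.

SHM applies per-position substitution probabilities proportional to
`hotspotBias` on positions inside RGYW/WRCY windows of the pre-mutation
sequence and `cdrBias` (default 3) on CDR positions, scaled so the expected
per-sequence rate equals a per-sequence target drawn from 2.9--20.5%. The
epithelial preset uses a mixture with 60% of its mass on 5--10%, matching the
reported distribution shape; the B-cell preset draws uniformly. The default
`hotspotBias` is calibrated at configuration time by solving
`b f / (b f + 1 - f) = 0.9` with `f` the mean hotspot-masked fraction of the
reference V segments, so that about 90% of mutations fall in hotspot windows,
the level reported for this assay. Mutated bases are uniform over the three
alternatives; insertions and deletions are not modeled because the analysis
treats substitutions only.

Clonal sharing is injected structurally rather than mechanistically: with
probability `pSharedClone` (0.10 in the epithelial preset) a cell reuses a
clone from a global pool spanning both donors, which reproduces
identical-junction sharing within and across donors without asserting a
biological mechanism. All randomness flows from a single `set.seed()` on the
config seed; reruns are byte-identical.

## The annotator

`annotateRepertoire()` is the in-package replacement for an IgBLAST-style
assignment step. Alignment is optimal local alignment
(`Biostrings::pairwiseAlignment`) under fixed scoring -- match +2, mismatch
-1, gap open -4, gap extend -1 -- chosen to mimic standard immunogenetic
aligner defaults while remaining fully documented and reproducible. V is the
best-scoring V segment; J is the best J constrained strictly downstream of
the V match; both require score >= 40 (a configurable floor; failures are
recorded per sequence, not fatal, mirroring per-cell positive/negative
bookkeeping). Ties break deterministically by score, then lower genomic
rank, then name. D is searched only in the V--J insert and requires at least
5 consecutive exact matches, else `"unassigned"` and the whole insert is
reported as one junction string.

One numerical subtlety is worth stating: a locally optimal alignment happily
extends a trimmed germline end a few bases into the non-templated junction
whenever that gains score, which would both misplace the junction and
manufacture spurious mutation calls. The junction-facing alignment ends (V
3', J 5') are therefore trimmed back until they terminate in four consecutive
matched columns. Pure-match chance extensions remain -- if the first N base
happens to equal the next trimmed germline base, that base is attributed to
the segment. This attribution ambiguity is intrinsic to junction analysis,
affects only junction-adjacent bases, and is why the test suite asserts exact
junction recovery only where it is theoretically guaranteed (zero trims) and
asserts mutation-call agreement away from junctions.

Productivity follows the standard rules: `out_of_frame` when the conserved J
Trp codon is not in the V reading frame, `stop_codon` when an in-frame stop
occurs between the V FR2 start and the J end, `no_j_anchor` when the Trp
cannot be located, productive otherwise. The reading frame is taken from the
modal aligned offset over V columns, which tolerates an occasional spurious
one-base gap in a hypermutated alignment.

Mutations are mismatches within germline-aligned columns only -- N-region
bases are never counted -- over the FR2-to-JH window, because that is the
window this assay amplifies (the forward primer sits in FR2). The mutation
frequency is mismatches / aligned germline columns x 100, and a sequence is
flagged mutated at >= 2.0%, the conventional cutoff separating mutated from
unmutated variable regions. Each mutation carries its region label (CDR3 for
the germline-aligned junction columns) and a hotspot flag computed on the
germline segment context, so a mutation can neither create nor destroy its
own hotspot status.

Colonies of one cell collapse to patterns keyed by
`(v_call, d_call, j_call, n1, n2)`. Two colonies differing only by SHM count
as one pattern; whether that matches every author's convention is not
documented anywhere we know of, but it is the only key that is stable under
the assay's own noise, and it is applied consistently.

## Repertoire statistics

Usage tables count each distinct cell pattern once, never per colony, so
clonal resampling of colonies cannot inflate a gene's frequency; `unassigned`
D calls are excluded from D usage and reported separately. Family usage is
compared between repertoires with Pearson's chi-square on the 2 x k count
table (`stats::chisq.test`, no continuity correction, df = k-1), with a hard
error if any margin is zero. The CDR-versus-FR comparison uses per-sequence
paired rates (region mutations / aligned region length, CDR = CDR2 plus
germline-aligned CDR3 columns, FR = FR2 + FR3 + FR4) and a paired t
statistic implemented from its closed formula `t = mean(d)/(sd(d)/sqrt(n))`
on n-1 df -- deliberately hand-written so it is unit-verifiable, and checked
against `t.test` in the suite. The degenerate all-zero-difference case
returns t = 0 rather than NaN.

Shared-rearrangement detection groups patterns on the full junction key and
reports every key held by two or more cells, with a `cross_donor` flag and
deterministic ordering; pair counts, when needed, derive as `choose(m, 2)`
from set sizes, the set-level report being primary. CDR3 length diversity is
summarized by a least-squares Gaussian fit `A exp(-(x-mu)^2/(2 sigma^2))` to
the amino-acid length-frequency histogram (Levenberg-Marquardt via
`minpack.lm::nlsLM`; deterministic initialization A = max frequency, mu/sigma
= weighted moments; R^2 = 1 - SS_res/SS_tot). A diverse repertoire yields
R^2 near 1; clonal dominance pushes it down -- the package's simulated
presets reproduce this contrast qualitatively (about 0.92 versus 0.60 on the
acceptance run), which is the intended reading; the printed real-data values
are not reproducible without the underlying sequences. The genomic-position
statistic is the usage-weighted mean normalized rank in [0, 1] (0 = fully
3'-proximal), and is lower for the restricted epithelial preset than for the
diverse baseline.

Two hotspot accounting conventions exist: the default counts a mutation as
hotspot when it falls anywhere inside a matching 4-mer window (matching how
pooled "mutations in the motif" percentages are usually reported), and
`aid_target` restricts to the mutable G of RGYW / C of WRCY. The aid_target
mask is provably a subset of the default, a property the suite checks.
Pooled fractions are reported as the primary statistic, per-sequence
fractions alongside; zero mutations give a missing value, never 0.

## What the simulator does and does not establish

Passing the round-trip suites shows the annotator recovers what the generator
planted under the generator's assumptions: substitution-only SHM, no
insertions or deletions, no PCR chimerism, no sequencing error by default,
one allele per gene, and germline segments that are mutually distinct at
random-sequence levels. Real Sanger data violates several of these mildly
(real V genes within a family are more similar, so V-call accuracy on real
data will be lower than the near-perfect recovery seen here), and the
synthetic reference cannot validate allele-level behavior at all. The
statistics layer, by contrast, is exercised on exact worked examples from
published count tables and is independent of those assumptions.

## Problem sizes and budgets

The test suite simulates desk-scale repertoires: 500 sequences for the
assignment-accuracy properties, 5000 for usage recovery, 1000 cells for the
patterns-per-cell recovery, 1000 replicates for the chi-square type-I check,
and 1000 random sequences for the hotspot-scan oracle -- sizes chosen so each
property is measured at 3-standard-error resolution while the whole suite
stays in a few minutes. The acceptance script runs the full pipeline at the
study's own scale (2 donors x 50 cells, 4--8 colonies per cell, about 600
sequences).

## Known limitations

* Junction-adjacent bases are attributed by alignment extension, so recovered
  N strings can differ from the generative truth by a few bases; clonotype
  keys remain internally consistent.
* The D floor of 5 exact matches means short retained D segments go
  unassigned, and chance 5-mers can (correctly, per the rule) support a
  different D than the generative one.
* Shared-clonotype detection on annotated data requires the junction strings
  of both cells to be called identically, so a hypermutated shared clone is
  detected only when neither cell's SHM touched the junction region or its
  attribution-sensitive flanks. With the default 10% sharing rate and 5--10%
  SHM, most injected sharing is therefore invisible at the annotated level --
  the identical-junction criterion is intentionally conservative, exactly as
  it is when applied to real data. The truth table makes the injected
  sharing fully observable for validation.
* Per-sequence mutation frequencies are measured over ~250 aligned columns,
  so the measured 5--10% band is smeared relative to the generative rates by
  binomial noise of about 1.6 percentage points.
* The paired t-test assumes approximate normality of per-sequence rate
  differences; with hundreds of sequences this is benign, but for very small
  repertoires a sign-flip test would be more defensible.
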