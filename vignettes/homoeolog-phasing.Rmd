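---
title: "Separating homoeologous gene copies: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating homoeologous gene copies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeophase)
```

## The problem

An allotetraploid genome carries two homoeologous copies of every
single-copy nuclear gene, and each copy carries up to two alleles — four
haplotypes per locus. PCR amplifies all of them together, so both Sanger
chromatograms and short-read amplicon libraries mix the copies. Using such
mixed sequences in phylogenetics confounds orthology, which is why copy
separation must happen *before* tree building.

`homeophase` implements two complementary phasing routes:

* **amplicon short reads** (`sep_assem()`): a mapped read alignment,
  exported as FASTA with the reference row removed, is separated into
  `copy_number` full-length copy sequences;
* **Sanger clone sets** (`phase_clone_set()`): cloned amplicons are sorted
  into copies and alleles after removing PCR-chimeric clones.

Around these sit frame QC (`find_indels()`, `find_unexpected_stops()`),
site-distance diagnostics (`site_distances()`,
`required_read_length()`), and a ground-truth simulator
(`simulate_locus()` and friends) that makes every stage testable without
any external data.

## The read-separation model

The signal that separates copies is the *copy-distinguishing site*: an
alignment column where the two homoeologs carry different bases. With `k`
equally amplified copies such a column shows a minor-state frequency near
`1/k` (50% for a tetraploid). An *allelic* site — the two alleles of one
copy differing — shows roughly `1/(2k)` (25%), because only half of one
copy's reads carry the variant. Sequencing error sits far below both.
`detect_variable_sites()` therefore classifies a column by its minor-state
frequency:

* below `max(noise_freq, 3/coverage)` — noise, excluded. The floor of
  0.05 sits an order of magnitude above the MiSeq substitution error rate
  (~0.1–1%), and the `3/coverage` term guards low-coverage columns where a
  frequency estimate from one or two reads is meaningless.
* at least `copy_site_freq` (default 0.35, between the allelic 0.25 and
  the copy 0.5 expectation) — copy-distinguishing.
* in between — allelic.

The gap character is a countable state *inside* a read's mapped span (a
deletion allele — decayed copies really do carry them) and missing data
outside it; `N` never votes anywhere.

### Windows, clustering, linking

Reads of length `read_length` are clustered within sliding windows of that
same width, advancing by `read_length − overlap` columns (defaults 300 and
225, i.e. step 75). The last window is right-anchored at the alignment end
so the 3′ tail keeps full width. Within a window, each read's *signature*
is its bases at the window's copy-distinguishing sites, and reads are
partitioned into `k` groups minimizing total mismatch to the group
consensuses at those sites. Windows with at most 15 distinct signatures
(and `k = 2`) are solved exactly by enumerating all signature
bipartitions — at that size exhaustive search is cheap and removes any
dependence on a heuristic's local optima; larger windows use weighted
average-linkage agglomeration followed by consensus reassignment and
steepest single-signature moves. Everything is deterministic: signatures
are processed in canonical (sorted) order, so the result is invariant to
the input order of the reads.

Consecutive windows are then linked through their `overlap` columns. A
junction is `linked` when the overlap contains a copy-distinguishing
difference between the cluster consensuses, or when at least
`min_link_support` reads span the nearest distinguishing sites on either
side and agree on one pairing. Otherwise it is `ambiguous`: the assembly
is still completed (with an arbitrary, recorded pairing) but the chimera
report flags it — the flag replaces the manual inspection a careful analyst
would perform. `verify_assembly()` re-checks the finished copies
independently: for every adjacent pair of copy-distinguishing sites it
counts reads concordant with one copy's phase versus reads crossing
phases.

### Consensus and allele ambiguity

Within one copy's cluster the two alleles are expected near 50/50, so a
column whose minor base frequency falls inside `allele_freq_band`
(default 0.30–0.70) is written as the IUPAC merge of the bases involved
(R, Y, M, K, ...). Short reads usually cannot phase alleles — the
distances between neighboring allelic sites routinely exceed any
short-read length — so ambiguity codes are the honest representation.
Below the band the minority is treated as error and the major base wins.

Copies are labeled "Copy I", "Copy II", ... arbitrarily except that the
sequence with more gap columns (more deletions) takes the later label,
matching the convention that the decayed copy is "Copy II".

## Clone phasing and chimera detection

Sanger clones are single molecules, so each clone is one haplotype — or a
PCR template-switching artifact. On the alignment reduced to its variable
columns, clones are grouped by signature identity within `max_mismatch`
(default 1: a Sanger error on a clone is rare; use 0 for error-free data).
A minority group is *chimeric* when its consensus is farther than
`max_mismatch` from every accepted haplotype yet is explained within
`max_mismatch` by a single crossover between two accepted consensuses;
the crossover is reported as the interval between the flanking discordant
sites. Only single-crossover chimeras are modeled — PCR template switching
most often produces one junction — and anything needing more crossovers
falls to `unassigned` with a warning rather than being forced into a
group.

Surviving groups are paired into copies by minimum inter-consensus
distance, which works because intra-copy allele divergence is far smaller
than inter-copy divergence. Allele sequences are reported when each
allele group is supported by at least two clones; the copy consensus
always carries IUPAC merges at allele differences.

## Frame QC and the read-length bound

`find_indels()` reports maximal gap runs relative to a reference copy,
`find_unexpected_stops()` scans gap-compacted codons so a frameshifting
deletion propagates downstream exactly as it does biologically, and both
report 1-based alignment columns ("628–634" style). An IUPAC-ambiguous
codon counts as a stop only when every resolution is one.

`required_read_length()` turns a site-distance profile into a design
number: a linking read must cover the widest inter-site gap plus both end
sites within its usable span, so the bound is
`ceiling((max_gap + 1) / overlap_fraction)` with `overlap_fraction`
defaulting to 0.75 (the 225/300 linking geometry). Copy pairs typically
show gaps under ~150 bp — comfortable for 300 bp reads — while allele
pairs can exceed 800 bp, which is why allele phasing needs long reads.

## What the simulator does and does not emulate

`simulate_locus()` draws an ancestor uniformly over A/C/G/T and diverges
copies (rate `copy_divergence/2` each) and then alleles
(`allele_divergence/2`) under a uniform substitution model without rate
heterogeneity: the tests need controlled site density, not evolutionary
realism. Defaults describe the study conditions of a RAG1-like amplicon —
1500 bp, 2% copy divergence, 0.2% allele divergence, 300 bp reads at 100×
with 0.2% per-base error. Choices worth knowing:

* **Boundary-anchored reads.** Shearing a PCR amplicon leaves every
  molecule's terminal fragments ending exactly at the primer-defined
  boundaries, so mapped alignments cover the terminal columns; the
  simulator anchors `boundary_frac` (default 10%) of reads at the ends to
  reproduce that. Without it the extreme columns would be read-free, which
  real amplicon alignments are not.
* **Balanced clone sampling.** Non-chimeric clones are spread as evenly
  as possible across the four haplotypes. Real clone picking is closer to
  multinomial; the balanced design makes "did the method recover the
  haplotypes present" testable separately from "did sampling happen to
  miss one".
* **Chimeric clones differ from both parents.** The crossover is placed
  uniformly between the parents' differing sites, never outside them — a
  recombinant identical to a parent is not a chimera in any observable
  sense.
* **ORF mode.** With `orf = TRUE` no stop triplet occurs in any reading
  frame of any haplotype (the ancestor avoids TA/TG dinucleotides and
  mutations that would create stops are resampled), emulating purifying
  selection; planted stops and deletions are then the *only* frame
  defects, which is what makes the frame-QC round-trip exact.
* **Sub-seeds.** One master seed drives everything; read and clone stages
  derive fixed offsets from it so that stages are independently
  reproducible.

Passing tests on these simulations show the algorithms do what they claim
under their stated assumptions. They do not show robustness to mapping
artifacts, indel-rich alignments beyond planted deletions, coverage
dropout, or PCR amplification bias — `skew` exists to explore the latter,
but no test asserts recovery under strong skew.

## Numerical and degenerate-input choices

* Ties in any majority vote resolve to the lexicographically first state;
  together with canonical signature ordering this makes byte-identical
  outputs reproducible from a seed.
* Zero copy-distinguishing sites yield a *single* consensus plus an
  explanatory notice — never `k` fabricated duplicates. Identical chains
  collapse the same way.
* A locus whose widest invariant stretch exceeds the read length cannot
  be phase-linked by any read: the junction is flagged `ambiguous`, the
  verdict `suspect`, and the completed sequence must be treated as
  unphased across that junction. Under the default study conditions
  (~30 distinguishing sites over 1500 bp) roughly 4% of random loci
  contain such a stretch, so occasional flagged assemblies are expected
  behaviour, not failures.
* Coverage below `min_site_coverage` anywhere produces a notice with the
  affected column ranges; the columns are excluded from site detection.

## Problem sizes used in the test suite

Unit tests run on 300–800 bp loci at 40–60× coverage; the end-to-end
checks use the full study conditions (1500 bp, 100×, 20 seeds for read
phasing, 50 seeds for clone phasing, 200 random instances for the
exhaustive-clustering comparison). These sizes keep the whole suite to a
few minutes while leaving every code path exercised at realistic depth.
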