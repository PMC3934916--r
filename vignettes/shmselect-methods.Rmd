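---
title: "Methods: mutation analysis and the antigen-selection test"
author: "shmselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation analysis and the antigen-selection test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmselect)
```

## The scientific question

Antigen selection in the germinal center favours B cells whose somatic
mutations improve antigen binding. Because binding is mediated by the
complementarity-determining regions (CDRs), selected lineages accumulate an
excess of replacement (amino-acid-changing, R) mutations in CDR1 and CDR2
relative to what an unselected mutation process would deposit there. This
package quantifies that excess for every sequence in an amplicon repertoire
and asks, per sequence: *is the number of CDR replacement mutations larger
than a random mutation process would plausibly produce?*

## The random-mutation model

For a sequence with `Mv` total mutations in its IGHV gene, the number of
CDR replacement mutations `R_CDR` under no selection is modelled as

$$R_{CDR} \sim \mathrm{Binomial}(M_v,\; p), \qquad p = 0.26 .$$

The constant `p = 0.26` is the probability that a somatic mutation is both
located in the (broadened) CDR1/CDR2 and non-synonymous, as estimated from
non-productive rearrangements — sequences that cannot have experienced
selection, so their mutation spectrum reflects the raw targeting of the
hypermutation machinery (including hotspot biases, which concentrate
activity in the CDRs beyond what uniform-position mutation would give).

A sequence is flagged as *showing evidence of antigen selection* when its
`R_CDR` lies strictly above the one-sided 97.5% confidence limit of that
binomial: the threshold `k*(Mv)` is the smallest count whose exact upper
tail mass `P(X >= k)` is at most `alpha = 0.025`. Tails are computed by
exact summation of the probability mass function — with the mutation-count
filter capping `Mv` at 45, exact enumeration is cheap and avoids any
normal-approximation ambiguity. Consequences of the discreteness:

* `k*(1) = 2`: a sequence with a single mutation can never be flagged
  (`P(X >= 1) = 0.26 > 0.025`), and unmutated sequences carry no evidence
  by construction.
* The achieved per-`Mv` false-flagging rate is below 2.5%, so the test is
  conservative; pooled over sequences, more than 97.5% of null sequences
  stay unflagged.
* Points exactly *on* the plotted boundary (the largest count still inside
  the confidence band) are not flagged. `on_boundary_selected = TRUE`
  switches to the inclusive reading; whether boundary-equal points should
  count was a genuinely open reading, and the strict rule is the default
  because the flag is meant to mark exceedance of the limit.

Two further open choices were fixed as follows. `p` is applied uniformly
across V genes rather than per gene, matching the single published
constant; per-gene CDR fractions vary little under the broadened CDR
definition. And the group-level comparison of selection percentages uses
the chi-square test without Yates continuity correction (`yates = TRUE`
restores it); at the dataset sizes involved the correction does not change
any qualitative conclusion.

## Region definitions

CDR boundaries differ between the Kabat and IMGT conventions. To avoid
scoring a plausibly antigen-contacting position as framework, the analysis
uses a *union* scheme: a position belongs to CDR1 (or CDR2) if either
convention places it there. Boundaries are supplied per gene as a TSV of
0-based, half-open intervals in ungapped V-gene coordinates — they are an
input, not a constant of the package, because curated boundary sets cannot
be redistributed with it. CDR3 is never part of the region map: the
statistic is defined on V-gene (CDR1 + CDR2) mutations only, and mutations
3' of FR3 are excluded from `Mv`.

## Mutation classification

Each aligned mismatch is classified one at a time: the observed codon is
the germline codon with only that mutation applied, translated in the
reading frame fixed by the germline V annotation; the mutation is R when
the amino acid changes (a created stop codon counts as R). Judging
mutations one-at-a-time rather than against co-mutated neighbouring bases
is the convention matching a per-mutation R/S count; co-mutated codons are
rare below ~10% mutation load, and the alternative would make each call
depend on the (unknowable) temporal order of mutations. Mutations in
codons partially truncated by the 5' primer cannot be classified against a
complete observed codon and are excluded from `Mv` (tallied per sequence
in `n_excluded`); mismatches involving an ambiguity character are likewise
excluded.

## The filter cascade

Raw amplicons pass through three nested datasets:

* **Dataset A** — unique sequences after orientation normalisation and
  deduplication, excluding sequences that could not be V-aligned, missing
  more than 45 5' V nucleotides, containing ambiguities, containing V-gene
  indels, or carrying more than 45 apparent V mutations. "More than 45" is
  read strictly: 45 is kept, 46 removed. The published account does not
  state the order in which these rules were applied, so the cascade fixes
  the order above and reports a per-rule removal tally (each sequence
  counted under the first rule it fails).
* **Dataset B** — the subset of A observed as both a forward and a reverse
  read. Agreement between independent reads of opposite orientation makes
  residual sequencing error very unlikely.
* **Dataset C** — one sequence per clone. Clones share V, D and J gene
  calls and a CDR3 key (amino-acid translation by default; nucleotide
  keying via `key = "nt"`); the dominant member is the one with the
  highest replicate count, ties broken by longest sequence then
  lexicographic id. Sequences without a CDR3 call form singletons.

Duplicate detection deliberately uses *exact* identity over the shared
span (substring matching after orientation normalisation) rather than a
similarity tolerance: amplicons differing only in 5' primer truncation
collapse, with the longest member retained, while any true mismatch splits
the pair — a tolerance would have had to be invented, and the downstream
bidirectional filter already absorbs near-duplicates caused by sequencing
error. A consequence is that deduplication is idempotent.

Stop-codon-containing and out-of-frame sequences are *retained* in all
three datasets and only tallied: they are legitimate members of an
expressed repertoire's cDNA pool at low rates, and their prevalence is
itself the quality signal the tallies track.

## Annotation

V genes are assigned by best Smith–Waterman local alignment (match +5,
mismatch −4, gap open 25, gap extend 4) over the reference set, ties
broken by fewest mismatches then name. The relatively high gap-open
penalty reflects the error structure of the data: true indels shift the
reading frame and are always cheaper to represent with a gap, while
spurious gaps that shave a few mismatches off a heavily mutated ungapped
alignment become unprofitable. The local alignment is then extended along
its diagonal to the read and gene ends, so a mutation in the first or last
V base is recorded as a mismatch instead of being soft-clipped — without
this, terminal mutations silently vanish from `Mv`. J genes are assigned
the same way in the region 3' of the V match; D genes by the best ungapped
run of at least 5 consecutive identities inside the junction, with "no D"
allowed. CDR3 is extracted between the conserved V-end cysteine codon and
the J-region tryptophan motif (located as the first `TGGGG` in the J
reference). Reads whose best V score falls below 100 (20 net matching
bases) are marked unalignable and tallied. Isotype is called from the
CH1 constant-region primer sites with a tolerance of 2 mismatches — a dial,
not a published constant; the amplicons were physically isotype-specific
and the tolerance only guards against sequencing error in the primer site.

## What the synthetic repertoire emulates — and what it does not

The generator produces clonal VDJ rearrangements with the statistical
structure the pipeline's contracts assume: geometric replicate counts
(mean 5), an IgE-heavy isotype mix (58.2/31.6/10.2% IgE/IgG/uncertain,
the composition of the motivating amplicon pool), true mutation loads
uniform on 0–30, forward/reverse orientations with a 10% bidirectional
rate, geometric 5' primer truncation (mean 15 nt, capped at 60, so a small
tail exercises the offset filter), per-base substitution errors (10⁻³),
per-homopolymer-run indels (5×10⁻³ for runs of length ≥ 3, the 454 failure
mode), and occasional ambiguity characters (2% of reads). The two error
rates are documented placeholders of the right order of magnitude for 454
chemistry, not fitted values. Junctions carry 0–10 random N-nucleotides
per side of D; 95% of clones have junction lengths adjusted to preserve
the reading frame, and in-frame clones redraw junctions containing stop
codons, emulating the expressed-mRNA origin of real amplicons.

Mutations are placed by a two-stage draw that pins the marginal
CDR-replacement probability exactly: with probability `p` (0.26 under the
null, 0.45 under the "selected" mode) a mutation is drawn uniformly from
the (position, base) pairs that are CDR replacements; otherwise uniformly
from the complement. This is chosen over a mechanistic hotspot model
because the random-mutation model being tested is *defined* directly on
the CDR-replacement probability; hotspot structure is already folded into
the 0.26 constant.

Passing tests on this generator therefore show that the pipeline's
bookkeeping — alignment, region attribution, R/S calls, filters, the
threshold — is correct and calibrated, **not** that real 454 data meets
the model's assumptions. Features of real data deliberately not emulated:
flowgram-level error structure and quality scores, V-gene 3' exonuclease
trimming (the diagonal extension assumes the V gene runs to its reference
end; real junctions trim a few bases, which would misattribute a handful
of junction bases per read), germline polymorphism, hotspot-clustered
mutation positions, chimeras, and donor structure. One visible consequence:
because placed mutations are never purged by cellular selection, highly
mutated synthetic clones show stop codons at rates far above Table-style
real-data tallies — the tallies are still computed, but their absolute
values on synthetic data are not comparable to a real repertoire's.

The packaged germline reference is itself synthetic (8 V, 4 D, 4 J genes
with realistic FR/CDR geometry, generated by `make_synthetic_repertoire()`),
because curated germline databases are license-restricted. Analyses of
real data should supply a proper reference FASTA and boundary table.

## Problem sizes and reproducibility

All randomness flows from single integer seeds. The test-suite simulations
use 100–700 clones; the calibration checks use 2,000 placement draws per
mutation count for the binomial goodness-of-fit, 10,000 profiles for null
coverage, and a 2,000-clone noise-free repertoire for end-to-end recovery
of the 0.26 constant — sizes at which the binomial standard errors are a
few parts per thousand, so the ±0.02 acceptance band is dominated by any
systematic error, which is the point of the check. `scripts/acceptance.R`
re-runs the two calibration quantities from scratch at those sizes.

## Known limitations

* The annotator is a best-local-alignment tool, adequate for gene *calls*
  and mismatch lists against a known reference; it does not attempt the
  probabilistic junction partitioning of dedicated VDJ aligners, and
  D-gene calls inside short junctions are heuristic.
* Exact-substring deduplication will not merge replicates that differ by
  a single sequencing error; such reads survive to Dataset A as separate
  unique sequences (as in the motivating study design) and are handled by
  the bidirectional filter.
* The selection test treats sequences as independent; within Dataset A/B,
  clonal relatives violate this, which is exactly why group-level
  conclusions should be read from Dataset C.
* `p = 0.26` travels with the broadened CDR definition and the V-gene
  families it was estimated from; users analysing other loci or region
  definitions should supply their own constant.
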