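---
title: "Methods: diploid-similarity assignment of subgenome bases at HSPs"
author: "homeoassign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diploid-similarity assignment of subgenome bases at HSPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

An allopolyploid transcriptome with up to three homeologous subgenomes
is sequenced as a single pooled sample and aligned to an *in silico*
reference built by concatenating gene (transcript consensus) sequences
with 200-`N` spacers, so that no fragment can span two genes.  A
homeolog-specific polymorphism (HSP) is a reference position at which
the subgenomes carry different bases; a diploid relative's single-base
substitution (SBS) is a position at which that diploid differs from the
reference.  All coordinates are 1-based and inclusive, following SAM.

The central object is the **base pattern**: for one read pair, the
ordered sequence of (position, base) observations over the HSPs the
pair covers, with a support count of the read pairs showing exactly
that pattern.  A pattern is a haplotype fragment of one subgenome, and
the method's premise is that its percentage identity with each
diploid relative's bases at those HSPs identifies the subgenome of
origin, because each subgenome is far closer to its own relative than
to the others'.

Per gene the engine proceeds in five steps:

1. **Pattern construction.**  Both mates are read together.  A
   forward/reverse base disagreement at a shared HSP discards the pair
   (one mate must carry an error); an `N` (or a deletion) at an HSP
   drops that site only; identical patterns merge with summed support.
2. **Cleaning.**  For every *adjacent* pair of covered HSPs within a
   pattern, the supporting reads are counted against all reads carrying
   any base combination at those two positions; a pattern containing a
   base pair below the `min_pair_fraction` of that total is removed as
   error-supported.  Patterns whose (position, base) sites form a
   strict subset of another pattern's are then removed as embedded.
3. **Pattern-to-genome assignment.**  A pattern is assigned to every
   subgenome with which its identity is at least `min_identity`,
   identity being the matched fraction over *informative* diploid
   sites: unambiguous base, coverage at least `min_diploid_cov`.  A
   pattern assigned nowhere falls to the designated distant subgenome
   when one is configured, since it must originate from one of the
   subgenomes and poor diploid identity is the expected signature of a
   diverged relative.
4. **Iterative base assignment.**  Per subgenome, each sweep evaluates
   all still-open positions against the patterns live at sweep start:
   the position's candidate nucleotides are ranked by the maximum
   identity among patterns carrying them; a unique nucleotide, or one
   whose maximum strictly exceeds all others', is assigned; an identity
   tie across nucleotides leaves the position open.  After the sweep,
   patterns contradicting any assigned base are discarded, and sweeping
   repeats until nothing new is assigned.
5. **Rescue.**  Discarded patterns are re-scored against the already
   assigned bases (the diploids play no role): identity is the matched
   fraction over a pattern's sites at assigned positions.  They may
   fill open positions, and may replace an assigned base only when
   strictly better than the identity recorded for that base's source.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_pair_fraction` | 0.05 | fraction | step-2 error filter; "less than" is strict, so a pair at exactly 5% survives |
| `min_identity` | 0.5 | fraction | step-3 threshold; "at least", so exactly 50% is assigned |
| `min_diploid_cov` | 3 | reads | diploid informativeness (steps 3–4) and the `DIPLOID_LOW_COV` status |
| `min_mapq` | 20 | phred | alignment filter; MAPQ ≤ 20 removed |
| `min_variant_quality` | 20 | phred | variant filter; quality ≤ 20 removed |
| `min_variant_cov` | 3 | reads | variant filter |
| `spacer_len` | 200 | bases | `N` run between concatenated genes |

## Design choices where the procedure was open

Several points of the procedure admit more than one faithful reading;
the package fixes them as follows and tests the fixed semantics.

* **Pair-fraction denominator** (step 2): reads contributing any base
  combination at that specific adjacent position pair, not all reads of
  the gene — "the reads at these positions" scopes to the two
  positions.  "Adjacent" means adjacent among the pattern's covered
  sites: a read with an `N` at an intermediate HSP pairs its
  flanking sites directly.
* **Embedded-pattern support**: support of an embedded pattern is
  added to its containing pattern when exactly one maximal (itself
  non-embedded) container exists; with several competing containers
  the support's origin is ambiguous and it is discarded.  The filters
  run in the order error filter → embedding removal.
* **Step-4 sweep semantics**: all positions are evaluated against the
  pattern set as it stood at sweep start, and contradicting patterns
  are removed only between sweeps ("once all the positions have been
  checked"), making results order-independent within a sweep.
  "Contradicts" means carrying a different base at any assigned
  position.  A tie between patterns carrying the *same* nucleotide is
  harmless; a tie across different nucleotides blocks assignment.
* **Distant-genome identity**: a pattern routed to the distant
  subgenome with zero informative diploid sites has no defined
  identity; for step-4 ranking it is taken as 0, so it can never beat
  a nucleotide backed by measured identity, and equal-zero contests
  correctly yield no assignment.
* **Step-5 structure**: one deterministic pass per subgenome, patterns
  ordered by identity-versus-assigned (descending), ties broken by
  higher support then lexicographic pattern string.  Identities are
  computed once, against the step-4 assignments.  Each subgenome's
  rescue pool is the union of patterns discarded in *any* subgenome's
  sweeps, minus those still live in the subgenome at hand.  Whether
  rescue should iterate to a fixpoint is unspecified; a single pass is
  used because later passes could only act on identities measured
  against bases the pass itself just changed.
* **Uniqueness of mapping**: a record is uniquely mapped when it is
  not flagged secondary/supplementary and the aligner reports no
  alternative hit (`XA` absent, `X0` ≤ 1); when the aligner emits no
  such tags, surviving the MAPQ filter acts as the proxy.  The
  original filtering used unpublished custom code, so this is a
  documented package choice, not a reproduction.
* **Variant-list dialect**: four mandatory columns (sequence,
  position, reference base, IUPAC consensus) plus optional quality and
  coverage; a separate per-position depth table supplies diploid
  coverage at positions matching the reference.  A diploid IUPAC
  ambiguity code marks a heterozygous, uninformative position; a
  polyploid IUPAC code at an HSP enumerates the homeoallele set, so
  tri-homeoallelic HSPs (e.g. A/C/T = `H`) need no special casing —
  the engine only ever consumes per-read bases.

## The synthetic fixture generator

`sim_config()` describes a desk-scale emulation of a hexaploid
transcriptome experiment: a random ancestral gene set (default 50 genes
of 1–2 kb) diverges into three subgenomes at 2% per site; each
subgenome's diploid relative diverges a further 0.5%, except the
distant B relative at 2%; paired-end 75 bp reads (fragments
300 ± 30 bp) are drawn at 30× per subgenome with 0.5% uniform base
error; each (gene, subgenome) is silenced with probability 0.05.
Substitutions are uniform (Jukes–Cantor-like), with no indels or
transition bias — the engine is base-identity only, so substitution-
model realism does not affect correctness.  The silencing rate is a
round value in the range seen for homeolog expression bias; silenced
positions leave the evaluation denominator, so measured accuracy is
insensitive to it.

Alignments are emitted at their true coordinates (an idealised
aligner), so the test suite requires no external aligner; variant lists
come from a majority pileup that honours the standard filters (an HSP
needs ≥ 2 alleles, each in ≥ 2 reads and ≥ 20% of coverage; a diploid
call is ambiguous when two alleles qualify).  The synthetic caller has
no quality model and stamps all calls with quality 60; the quality
filter is exercised by unit tests on hand-built lists.  A
`uniform_coverage` mode tiles fragments deterministically so that every
position of every gene is covered in every subgenome; it is used where
"full coverage" must hold literally (the noise-free completeness check
and the planted worked-example gene), because random fragment starts
structurally under-cover gene ends — a sequencing artefact, not an
engine property.

What the generator does **not** emulate: mapping ambiguity and
mismapping (ideal coordinates), realistic expression levels and
quality-score profiles, PCR duplicates, splicing, indel polymorphism.
Passing tests therefore demonstrate the engine's correctness given
honestly aligned reads and externally called variant lists, not the
behaviour of any particular aligner/caller stack on real tissue.

## Evaluation accounting

`evaluate_against_truth()` mirrors a truth-line evaluation: per
subgenome, positions are first ignored when no truth base exists for
them (the analogue of positions a nullisomic–tetrasomic design cannot
resolve — in the simulator these are rare error-driven variant calls at
positions where the subgenomes agree), then when the subgenome was
silenced, then when the assignment table records an uninformative
diploid (`DIPLOID_LOW_COV`, `DIPLOID_AMBIGUOUS`).  The remainder is
*considered* and splits into correct / incorrect / unassigned, with
percentages over the considered denominator.

## Numerical and degenerate-input behaviour

The engine is deterministic: no step draws random numbers, every
ordering is explicit (positions ascending, pattern keys lexicographic),
and per-gene results are independent, so genes may be processed in any
order.  Zero-HSP genes yield empty output; genes without reads yield
all-status rows; an empty pattern set short-circuits each step.
Identity comparisons are exact fractions of small integers, so strict
">" tests at ties are safe.  Step 4 terminates in at most one
productive sweep per HSP position.

## Problem sizes used by the test suite

The suite validates the two step-2 filters and the step-4 sweeps
against independent brute-force implementations on 1,000 random
instances (≤ 5 HSPs, ≤ 8 patterns), checks perfect recovery on
noise-free uniformly covered fixtures (8 genes) and on a planted
100 bp worked-example gene with allele sets A/C, C/T, C/G, A/C/T, C/G,
and measures accuracy on ten seeded 50-gene fixtures at the default
conditions, requiring ≥ 90% correct per subgenome; these sizes keep
the whole suite at a few minutes on one CPU while covering every code
path at full default parameters.

## Known limitations

* At most three subgenomes (matching the supported ploidy range of the
  original procedure); the engine itself is genome-count-agnostic but
  is only exercised up to three.
* Only base substitutions are modelled; indel HSPs are out of scope.
* One distant subgenome at most; two highly diverged relatives would
  make the distant fallback ambiguous.
* Patterns are hard counts; base qualities are not weighted.
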