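---
title: "Methods: quadripartite structure, repeat censuses and mutation-hotspot statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quadripartite structure, repeat censuses and mutation-hotspot statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`plastocompare`, in the spirit of a methods section: what each statistic is,
which knobs matter, what the synthetic generator does and does not emulate,
and where the design was genuinely open.

## Sequence model and coordinates

Plastomes are treated as circular strings over `A,C,G,T,N`. On input,
lowercase is raised, `U` becomes `T`, and every other IUPAC ambiguity code
becomes `N` (with a message counting replacements). `N` is inert everywhere:
it never participates in repeat or SSR hits, carries no state in alignment
columns, and scores zero in pairwise alignment. This is the simplest
defensible treatment given that published plastomes contain few ambiguous
bases and no convention for them is stated in the comparative literature we
reproduce; the alternative (treating ambiguity codes as partial states) would
change variable-site counts only at those rare sites.

Internally every interval is 0-based half-open and a feature crossing the
origin of the linearized circle carries `wraps = TRUE`; all written tables
are 1-based inclusive. A junction between regions X and Y is the coordinate
of the first base of Y. These two rules make interval arithmetic unambiguous
and the external tables familiar.

## IR detection

`detect_ir()` finds the maximal-length *exact* inverted repeat pair:
seeds of `seed_len` (default 25) taken every `min_ir_len - seed_len + 1`
positions are matched against the reverse complement of the doubled sequence
(doubling handles circularity), each seed hit names one anti-diagonal of the
implicit match matrix, and maximal runs on seeded anti-diagonals are
enumerated by run-length scan. Any true IR copy of at least `min_ir_len`
(default 1000 bp, far below real plastome IRs of ~20–25 kb but above
incidental repeats) necessarily contains a seed, so the search is exact, not
heuristic. The two arcs between the copies are labelled LSC (longer) and SSC
(shorter) — by span alone, never by gene content, so no annotation is needed.
Mismatch tolerance is 0: the defining invariant `IRb == revcomp(IRa)` is
asserted on every detection. Genomes without an IR raise a structured
`plasto_no_ir` error (single-IR-loss lineages exist among conifers and some
legumes); several equally long non-overlapping candidates raise
`plasto_ambiguous_ir` listing them rather than guessing.

A gene *spans* a junction only when it covers both bases flanking the
boundary; a gene abutting the junction exactly has distance 0 but is
upstream/downstream, not spanning. Distances are measured from the gene's
*nearest* end to the junction — whether published junction figures measure to
the gene start or nearest end is not stated anywhere we know of, so the
nearest-end convention is fixed and documented here. IR types in
`compare_junctions()` are keyed on the identity and relation of the JSB and
JSA context genes, which is what distinguishes published junction classes
(e.g. *ndhF* straddling JSB versus lying wholly in the SSC).

## Repeat and SSR censuses

`find_repeats()` reports exact, maximal hits of the four classical types —
forward, palindromic (reverse complement), reverse, complement — of length at
least `min_repeat_len`. The published censuses we emulate use "motif length
> 8 bp" with REPuter, whose inclusive/exclusive convention is
version-dependent; we read it as *minimum length 8* and expose the parameter.
Totals from those censuses (e.g. a grand total across two genomes) are
deliberately not reproduction targets: they depend on REPuter's hit capping
and IR-deduplication conventions that the original reports do not state.
Implementation is k-mer seeding plus character-wise extension; maximality
holds per pair (no extension on either side preserves the relation), which
suppresses all sub-hits of longer hits. Symmetric types are reported once
with `start1 <= start2`; a substring equal to its own reverse (or reverse
complement) is a legitimate single hit with `start1 == start2`. The scan is
linear, as in REPuter; a repeat pair straddling the origin would be found
only in rotated coordinates. When a quadripartite structure is supplied, the
full-length IRb/IRa hit is flagged (`ir_pair`) but kept — it is the genome's
defining repeat, not an artifact.

`find_ssrs()` applies the MISA-style minima 10, 6, 5, 5, 5, 5 complete
copies for unit sizes 1–6. A hit is a maximal tandem stretch; a partial
trailing unit belongs to the reported locus but does not count toward
`copies`; runs are split at `N`; and a stretch whose motif is itself periodic
is reported only at its primitive unit (an `AT` run is not also an `ATAT`
run — for runs of five or more copies the divisor test on the motif is
sufficient by the Fine–Wilf periodicity argument). Compound/interrupted SSRs
are reported as separate simple runs, a simpler and fully specified behavior
than MISA's compound merging. Both IR copies are scanned by default (an SSR
inside the IR counts twice, as in a whole-genome scan); `dedupe_ir = TRUE`
drops the IRb copy.

## Locus extraction and homology

Within each annotated genome, coding loci are per-gene exon concatenations
(minus-strand genes reverse-complemented), non-coding loci are introns and
the gaps between consecutive gene extents, named `geneA-geneB` along the
canonical orientation. Spacers are bounded by *any* annotated feature class,
because real marker tables mix tRNA and CDS flanks. Only loci strictly longer
than 100 bp survive, reading the published "length > 100 bp" literally; and
only one IR copy (IRa) contributes loci, mirroring the usual practice of
omitting IRb from alignment matrices to avoid duplicated signal. Overlapping
genes contribute their overlap to both coding loci and suppress the spacer
(logged in the accounting attribute, which reconciles every LSC+SSC+IRa base
into assigned or residual). Homology across taxa is by shared locus name
only — annotation-based, with no similarity search; loci absent from any
taxon (configurable `min_taxa`) are excluded from the statistics, a policy
choice the underlying studies leave unstated.

## Alignment and variability statistics

The per-locus aligner is a deterministic center-star multiple alignment: the
center is the sequence with the highest summed pairwise global score
(ties broken by taxon name), all other sequences are pairwise-aligned to it
(match 1, mismatch −1, gap open −4, gap extend −1; `N` scores 0), and the
pairwise alignments are merged under "once a gap, always a gap" with each
insertion block left-aligned and right-padded. Pairwise steps use
`Biostrings::pairwiseAlignment`; the merge asserts that degapping every row
reproduces its input. The published pipelines used MUSCLE; the statistics,
not the aligner, are the scientific content here, so a dependency-free
deterministic aligner is preferable — and `prealigned = TRUE` accepts
externally aligned FASTA rows as the fidelity escape hatch.

A column is **variable** when it contains at least two distinct bases from
`A,C,G,T`; gaps and `N` carry no state, so gap-only variation never counts.
A column is **parsimony-informative** when at least two states each occur in
at least two rows. Per locus, `pct_vc = 100·NS/L` and `pct_pic = 100·PIC/L`
where `L` is the full aligned length (all columns, including gapped ones —
the literal "aligned sequence length"). Percentages are rounded half-up to
two decimals and the non-coding/coding ratio of class means to one decimal,
matching printed precision; the bundled 20-row Olyreae marker table
reproduces its printed percentages from its own `NS`, `PIC` and `L` columns
under exactly these conventions, which is the strongest available check on
the arithmetic (whether the original tally used complete gap deletion for
`NS` is not stated, so raw counts are validated only against the table's
internal arithmetic). Class means are unweighted over loci, not
length-weighted — that is what reproduces "mean of per-locus percentages"
style summaries. Marker selection sorts by `pct_vc` (ties: `pct_pic`, then
name) and is permutation-stable; published selections may additionally have
weighed primer-design convenience, which is out of scope.

`sliding_identity()` computes, per window of alignment columns (default 100
wide, step 25), `100 · matches / comparable` where comparable positions have
a base in both rows; windows with fewer than 10 comparable positions are NA
rather than meaningless percentages.

## The synthetic generator

`synth_plan()` describes the study conditions the generator emulates. The
full-scale defaults are an 82 kb LSC, 13 kb SSC and 20 kb IR (a
herbaceous-bamboo-like plastome), 13 taxa (the size of the published Olyreae
marker-mining panel), and per-branch per-site substitution probabilities of
0.005 for coding and 0.010 for non-coding loci — chosen once so that a
13-taxon star tree yields roughly 6.5% and 12.3% variable columns, the class
means reported for that panel, since `P(variable) ≈ 1 − (1−p)^k`. The default
planted census is 14 mononucleotide runs (10–11 copies) plus one
dinucleotide run, and six 30 bp dispersed repeats (three forward, one each
palindromic/reverse/complement). Junction-context genes are planted the way
the field's junction figures show them: *psbA* 80 bp downstream of JLA,
*rpl22* upstream of JLB in the LSC, *rps19* and *trnH* inside the IR
(annotated in both copies), *ndhF* straddling JSB, *ndhH* straddling JSA.
Tests and the acceptance script use the scaled-down geometry (5 kb LSC, 1 kb
SSC, 2 kb IR) that the plan supports explicitly.

Construction guarantees, not post-hoc checks, make the ground truth exact:
IRb is written as the reverse complement of IRa; every planted element's
flanks are broken so it is exactly maximal; the four junction flanks are
broken so the IR cannot extend; and an iterative screen removes *accidental*
SSRs and accidental dispersed repeats of length ≥ 12 from the random
background (resampling one base per offending hit, mirrored through the IR).
Two classes of extra hits are left deliberately: repeats whose both copies
lie on planted elements (two same-motif SSR runs necessarily read as a short
direct repeat — breaking them would destroy the planted elements), and
anything shorter than the 12 bp screening length. Recovery tests therefore
assert planted ⊆ found for censuses on SSR-containing plans, and exact
equality on SSR-free plans.

Evolution is Jukes–Cantor on a star tree: each taxon's copy of each site
mutates independently with the locus rate (uniform choice among the three
other bases), one IR is simulated and mirrored, and rates are constrained to
`[0, 0.75)`. Indel-free evolution is the default so that locus homology is
positional and the variability statistics have closed-form expectations —
this separates statistic error from aligner error in recovery tests, at the
price that those tests exercise `align_locus` only on its no-gap path (its
gap behavior is tested separately on constructed examples). Optional
per-taxon junction shifts emulate IR expansion/contraction at JSB: the first
`d` SSC bases are captured by IRb and their reverse complement inserted at
the head of IRa; annotations downstream of the old JSA shift by `d`, while a
gene already straddling JSA keeps its printed extent, so its IR tail is
approximate after a shift — a known limitation that does not affect the
junction-type analyses the feature exists for.

What passing these tests shows — and does not show. The generator produces
uniform-composition random background (real plastomes are ~38–39% GC and
locally structured), clean annotations, exact IR copies and no indels,
rearrangements or sequencing error. Success on it validates the algorithms
and conventions (exactness of IR detection, maximality of repeat hits,
correctness of the statistics and their recovery of planted rates), not
robustness to annotation noise or alignment ambiguity in real data.

## Orchestration and determinism

`run_compare()` runs structure detection, censuses, junction comparison,
locus extraction, alignment, variability, marker ranking and an identity
profile, writing TSVs plus a manifest with an MD5 checksum per artifact and
a config hash. The identity profile is computed over the per-locus
alignments concatenated in genome order rather than a whole-genome MSA — at
plastome scale a whole-genome MSA is an external-tool task, and the windowed
statistic is the same. All randomness in the package flows from plan seeds
through scoped RNG (`withr::with_seed`); no function touches the global RNG
state, and re-running any pipeline with the same inputs and configuration is
byte-identical. Problem sizes in the test suite (10 kb genomes, 13 taxa,
~60-locus panels, 50 two-kilobase oracle sequences) were chosen as the
smallest scales at which every planted phenomenon — junction context, both
IR types, threshold-straddling SSRs, a two-decade rate ladder — is still
expressible.

## Known limitations

* Homology is name-based; diverged annotations (synonyms, split genes) must
  be harmonized upstream.
* The repeat scan is linear in the given rotation; origin-straddling repeat
  pairs require rotating first (IR detection itself is rotation-invariant).
* `trans`-spliced genes (the classic *rps12* case) are not modelled: parts
  are assumed collinear along one strand.
* The center-star aligner is O(k²) in taxa for center selection and is not a
  substitute for progressive aligners on strongly length-variable loci; use
  `prealigned = TRUE` with an external alignment there.
* Pseudogene status is taken from the input annotation (`pseudo` flag), never
  inferred from ORF checks.
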