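---
title: "splitsv: methods, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splitsv: methods, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`splitsv` locates and annotates large genomic rearrangements from aligned
long-read data. This vignette records the model, the coordinate and
consensus conventions, the parameters that matter, what the simulator does
and does not emulate, and the design decisions taken where more than one
reasonable choice existed. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The evidence model

A long read crossing a rearrangement breakpoint cannot be aligned in one
piece. Long-read aligners emit a *split read*: one primary local alignment
plus supplementary alignments, each describing part of the read, linked
through the SAM `SA` tag. `splitsv` assumes this representation (the one
produced by minimap2-style aligners with secondary alignments disabled);
flag-256 secondary records are ignored. Aligners that instead absorb an
event into a single gapped alignment are served by a separate path that
reads `I`/`D` CIGAR operations (only insertions and deletions can be
encoded this way, since a gapped alignment cannot change strand or
chromosome mid-read).

Every alignment record is placed on two coordinate axes:

* **Reference axis:** 0-based half-open `[ref_start, ref_end)` internally;
  all *reports* are 1-based inclusive.
* **Read axis:** the original read's forward orientation. For a `+`
  alignment the read offset of the first aligned base equals the leading
  clip; for a `-` alignment it equals the trailing clip (the BAM stores
  the reverse complement). Hard and soft clips are treated identically —
  both consume original-read bases, and supplementary records are commonly
  hard-clipped.

Consecutive segments along the read define *junctions*. Each junction end
is a between-base boundary with a side: `left` means the retained sequence
lies left of the break (boundary at a segment's `ref_end` for `+`
alignments), `right` the mirror case. This boundary convention makes
error-free recovery exact: a deletion of 0-based `[s, e)` yields ends
`(s, left)` and `(e, right)` and is reported as `s+1 .. e` 1-based
inclusive.

## Detection parameters

| parameter | default | units | role |
|---|---|---|---|
| `window` | 250 | nt | single-linkage gap for junction-end clustering; also the agreement tolerance for mirrored inversion breakpoints and reciprocal translocations |
| `min_support` | 2 | reads | minimum junction ends per breakpoint |
| `secondary_half_width` | 50 000 | bp | partner-locus inspection window |
| `block_limit` | 10 000 000 | bp | maximum region per query; screening proceeds in blocks |
| `indel_min_len` | 10 | bp | gapped-path threshold (strictly greater than) |
| `min_mapq` | 0 | — | no mapping-quality filter by default: the workflow is review-oriented, and filtering hides evidence |
| `overlap_tol` | 200 | bp | tolerated read-span overlap between consecutive segments; beyond it the chimeric alignment is inconsistent and the read is excluded from junction extraction |
| `min_pattern_reads`, `min_pattern_prop` | 2, 10% | — | a junction pattern must reach both to enter classification; minority patterns are reported but not voted on |

The 250 nt / 2 reads clustering rule and the 50 kb and 10 Mb windows are
the published operating points of the workflow this package reimplements;
the remaining defaults are this package's documented choices where the
original is silent.

Clustering is single linkage on sorted positions per (chromosome, side):
merge while the gap between consecutive ends is at most `window`. It is
the simplest rule consistent with "two or more ends within 250 nt", it is
permutation invariant, and the test suite checks it against a brute-force
transitive-closure oracle. Both junction ends are clustered symmetrically
(whether the original tool clusters only primary-side ends is not
documented); partner consistency is checked at classification rather than
at detection, keeping the detection stage mechanical.

**Columns.** A *column* — the visual unit of breakpoint evidence, a stack
of co-terminating alignments — pools the per-side clusters at one
position: an inversion breakpoint produces a left-side and a right-side
cluster at the same coordinate, which is one column, not two. Simple
events therefore show 2 columns (insertions 3, the insertion-site column
being paired with both origin-end columns), complex insertion-deletions 3
or 4, and more than 4 columns triggers a manual-review warning (several
events at one locus).

## Classification

Each junction is canonicalized so that reads sequenced in either
orientation over the same breakpoint yield the same pattern: ends are
sorted by (chromosome, position, side); if the first end's strand is `-`,
both strands are flipped and the traversal direction (concordant =
read runs low-to-high coordinate) is inverted. Patterns are keyed by the
*locus* of each end (single-linkage position groups within `window`), the
sides, the relative strand and the traversal order — locus identity
matters because two distinct junctions of one event can share pure
orientation geometry.

The decision table, in order:

* one same-chromosome, same-strand, concordant, positive-gap pattern →
  **deletion**;
* one same-chromosome, same-strand, *reversed* pattern → **tandem
  duplication**, with **ring chromosome** as a standing alternative: the
  two signatures are identical (a ring junction joins the span's right
  boundary back to its left boundary exactly as a duplication junction
  does) and only copy number or a karyotype separates them. Duplication
  is primary because duplications are overwhelmingly the more common
  explanation;
* two opposite-strand patterns with sides (left,left) and (right,right)
  whose positions mirror within `window` at both loci → **inversion**;
* two inter-chromosomal patterns with complementary sides agreeing within
  `window` on each chromosome → **balanced translocation**; a single
  inter-chromosomal pattern → **unbalanced translocation**;
* any remaining two-pattern set is fed to the transposition solver (below)
  → **insertion** or **complex insertion-deletion**;
* everything else → **unclassified**, never an error (classification is
  total; a fuzz test asserts it).

**Transposition solver.** Two junction patterns carry four ends; each
pattern contributes one *insertion-site flank* end and one *origin* end.
A valid assignment needs a left + right flank pair on one chromosome
(site `p ≤ q`, loss `q − p`) and a right (start) + left (end) origin pair
delimiting a positive span on one chromosome. Among valid assignments the
minimum-loss one wins (ties: smaller origin), and a site *gain* deeper
than `window` is rejected. If the resolved loss is within `window` the
event is a clean **insertion** (the site is one breakpoint); a larger loss
makes it a **complex insertion-deletion** with the loss span reported.

For a same-chromosome *inverted* transposition with loss, the assignment
is provably ambiguous: the same junction set also describes an offset
inversion (and other flank/origin splits). The call is the minimum-loss
reading with **inversion** listed as an alternative — long reads spanning
only single junctions cannot do better, and the two readings generate
byte-identical signatures (asserted in the acceptance tests on a
constructed pair). The non-inverted and inter-chromosomal cases are
unambiguous, and the solver's geometry shows why: the alternative
assignments fail the sign constraints.

A related degeneracy worth knowing: two adjacent deletions with a retained
middle produce the same derived sequence as an insertion-deletion whose
origin is that middle; the solver reports the transposition reading. Both
descriptions are literally true of the sequence.

## Consensus and reporting

Per-read annotations are reduced per coordinate slot by the **lower
median** (for even *n*, the smaller central value — deterministic and
integer-preserving). The median is stated for gapped-indel aggregation in
the source workflow; we unify on it for split-read consensus as well,
since it tolerates up to half-minus-one corrupted reads (a brute-force
property test covers the 101-tuple case) and never invents a coordinate
that no read reported. When per-read annotations disagree on the *type*,
annotation aborts naming the offending reads instead of majority-voting.

Rendered forms: `chr:start_end` + `del`/`dup`/`inv` with the affected span
1-based inclusive; `chrB:p_p+1ins[chrA:x_y]` (with an `inv` marker) for
insertions; `t(chrA;chrB)(g.X;g.Y)` for translocations, where a left-side
breakend reports its last retained base and a right-side end its first
retained base; and for complex events the fixed machine-parseable
composite `INS(origin=chrA:x-y;inverted=yes|no);LOSS(chrB:p-q)` — complex
HGVS naming is subjective near the boundaries between indel, inverted
duplication and offset inversion, so the package states origin,
orientation and loss and leaves nomenclature to the user. Whether the
breakend exemplars of the original tool report the base before or after a
junction cannot be pinned from published numbers alone (their ±1–11 bp
offsets against Sanger are confounded with alignment jitter); the
convention here is fixed and documented instead. Simple rendered strings
re-parse to identical calls (`parse_hgvs()`), which the tests assert.

## The simulator's stated world

`scenario_suite()` is the package's validation ground: 32 simple + 36
complex rearrangements (68 total), defined against a seeded synthetic
reference of two contigs (800 kb + 400 kb) with low-complexity patches.
Faux reads are error-free 10 kb windows every 1 kb, alternating
orientation, truncated (not dropped) at contig ends, wrapping the junction
on ring contigs; truth BAMs are computed *exactly* from the coordinate
map (piece table) — primary = longest piece, soft clips on primaries,
hard clips + `SA` tags on supplementaries, so the SA-synthesis path is
exercised. Reference-contiguous neighbouring pieces are merged so that
piece seams are true junctions only.

Choices fixed once, with rationale:

* **Reference size.** The substrate is ~1.2 Mb rather than multi-Mb
  chromosomes: event geometry, not substrate length, is what validation
  exercises, and the full 68-scenario round trip must stay well inside a
  10-minute single-CPU budget (it runs in about 5 minutes here, measured
  by the acceptance script).
* **Event sizes ≥ 20 kb** (origins ≥ 25 kb) so no 10 kb read spans two
  junctions of one event — reads spanning a whole feature are a different
  evidence regime, which the source workflow also notes as the resolver
  for its ambiguities.
* **Rings share breakpoints with tandem duplications** (three pairs) so
  the signature-identity assertion runs on identical coordinates, and all
  suite breakpoints are multiples of 500 so crossing-read counts match
  between paired scenarios.
* **Complex grid**: origin location (other chromosome / same chromosome
  distant / nearby / within the copied sequence) × orientation × loss at
  the insertion site (0 / 2 kb / 8 kb) × two origin sizes. Zero-loss
  members are duplicative insertions near or within the copied sequence;
  their expected call type is *insertion*. The inverted within-origin
  with-loss cell is excluded: there the minimum-loss reading differs from
  the generating spec, i.e. the scenario has no unique expected
  annotation to test against.
* **Noise** (`add_read_noise()`) is off in the validation suite — the
  published in-silico data is clean by construction. Substitution noise
  leaves truth alignments valid (mismatches inside `M`); indel noise
  shifts read coordinates and is for robustness experiments only.

What a green suite does *not* establish: behaviour under real base-calling
error and alignment jitter (only the median machinery is tested under
synthetic jitter at the documented ~190 bp / 8 bp scales), heterozygous
mixtures (faux data is haploid), chimeric library artefacts, repetitive
regions where the aligner itself fails, or events whose inserted sequence
is absent from the reference — the method is limited to variants composed
of reference sequence flanking the breakpoints.

## Degenerate inputs and numerical corner cases

* Empty regions, regions without split reads, and cluster-free inputs
  return empty tables, not errors; unknown chromosomes and oversized
  blocks are errors before any output.
* Unparsable `SA` entries skip the entry with a warning; a read group
  without a primary (primary outside the query, known only through `SA`)
  promotes its longest segment so the one-primary invariant holds.
* Ties: cluster representatives and all consensus coordinates use the
  lower median; equal-length primary candidates take the first in read
  order; equal-loss solver assignments take the smaller origin.
* A single supporting read is allowed in the user-guided pathways but is
  flagged (`low_confidence`, plus a warning in the gapped path).
* Gapped-path grouping uses reference-span overlap (single linkage), with
  an insertion's interval extended by its inserted length so that long
  insertions with a few-hundred-bp placement jitter still co-group; no
  fixed window is imposed because the documented jitter scales with the
  event, not with a constant.

## Known limitations

Ring-versus-duplication and offset-inversion ambiguities are reported,
not resolved (resolution needs copy number, a karyotype, or reads long
enough to span the feature). The automatic classifier handles one event
per region; loci with more than four columns are deferred to manual
review through the user-guided pathways. CRAM is not supported, reads are
not realigned, and base qualities are unused.
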