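---
title: "Comparing alternate genome assemblies and disambiguating their discordances"
author: "draftcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing alternate genome assemblies and disambiguating their discordances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(draftcompare)
```

## The problem

When the same shotgun read set is assembled with two different pipelines,
the resulting drafts can disagree substantially: segments placed at nearly
the same position but in opposite orientation; segments placed at distinct
positions along a chromosome; sequence assembled onto a chromosome by one
draft but left on unassigned scaffolds (ChrUns) by the other; segments
assigned to different chromosomes altogether; and duplications collapsed
into a single copy or, conversely, falsely duplicated. Because both drafts
derive from the same reads, read-based evidence cannot arbitrate.
Cytogenetic evidence can: fluorescence in situ hybridization (FISH) of BAC
clones is assembly-independent, and long-range PCR across predicted
junctions resolves discordances too small for microscopy.

`draftcompare` implements this comparison-and-arbitration workflow as a
reusable pipeline, together with a synthetic-genome simulator that plants
rearrangements of exactly these classes, so the whole procedure is testable
end to end with a known ground truth.

## Sequence model and coordinates

Assemblies are named sets of soft-masked sequences (`A,C,G,T,N`, lowercase
marking repeats), partitioned into chromosomes and unassigned scaffolds.
All coordinates are 0-based half-open internally; every emitted report is
1-based inclusive, matching the positions genome browsers print. Lowercase
and `N` both count as "masked": assembly gaps and repeats are
interchangeable for every filter in this pipeline, since both disqualify a
locus from probe design.

## Stage 1: anchors and synteny blocks

Homologous chromosomes are paired by name and compared with a
seed-and-extend engine that reports **every maximal exact match of at least
`min_anchor` bp (default 50) on both strands**. Matching is
case-insensitive, so a unique match runs straight through a soft-masked
repeat; `N` never matches anything. The engine seeds with 2-bit-packed
k-mers (k = min(31, `min_anchor`)) taken at stride `min_anchor - k + 1`,
which provably visits every match of qualifying length, and extends each
seed maximally with a per-diagonal high-water mark; the output is
identical to a direct k-mer scan at k = `min_anchor`, just cheaper.

Masking policy: an anchor that is more than 75% masked on *both* sides is
discarded. Such anchors are matches between distinct copies of a repeat
family and carry no positional information; worse, they can extend a base
or two into unique flank by chance, so a rule based on the start position
alone is not robust (it both loses unique matches whose maximal extension
happens to begin inside a repeat, and keeps inter-copy matches that got
lucky at their edge). Taking the minimum of the two sides keeps the rule
symmetric under swapping the assemblies. The 0.75 cutoff is the same
constant used for the gap/repeat exclusion below and is configurable.

Anchors are chained into **synteny blocks**: maximal runs (over anchors
sorted by A-position) in which consecutive anchors share orientation,
advance colinearly on both genomes with gaps of at most `max_gap`
(default 50 kbp) and change diagonal offset by at most `max_drift`
(default 20 kbp). Both defaults sit below the 100 kbp reporting floor, so
no chaining artifact can create a reportable discordance. The maximal-run
partition is the unique minimum-size partition of the sorted anchor list
into contiguous valid chains; the test suite verifies this against an
exhaustive partition search.

## Stage 2: discordance classification

Discordances carry four categories:

* **INV** — near-coincidental position, opposite orientation;
* **MDP** — mapped in distinct positions along the same chromosome;
* **ODS** — one-draft-only sequence: covered by no block on one
  assembly's chromosome;
* **DCM** — discordant chromosome mapping: a pair of mutually matching
  ODSs on different chromosomes.

The dominant colinear order of a chromosome pair is computed as the
anchor-bp-weighted longest increasing subsequence (by B-position, over
same-orientation blocks sorted by A-position) — the *backbone*. This is
essential: an insertion or deletion in one assembly shifts every
downstream block's diagonal without changing their order, so a rule based
on a single global offset would flag all of them as displaced. Against the
backbone:

* an inverted block whose A-span and B-span, projected through the nearest
  backbone diagonal, reciprocally overlap by ≥ 80% is an INV (the
  "almost coincidental" requirement is not quantified anywhere we could
  adopt it from, so 0.8 is a configurable package decision); an inverted
  block failing it is treated as an MDP;
* a same-orientation block outside the backbone whose centre is displaced
  from the locally predicted position by more than its own length is an
  MDP; the recorded displacement (in the colinear frame, immune to
  unrelated indels on the same chromosome) later routes the discordance
  to FISH or PCR;
* maximal uncovered regions of either chromosome become ODSs of that
  assembly; regions under 10 kbp are ignored as chaining noise. ODS
  boundaries end exactly at the neighbouring anchor ends, so no anchor
  slack is retained.

Note an inherent ambiguity of relative displacement: when a segment moves
past a stretch *shorter than itself*, the stretch (not the segment) is the
minority of the weighted order and gets flagged. The synthetic generator
therefore plants relocations whose displacement exceeds 2.5× the segment
length, which keeps the planted segment the flagged one; on real data both
calls describe the same event.

**Eligibility** is strict, following the "larger than" phrasing of the
reporting rules: > 100 kbp ⇒ reportable, > 200 kbp ⇒ test-eligible for
MDP/ODS/DCM, > 500 kbp ⇒ test-eligible for INV (an inversion test needs
three non-overlapping ~50–300 kb BACs, hence the higher floor). A
discordance exactly at a threshold stays in the lower tier. Sizes are
measured on the A-span for INV/MDP (the source does not state which
assembly's span defines the size; both spans are reported).

**DCM pairing.** Every reportable ODS is re-anchored against the full
other assembly. Two ODSs covering each other ≥ 50% reciprocally while
lying on different chromosome names form a DCM. An ODS matching (≥ 50%) a
different chromosome at a locus that is *not* an ODS is a one-sided DCM:
the segment exists twice in the ODS's own assembly and once in the other,
so it is flagged as duplicated there — the signature of either a false
duplication or a collapsed duplication, and only the simulated FISH can
tell which assembly is right. The 50% cutoff operationalizes
"substantially matching"; it is configurable.

**Gap/repeat exclusion.** A discordance whose defining locus (source locus
for an ODS, A-locus otherwise) is more than 75% masked is excluded from
consideration but retained in the reports with a flag, mirroring how
"almost completely gaps and/or repeats" segments are listed but not
studied. The cutoff is strict (exactly 75% masked is kept).

**Codes.** `<CAT>_<chromosome>_<start in Mbp, one decimal>` with a
trailing `.0` dropped (so a start at 24.0 Mbp prints `24`), and
`DCM_<chrA>-<chrB>`; collisions get `.2`, `.3` suffixes. The position unit
is Mbp: although the naming convention is described in kbp in the text we
follow, every printed code is consistent only with Mbp, so the codes win
over the prose.

## Stage 3: scaffold placement

Each unassigned scaffold of one assembly is anchored and chained against
every sequence of the other. Verdicts mirror the published table
semantics: `single-locus` (one block covers ≥ 90% of the scaffold),
`split-multi-chromosome` (≥ 2 chromosomes each own a distinct sub-interval
above the reporting floor), `multi-site-dispersed` (some sub-interval
matches ≥ 3 loci — a low-copy repeat or collapsed duplication signature),
`unplaced` (total coverage < 10%). The 0.90/0.10 cutoffs are package
decisions exposed as arguments; verdicts in the published source are
qualitative. Placements onto the target's own scaffolds are reported but
never produce a chromosome verdict. Reportable ODSs are also cross-linked
to the scaffolds that cover ≥ 50% of them (`NS` otherwise).

## Stage 4: probe design

BAC end sequences are mapped by seeded ungapped search tolerating 2
mismatches per 100 bp (enough to catch the planted repeat-copy noise, so
an end inside a repeat family is correctly flagged non-unique when two or
more hits tie at the best mismatch count). A clone is *usable* when both
ends are unique, hit one sequence, and face inward on opposite strands
with an implied span inside the closed interval [50, 300] kb.

* **Inversions** get a triplet: one clone wholly inside the segment, two
  outside within 1 Mbp of the opposite breakpoints ("close to the
  borders" carries no printed number; 1 Mbp is the package's choice). The
  inside clone is chosen as off-centre as possible (at least 10% of the
  span off the midpoint): a perfectly centred probe produces the same
  interphase arrangement under both hypotheses and cannot discriminate.
  Candidate probes must also map concordantly (same chromosome, both
  ends, inward) in *both* assemblies, so a flank never sits on sequence
  whose chromosome assignment is itself in dispute.
* **DCMs** get a single clone selected on the side that carries the
  segment once (there its placement is unique and lives in the locus
  coordinate frame); the deliberate multi-mapping on the duplicated side
  is exactly what the metaphase assay reads out.
* **Reference panel**: one clone per chromosome inside a same-orientation
  block whose raw coordinates agree ≥ 99% reciprocally between the
  assemblies, for chromosome identification in metaphase spreads.
* **MDPs** displaced less than 1 Mbp (in the colinear frame) cannot be
  resolved by interphase FISH and get **junction long-PCR** instead: for
  each assembly hypothesis, 25 bp primer sites 2 kb either side of the
  predicted left junction of the discordant segment, each site required
  to be a unique exact substring of its assembly (slid outward in 500 bp
  steps when not). Primer thermodynamics are out of scope; uniqueness and
  geometry are the model. The predicted product, 2 × (2000 + 25) bp, must
  not exceed the 12 kb long-PCR ceiling, which operationalizes the
  11-minute extension protocol.

## Stage 5: simulated FISH and the verdict

Simulated experiments run against the *true* genome — the simulator plays
the role of nature, while predictions come from the assemblies only.

**Metaphase.** A probe shows one signal per true-genome locus carrying at
least 5 kbp of contiguous exact homology (the conservative end of the
5–10 kbp visibility range; shorter homology is silent), with independent
per-locus dropout at 5% per cell. Ten cells are inspected. Each
hypothesis predicts a chromosome-assignment multiset (multiset, so a
duplicated prediction differs from a single one); the winner is the
hypothesis whose prediction equals the modal per-cell observation — an
all-or-nothing readout in which signals are either fully compatible with
a prediction or plainly discordant.

**Interphase.** Fifty nuclei are inspected per triplet. The observable is
the *proximity-canonical arrangement*: the three labels written from the
flank nearest the internal probe to the far flank. This encoding is the
package's resolution of a real subtlety: inverting a segment *between*
two outside probes never changes the positional order of the triplet —
only which flank the internal probe ends up nearest — and reading the
arrangement proximity-first simultaneously fixes the arbitrary reading
direction of a nucleus and keeps the sample space at the 6 label
permutations. Each nucleus reports the true arrangement with probability
`1 - disorder_p` and otherwise a uniformly random permutation, so the
expected true-arrangement fraction is `(1 - p) + p/6` (0.75 at p = 0.3),
which the test suite checks in closed form. The default `disorder_p` =
0.15 is motivated by the 73–98% support range such experiments report; the
simulator does not claim to fit any particular experiment. The winner is
the majority hypothesis with its matching share as the support fraction,
printed `"<assembly> (<pct>%)"`; if neither arrangement reaches half the
nuclei the verdict is `"neither"`, and identical predictions give
`"both-consistent"`.

**PCR.** An assay amplifies in silico when both primer sites occur on one
molecule of the template, inward, within the product ceiling. The
hypothesis whose assay amplifies on the true genome is supported;
both-negative is reported as `"-"` — the outcome class in which both
assemblies are wrong at the junction.

## The synthetic generator

`generate_true_genome()` draws i.i.d. uniform A/C/G/T chromosomes — which
makes long anchors unique with overwhelming probability at desk scale —
and plants two kinds of structure: lowercase interspersed-repeat families
whose copies carry 1% substitution noise (so uniqueness filters have
something to reject), and exact uppercase low-copy segmental duplications,
optionally pinned to pericentromeric or subtelomeric chromosome ends,
which reproduce the multi-signal FISH phenomena of real pericentromeric
duplications. `derive_assemblies()` applies planted events — inversion,
relocation, unplace-to-scaffold, cross-chromosome move, duplication
insertion, duplication collapse, deletion — each to one assembly, and
emits a truth table with realized coordinates in both assemblies plus the
expected discordance per event. `generate_bes_library()` samples clone
inserts uniformly (50–300 kb) with inward-facing end reads.

The standard study conditions, used by the replicated tests and the
acceptance script, are: 8 chromosomes × 2 Mbp; two repeat families × 40
copies × 2 kb at 1% noise; one 2-copy exact 220 kb duplication placed
pericentromerically; 12–13 events per genome spanning every kind, with
inversions of 520–900 kbp (plus one deliberately sub-threshold 90 kbp
inversion that must *not* be reported), relocations of 240–300 kbp
displaced 1.6–1.9× their length, unplaced segments of 400–800 kbp, a
220 kbp deletion, a 500 kbp cross-chromosome move, a 260 kbp false
duplication and one collapsed duplication; and 1600 BES clones (~17×
clone coverage). Event boundaries snap to unmasked positions and event
footprints keep 100 kb mutual clearance so flanking anchors stay
separable; interspersed repeats may fall inside event footprints, as they
would in real genomes. Twenty replicate genomes are used for the
recovery and verdict tests, five by the acceptance script; these sizes
were chosen so that every threshold in the pipeline is exercisable at
desk scale with clean margins.

What the generator does **not** emulate: base-calling and consensus
errors (the assemblies are locally exact copies of the truth), realistic
repeat families (SINE/LINE structure), gaps (`N` runs), nested or
overlapping rearrangements, copy-number polymorphism between the
sequenced individual and the cytogenetic cell line, and cross-species
contamination. Passing tests therefore demonstrate the logic of the
pipeline — detection, classification, probe geometry, decision rules —
not robustness to assembly base error, which would require
mismatch-tolerant anchoring throughout.

## Numerical choices and degenerate inputs

* Ties in chaining and probe ranking break by coordinate order;
  everything is deterministic given the seed, and rerunning a
  configuration reproduces the report bundle byte for byte.
* All randomness flows from explicit seed arguments through a private RNG
  stream; the caller's RNG state is untouched.
* Empty inputs: chaining an empty anchor set gives an empty block table;
  identical assemblies give zero reportable discordances; an empty BES
  library makes every plan infeasible (reported, never an error); a
  probe absent from the genome yields zero signals; deciding on zero
  cells is an error.
* The backbone LIS is O(n²) in blocks per chromosome, irrelevant at
  realistic block counts.
* Assemblies must share chromosome names; unpaired names are a hard
  pairing error listing the offenders, never silently dropped.

## Limitations

Anchoring is exact-match only: diverged duplicates below ~100%
identity are invisible to the comparison stage (though not to the
mismatch-tolerant BES mapper). Nested events inside one footprint are not
decomposed. The FISH simulator models signal arrangement and dropout, not
imaging: no fluorophore spillover, no 3D nuclear geometry, no
cross-hybridization chemistry. Support percentages produced by the
simulator characterize the simulator's noise model, not any wet-lab
experiment.
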