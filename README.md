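# draftcompare

Compare two alternate assemblies of the same genome, classify their
structural discordances, and decide between them with simulated
cytogenetic experiments.

When one read set is assembled by two different pipelines, the drafts
disagree in characteristic ways. `draftcompare` detects and classifies
those disagreements on exact-match synteny blocks:

* **INV** — a segment at almost the same position in both drafts but in
  opposite orientation;
* **MDP** — a segment **m**apped in **d**istinct **p**ositions along the
  same chromosome;
* **ODS** — a **o**ne-**d**raft-only **s**equence, present on a chromosome
  of one draft and absent from the homologous chromosome of the other
  (typically sequence the other draft left on unassigned scaffolds);
* **DCM** — **d**iscordant **c**hromosome **m**apping: a pair of mutually
  matching ODSs on different chromosomes.

Discordances above 100 kbp are reportable; MDP/DCM above 200 kbp and INV
above 500 kbp are eligible for experimental testing, and the package
designs the experiments: BAC probes selected from an end-sequence library
(both ends unique, inward orientation, 50–300 kb span), three-probe
triplets for inversions, a chromosome-specific reference panel, and
junction long-PCR assays for MDPs too small for FISH. A simulator then
runs the experiments against the true genome (metaphase chromosome
assignment with a 5 kbp visibility floor, 10 cells; interphase triplet
arrangement, 50 nuclei; in silico PCR) and reports which assembly each
experiment supports, as `"B (96%)"`-style verdicts.

Because real drafts come without ground truth, the package ships a
synthetic-genome module that plants rearrangements of exactly these
classes (inversions, relocations, unplaced scaffolds, cross-chromosome
moves, false and collapsed duplications, deletions) and emits
machine-readable truth tables, so the entire pipeline is testable end to
end. See the vignette (`vignettes/assembly-discordance.Rmd`) for the
methods.

## Worked example

```r
library(draftcompare)

true <- generate_true_genome(3, rep(1.2e6, 3), repeat_family_count = 1,
                             repeat_copies = 12, seed = 11, repeat_len = 1500)
events <- list(
  event_spec("inversion",  "A", "chr1", 300000, 900000),
  event_spec("relocation", "B", "chr2", 150000, 390000, dest_pos = 950000),
  event_spec("unplace",    "A", "chr3", 400000, 700000))
der <- derive_assemblies(true, events)
bes <- generate_bes_library(true, 500, seed = 12)

cfg <- run_config(der$a, der$b, bes = bes, truth = true, seed = 99)
res <- run_compare(cfg, verbose = FALSE)
print(res)
#> CompareResult
#>   reportable discordances: INV=1 MDP=1 ODS=1 DCM=0
#>   disambiguation table:
#>       code     test supported
#>  INV_1_0.3 FISH/int   B (96%)
#>  MDP_2_0.1      PCR         A
```

Each planted event is recovered as one discordance of its category: the
600 kbp inversion on chr1 (`INV_1_0.3`, test-eligible), the relocated
chr2 segment (`MDP_2_0.1`), and the unplaced chr3 segment as an ODS
present only in assembly B. The simulated interphase triplet supports
assembly B for the inversion with 96% of 50 nuclei — B is indeed the
assembly the inversion was *not* applied to — and the junction PCR
supports A for the relocation, which was planted into B. The ODS is
cross-linked to the scaffold that carries it (`res$ods_crosslinks`), and
`res$scaffold_placements` maps that scaffold back to its donor locus.
Coordinates inside result objects are 0-based half-open; every TSV
written by `write_report_bundle()` (and by `run_compare()` when
`out_dir` is set) is 1-based inclusive.

A thin command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/draftcompare.R", package = "draftcompare"))')" \
    simulate --out sim --seed 7
Rscript .../draftcompare.R compare --assembly-a sim/assemblyA.fa \
    --assembly-b sim/assemblyB.fa --bes sim/bes.tsv --truth sim/true.fa \
    --out report --seed 7 --min-inv-kb 500
```

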