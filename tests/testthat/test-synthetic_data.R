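test_that("true-genome generation is deterministic and respects packing", {
  g1 <- generate_true_genome(2, c(1e6, 1e6), 0, 0, seed = 1)
  g2 <- generate_true_genome(2, c(1e6, 1e6), 0, 0, seed = 1)
  expect_identical(g1$seq, g2$seq)            # byte-identical re-run
  expect_false(any(grepl("[a-z]", g1$seq)))   # all-unique, no masking
  g3 <- generate_true_genome(2, c(1e6, 1e6), 0, 0, seed = 2)
  expect_false(identical(g1$seq, g3$seq))
  expect_error(generate_true_genome(1, 1e5), ">= 200 kbp")
  expect_error(generate_true_genome(1, 5e5, repeat_family_count = 1,
                                    repeat_copies = 200, repeat_len = 2000),
               "infeasible packing")
})

test_that("planted repeat copies are scannable lowercase blocks", {
  g <- generate_true_genome(1, 5e5, repeat_family_count = 1,
                            repeat_copies = 10, seed = 3, repeat_len = 1500)
  runs <- gregexpr("[acgtn]+", g$seq[[1]])[[1]]
  expect_equal(length(runs), 10)
  expect_true(all(attr(runs, "match.length") == 1500))
  expect_equal(nrow(attr(g, "repeats")), 10)
})

test_that("uppercase unique fraction stays above 60% per chromosome", {
  g <- generate_true_genome(8, rep(2e6, 8), repeat_family_count = 2,
                            repeat_copies = 40, seed = 7)
  for (ch in chromosomes(g)) {
    s <- g$seq[[ch]]
    expect_gte(1 - nchar(gsub("[A-Z]", "", s)) / nchar(s), 0.6)
  }
})

test_that("derived assemblies realize each event kind faithfully", {
  true <- generate_true_genome(2, c(1.2e6, 1.2e6), seed = 5)
  events <- list(
    event_spec("inversion", "A", "chr1", 200000, 800000),
    event_spec("unplace", "A", "chr2", 300000, 500000))
  der <- derive_assemblies(true, events)
  tt <- der$truth
  # inversion: the A segment equals the reverse complement of the B segment
  inv <- tt[tt$kind == "inversion", ]
  sa <- substr(der$a$seq[[inv$a_seq]], inv$a_start + 1, inv$a_end)
  sb <- substr(der$b$seq[[inv$b_seq]], inv$b_start + 1, inv$b_end)
  expect_identical(sa, reverse_complement(sb))
  # unplace: chromosome shorter by the segment, scaffold of exact length
  # and content
  up <- tt[tt$kind == "unplace", ]
  expect_equal(nchar(der$a$seq[["chr2"]]), 1.2e6 - 200000)
  sid <- up$scaffold_id
  expect_identical(unname(der$a$role[sid]), "scaffold")
  expect_equal(nchar(der$a$seq[[sid]]), 200000)
  expect_identical(der$a$seq[[sid]],
                   substr(true$seq[["chr2"]], 300001, 500000))
  # assembly without the event equals the truth over the footprint
  expect_identical(substr(der$b$seq[["chr1"]], 200001, 800000),
                   substr(true$seq[["chr1"]], 200001, 800000))
})

test_that("collapsed duplications leave one copy where truth has several", {
  true <- generate_true_genome(3, rep(8e5, 3), seed = 9, segdup_families = 1,
                               segdup_copies = 3, segdup_len = 30000)
  sd <- attr(true, "segdups")
  unit <- substr(true$seq[[sd$chrom[1]]], sd$start[1] + 1, sd$end[1])
  count_copies <- function(asm) {
    sum(vapply(asm$seq, function(s)
      length(gregexpr(unit, s, fixed = TRUE)[[1]]) *
        (gregexpr(unit, s, fixed = TRUE)[[1]][1] != -1), numeric(1)))
  }
  expect_equal(count_copies(true), 3)   # brute-force substring count
  ev <- event_spec("dup_collapse", "B", sd$chrom[1], sd$start[1], sd$end[1],
                   copies = sd[-1, c("chrom", "start", "end")])
  der <- derive_assemblies(true, list(ev))
  expect_equal(count_copies(der$b), 1)
  expect_equal(count_copies(der$a), 3)
})

test_that("event validation rejects overlaps and out-of-bounds targets", {
  true <- generate_true_genome(1, 1e6, seed = 4)
  ok <- event_spec("deletion", "A", "chr1", 100000, 220000)
  overlap <- event_spec("inversion", "A", "chr1", 150000, 400000)
  expect_error(derive_assemblies(true, list(ok, overlap)),
               "overlapping events on assembly A")
  # same footprints on different assemblies are allowed
  other <- event_spec("inversion", "B", "chr1", 150000, 400000)
  expect_silent(derive_assemblies(true, list(ok, other)))
  expect_error(derive_assemblies(true, list(
    event_spec("deletion", "A", "chr1", 900000, 1100000))), "out of bounds")
})

test_that("sequence content is conserved up to planted indels", {
  b <- small_bundle()
  tt <- b$truth
  total_true <- sum(nchar(b$true$seq))
  for (side in c("a", "b")) {
    asm <- b[[side]]
    lost <- sum(tt$end[tt$applies_to == toupper(side) &
                       tt$kind %in% c("deletion", "dup_collapse")] -
                tt$start[tt$applies_to == toupper(side) &
                         tt$kind %in% c("deletion", "dup_collapse")])
    gained <- sum(tt$end[tt$applies_to == toupper(side) &
                         tt$kind == "dup_insert"] -
                  tt$start[tt$applies_to == toupper(side) &
                           tt$kind == "dup_insert"])
    expect_equal(sum(nchar(asm$seq)), total_true - lost + gained)
  }
})

test_that("BES library geometry and determinism", {
  true <- generate_true_genome(2, c(1e6, 1e6), seed = 6)
  lib <- generate_bes_library(true, 200, insert_range = c(150000, 150000),
                              end_len = 500, seed = 8)
  expect_true(all(lib$end - lib$start == 150000))  # degenerate range
  lib2 <- generate_bes_library(true, 200, insert_range = c(150000, 150000),
                               end_len = 500, seed = 8)
  expect_identical(lib, lib2)
  # ends are exact substrings at the insert extremities, facing inward
  for (i in sample(nrow(lib), 10)) {
    s <- true$seq[[lib$chrom[i]]]
    expect_identical(lib$end1[i], substr(s, lib$start[i] + 1,
                                         lib$start[i] + 500))
    expect_identical(lib$end2[i],
                     reverse_complement(substr(s, lib$end[i] - 499,
                                               lib$end[i])))
  }
  expect_error(generate_bes_library(true, 10, insert_range = c(1e5, 2e6)),
               "infeasible")
  expect_error(generate_bes_library(true, 10, end_len = 50), ">= 100")
})

test_that("the default event menu spans every kind above its threshold", {
  true <- generate_true_genome(8, rep(2e6, 8), repeat_family_count = 2,
                               repeat_copies = 40, seed = 13,
                               segdup_families = 1, segdup_copies = 2,
                               segdup_len = 220000,
                               segdup_placement = "pericentromeric")
  evs <- default_event_menu(true, seed = 14)
  kinds <- vapply(evs, `[[`, character(1), "kind")
  expect_setequal(unique(kinds),
                  c("inversion", "relocation", "unplace", "cross_move",
                    "dup_insert", "dup_collapse", "deletion"))
  sizes <- vapply(evs, function(e) e$end - e$start, numeric(1))
  # exactly one deliberately sub-threshold inversion; everything else
  # exceeds the MDP/DCM testing floor, inversions the 500 kbp floor
  expect_equal(sum(sizes <= 100000), 1)
  big_inv <- sizes[kinds == "inversion" & sizes > 100000]
  expect_true(all(big_inv > 500000))
  expect_true(all(sizes[kinds != "inversion"] > 200000))
  # relocations displace by more than the segment length
  for (e in evs[kinds == "relocation"])
    expect_gt(e$dest_pos - e$end, e$end - e$start)
})
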