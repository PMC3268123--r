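test_that("a clone from a unique insert maps uniquely, inward, full span", {
  true <- generate_true_genome(1, 1e6, seed = 41)
  lib <- generate_bes_library(true, 5, insert_range = c(150000, 150000),
                              seed = 42)
  pl <- map_bes(lib[1, ], true)
  expect_true(pl$e1_unique && pl$e2_unique)
  expect_true(pl$orientation_ok)
  expect_true(pl$usable)
  expect_equal(pl$span, 150000)
  expect_equal(pl$insert_start, lib$start[1])
  expect_equal(pl$insert_end, lib$end[1])
})

test_that("an end inside a repeat family is flagged non-unique", {
  true <- generate_true_genome(2, c(8e5, 8e5), repeat_family_count = 1,
                               repeat_copies = 10, seed = 43,
                               repeat_len = 2000, repeat_noise = 0.005)
  rp <- attr(true, "repeats")
  # construct a clone whose end1 sits wholly inside a repeat copy
  r1 <- rp[1, ]
  insert_start <- r1$start
  insert_end <- insert_start + 120000
  clone <- data.frame(
    clone_id = "R1",
    end1 = substr(true$seq[[r1$chrom]], insert_start + 1, insert_start + 600),
    end2 = reverse_complement(substr(true$seq[[r1$chrom]],
                                     insert_end - 599, insert_end)),
    stringsAsFactors = FALSE)
  pl <- map_bes(clone, true)
  expect_false(pl$e1_unique)
  expect_true(pl$e2_unique)
  expect_false(pl$usable)
})

test_that("ends on different chromosomes imply no insert", {
  true <- generate_true_genome(2, c(5e5, 5e5), seed = 44)
  clone <- data.frame(
    clone_id = "X1",
    end1 = substr(true$seq[["chr1"]], 1001, 1600),
    end2 = reverse_complement(substr(true$seq[["chr2"]], 2001, 2600)),
    stringsAsFactors = FALSE)
  pl <- map_bes(clone, true)
  expect_false(pl$same_seq)
  expect_true(is.na(pl$span))
  expect_false(pl$usable)
})

test_that("probe selection enforces the three criteria with strict span range", {
  th <- thresholds()
  mk <- function(span, unique1 = TRUE, unique2 = TRUE, orient = TRUE,
                 start = 500000)
    data.frame(clone_id = sprintf("S%d", span), e1_seq = "chr1",
               e1_start = start, e1_end = start + 600, e1_strand = "+",
               e1_unique = unique1, e1_hit = TRUE, e2_seq = "chr1",
               e2_start = start + span - 600, e2_end = start + span,
               e2_strand = "-", e2_unique = unique2, e2_hit = TRUE,
               same_seq = TRUE, insert_start = start,
               insert_end = start + span, span = span,
               orientation_ok = orient,
               usable = unique1 && unique2 && orient,
               stringsAsFactors = FALSE)
  region <- interval("chr1", 400000, 900000)
  pls <- rbind(mk(49999), mk(50000), mk(120000), mk(300000), mk(300001),
               mk(120000, unique1 = FALSE), mk(120000, orient = FALSE))
  sel <- select_probes_for_region(region, pls, th)
  expect_setequal(sel$clone_id, c("S50000", "S120000", "S300000"))
  for (i in seq_len(nrow(sel))) {
    expect_true(sel$usable[i])
    expect_gte(sel$span[i], th$bes_span_min)
    expect_lte(sel$span[i], th$bes_span_max)
  }
})

test_that("inversion plans have the inside/flank geometry, or are infeasible", {
  b <- small_bundle()
  res <- small_result()
  inv <- res$kept[res$kept$category == "INV", ][1, ]
  plan <- res$plans[[inv$code]]
  expect_true(plan$feasible)
  expect_setequal(plan$probes$role, c("inside", "flank-left", "flank-right"))
  p <- plan$probes
  ins <- p[p$role == "inside", ]
  expect_gte(ins$insert_start, inv$a_start)
  expect_lte(ins$insert_end, inv$a_end)
  expect_lte(p$insert_end[p$role == "flank-left"], inv$a_start)
  expect_gte(p$insert_start[p$role == "flank-right"], inv$a_end)
  # pairwise non-overlapping inserts
  expect_true(all(sort(p$insert_start)[-1] >=
                  sort(p$insert_end)[-3]))
  # a sub-eligible inversion violates the precondition
  fake <- inv; fake$eligibility <- "reportable"
  expect_error(plan_inversion_test(fake, res$placements_a), "test-eligible")
  # an empty library yields an infeasible plan
  empty <- res$placements_a[0, ]
  expect_false(plan_inversion_test(inv, empty)$feasible)
})

test_that("the reference panel picks one concordant unique clone per chromosome", {
  res <- small_result()
  b <- small_bundle()
  panel <- res$reference_panel
  expect_equal(nrow(panel), length(chromosomes(b$a)))
  expect_true(all(panel$found))
  expect_equal(anyDuplicated(panel$chrom), 0)
  blocks <- res$blocks
  for (i in seq_len(nrow(panel))) {
    bl <- blocks[blocks$a_seq == panel$chrom[i] &
                 blocks$orientation == "same", ]
    inside <- any(panel$insert_start[i] >= bl$a_start &
                  panel$insert_end[i] <= bl$a_end)
    expect_true(inside)
  }
})

test_that("a chromosome fully discordant has no reference clone", {
  true <- generate_true_genome(1, 1.2e6, seed = 45)
  ev <- event_spec("inversion", "A", "chr1", 20000, 1180000)
  der <- derive_assemblies(true, list(ev))
  blocks <- chain_anchors(find_anchors(der$a$seq[[1]], der$b$seq[[1]], 50,
                                       "chr1", "chr1"))
  lib <- generate_bes_library(true, 100, seed = 46)
  pl <- map_bes_library(lib, der$a)
  panel <- build_reference_panel(blocks, pl, der$a)
  expect_false(panel$found[1])
})

test_that("junction PCR supports the assembly matching the truth", {
  true <- generate_true_genome(1, 2e6, seed = 47)
  # relocation applied to A; B equals the truth
  ev <- event_spec("relocation", "A", "chr1", 400000, 640000,
                   dest_pos = 1400000)
  der <- derive_assemblies(true, list(ev))
  blocks <- chain_anchors(find_anchors(der$a$seq[[1]], der$b$seq[[1]], 50,
                                       "chr1", "chr1"))
  disc <- classify_discordances(blocks, der$a, der$b)
  mdp <- disc[disc$category == "MDP", ][1, ]
  assays <- design_junction_pcr(mdp, der$a, der$b)
  expect_true(all(assays$feasible))
  expect_true(all(assays$predicted_amplicon <= thresholds()$pcr_amplicon_max))
  v <- pcr_verdict(assays, true)
  expect_identical(v$supported, "hypothesis-B")
  expect_true(in_silico_pcr(assays[assays$hypothesis == "B", ], true))
  expect_false(in_silico_pcr(assays[assays$hypothesis == "A", ], true))
})

test_that("a truth matching neither assembly gives both-negative PCR", {
  true <- generate_true_genome(1, 2e6, seed = 48)
  evs <- list(event_spec("relocation", "A", "chr1", 400000, 640000,
                         dest_pos = 1400000),
              event_spec("relocation", "B", "chr1", 400000, 640000,
                         dest_pos = 1700000))
  der <- derive_assemblies(true, evs)
  blocks <- chain_anchors(find_anchors(der$a$seq[[1]], der$b$seq[[1]], 50,
                                       "chr1", "chr1"))
  disc <- classify_discordances(blocks, der$a, der$b)
  mdp <- disc[disc$category == "MDP", ][1, ]
  assays <- design_junction_pcr(mdp, der$a, der$b)
  v <- pcr_verdict(assays, true)
  expect_identical(v$supported, "neither")
  expect_identical(format_verdict(v), "-")
})

test_that("amplicons beyond the long-PCR ceiling are infeasible", {
  b <- small_bundle()
  res <- small_result()
  mdp <- res$kept[res$kept$category == "MDP", ][1, ]
  assays <- design_junction_pcr(mdp, b$a, b$b, flank = 10000)
  expect_false(any(assays$feasible))   # 2*(10000+25) bp > 12 kbp ceiling
})
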