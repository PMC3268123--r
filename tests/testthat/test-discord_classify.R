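# Classification of planted events; uses the shared small bundle (one
# inversion, one relocation, one unplaced segment on three chromosomes).

classified_small <- function() {
  cached("classified_small", {
    b <- small_bundle()
    blocks <- NULL
    for (ch in chromosomes(b$a))
      blocks <- rbind(blocks, chain_anchors(
        find_anchors(b$a$seq[[ch]], b$b$seq[[ch]], 50, ch, ch)))
    disc <- classify_discordances(blocks, b$a, b$b)
    pair_odss(disc, b$a, b$b)
  })
}

test_that("planted events map to their categories with tight breakpoints", {
  b <- small_bundle()
  disc <- classified_small()
  rep_rows <- disc[disc$eligibility != "sub-threshold", ]
  expect_setequal(rep_rows$category, c("INV", "MDP", "ODS"))
  inv <- rep_rows[rep_rows$category == "INV", ]
  expect_equal(nrow(inv), 1)
  expect_identical(inv$a_seq, "chr1")
  expect_lt(abs(inv$a_start - 300000), 50050)
  expect_lt(abs(inv$a_end - 900000), 50050)
  expect_identical(inv$eligibility, "test-eligible")
  mdp <- rep_rows[rep_rows$category == "MDP", ]
  expect_equal(nrow(mdp), 1)
  expect_identical(mdp$a_seq, "chr2")
  # the moved segment, not the intervening block, is flagged: the event
  # was applied to B, so A holds the truth position [150k,390k) and B the
  # relocated one
  expect_lt(abs(mdp$a_start - 150000), 1000)
  expect_gt(abs(mdp$b_start - mdp$a_start), 240000)
  ods <- rep_rows[rep_rows$category == "ODS", ]
  expect_equal(nrow(ods), 1)
  expect_identical(ods$source, "B")   # segment retained only by B
  expect_identical(ods$b_seq, "chr3")
  expect_lt(abs(ods$b_start - 400000), 1000)
  expect_lt(abs(ods$b_end - 700000), 1000)
})

test_that("swapping the assemblies swaps loci and ODS sources", {
  b <- small_bundle()
  blocks_sw <- NULL
  for (ch in chromosomes(b$b))
    blocks_sw <- rbind(blocks_sw, chain_anchors(
      find_anchors(b$b$seq[[ch]], b$a$seq[[ch]], 50, ch, ch)))
  disc_sw <- classify_discordances(blocks_sw, b$b, b$a)
  disc <- classified_small()
  fwd <- disc[disc$eligibility != "sub-threshold" & disc$category != "DCM", ]
  swp <- disc_sw[disc_sw$eligibility != "sub-threshold", ]
  expect_equal(nrow(fwd), nrow(swp))
  for (i in seq_len(nrow(fwd))) {
    d <- fwd[i, ]
    if (d$category == "ODS") {
      m <- swp[swp$category == "ODS", ]
      expect_identical(m$source, "A")  # source flips with the swap
      expect_equal(m$a_start, d$b_start)
      expect_equal(m$a_end, d$b_end)
    } else {
      m <- swp[swp$category == d$category, ]
      expect_equal(m$a_start, d$b_start)
      expect_equal(m$b_start, d$a_start)
    }
  }
})

test_that("reportable discordances are disjoint from concordant block spans", {
  b <- small_bundle()
  disc <- classified_small()
  blocks <- NULL
  for (ch in chromosomes(b$a))
    blocks <- rbind(blocks, chain_anchors(
      find_anchors(b$a$seq[[ch]], b$b$seq[[ch]], 50, ch, ch)))
  rep_rows <- disc[disc$eligibility != "sub-threshold" &
                   disc$category == "ODS", ]
  for (i in seq_len(nrow(rep_rows))) {
    d <- rep_rows[i, ]
    side <- if (d$source == "A") "a" else "b"
    bl <- blocks[blocks[[paste0(side, "_seq")]] ==
                 d[[paste0(side, "_seq")]], ]
    ov <- pmin(bl[[paste0(side, "_end")]], d[[paste0(side, "_end")]]) -
          pmax(bl[[paste0(side, "_start")]], d[[paste0(side, "_start")]])
    expect_true(all(ov <= 0))
  }
})

test_that("cross-chromosome moves yield exactly one DCM joining two ODSs", {
  true <- generate_true_genome(2, c(1.5e6, 1.5e6), seed = 21)
  ev <- event_spec("cross_move", "B", "chr1", 400000, 700000,
                   dest_chrom = "chr2", dest_pos = 900000)
  der <- derive_assemblies(true, list(ev))
  blocks <- NULL
  for (ch in chromosomes(der$a))
    blocks <- rbind(blocks, chain_anchors(
      find_anchors(der$a$seq[[ch]], der$b$seq[[ch]], 50, ch, ch)))
  disc <- classify_discordances(blocks, der$a, der$b)
  disc <- pair_odss(disc, der$a, der$b)
  dcm <- disc[disc$category == "DCM", ]
  expect_equal(nrow(dcm), 1)
  expect_identical(dcm$code, "DCM_1-2")
  expect_identical(dcm$a_seq, "chr1")
  expect_identical(dcm$b_seq, "chr2")
  expect_true(is.na(dcm$dup_in))
  members <- disc[!is.na(disc$dcm_partner) & disc$category == "ODS", ]
  expect_equal(nrow(members), 2)
  expect_setequal(members$source, c("A", "B"))
  expect_true(all(members$dcm_partner == "DCM_1-2"))
})

test_that("disjoint unrelated ODSs yield no DCM", {
  true <- generate_true_genome(2, c(1e6, 1e6), seed = 22)
  evs <- list(event_spec("deletion", "A", "chr1", 300000, 550000),
              event_spec("deletion", "B", "chr2", 300000, 550000))
  der <- derive_assemblies(true, evs)
  blocks <- NULL
  for (ch in chromosomes(der$a))
    blocks <- rbind(blocks, chain_anchors(
      find_anchors(der$a$seq[[ch]], der$b$seq[[ch]], 50, ch, ch)))
  disc <- pair_odss(classify_discordances(blocks, der$a, der$b),
                    der$a, der$b)
  expect_equal(sum(disc$category == "DCM"), 0)
})

test_that("a duplication present in one assembly gives a one-sided DCM", {
  true <- generate_true_genome(2, c(1.5e6, 1.5e6), seed = 23)
  ev <- event_spec("dup_insert", "A", "chr1", 500000, 760000,
                   dest_chrom = "chr2", dest_pos = 1000000)
  der <- derive_assemblies(true, list(ev))
  blocks <- NULL
  for (ch in chromosomes(der$a))
    blocks <- rbind(blocks, chain_anchors(
      find_anchors(der$a$seq[[ch]], der$b$seq[[ch]], 50, ch, ch)))
  disc <- pair_odss(classify_discordances(blocks, der$a, der$b),
                    der$a, der$b)
  dcm <- disc[disc$category == "DCM", ]
  expect_equal(nrow(dcm), 1)
  expect_identical(dcm$dup_in, "A")
  expect_identical(dcm$a_seq, "chr2")  # extra copy location in A
  expect_identical(dcm$b_seq, "chr1")  # its single-copy source in B
})

test_that("gap/repeat exclusion uses the defining locus with a strict cutoff", {
  s_masked <- paste0(strrep("A", 20000), tolower(rand_seq(160000, 31)),
                     strrep("N", 20000), strrep("A", 10000))
  asm <- Assembly("A", c(chr1 = s_masked))
  d90 <- data.frame(code = "x", category = "ODS", a_seq = "chr1",
                    a_start = 10000, a_end = 210000, b_seq = NA,
                    b_start = NA, b_end = NA, size = 2e5, source = "A",
                    eligibility = "reportable", gap_repeat_flag = FALSE,
                    dcm_partner = NA, dup_in = NA, stringsAsFactors = FALSE)
  fl <- filter_gap_repeat(d90, asm, asm)
  expect_equal(nrow(fl$excluded), 1)   # 90% masked locus is excluded
  expect_true(fl$excluded$gap_repeat_flag)
  # all-uppercase locus is kept
  d0 <- d90; d0$a_start <- 0; d0$a_end <- 20000
  expect_equal(nrow(filter_gap_repeat(d0, asm, asm)$kept), 1)
  # exactly at the cutoff is kept (strict inequality excludes)
  s_edge <- paste0(strrep("a", 75), strrep("A", 25))
  asm2 <- Assembly("A", c(chr1 = strrep(s_edge, 3000)))
  de <- d90; de$a_start <- 0; de$a_end <- 300000
  expect_equal(nrow(filter_gap_repeat(de, asm2, asm2)$kept), 1)
})

test_that("codes reproduce the printed naming grammar", {
  expect_identical(assign_code("INV", "chr27", 42300000), "INV_27_42.3")
  expect_identical(assign_code("MDP", "chr5", 9600000), "MDP_5_9.6")
  expect_identical(assign_code("DCM", "chr3", 0, b_seq_id = "chr13"),
                   "DCM_3-13")
  # trailing .0 is dropped, as in the printed codes at whole Mbp
  expect_identical(assign_code("INV", "chr20", 0), "INV_20_0")
  expect_identical(assign_code("INV", "chr1", 24000000), "INV_1_24")
  # collisions get .2, .3 suffixes
  expect_identical(assign_code("INV", "chr1", 24000000,
                               existing = "INV_1_24"), "INV_1_24.2")
  expect_error(assign_code("INV", NA, 1), "absent locus")
})

test_that("mismatched chromosome pairs are rejected", {
  bad <- data.frame(block_id = 1L, a_seq = "chr1", a_start = 0, a_end = 10,
                    b_seq = "chr2", b_start = 0, b_end = 10,
                    orientation = "same", n_anchors = 1L, anchor_bp = 10)
  b <- small_bundle()
  expect_error(classify_discordances(bad, b$a, b$b), "mismatched")
})
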