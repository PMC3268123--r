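test_that("probe loci respect the visibility floor and count copies", {
  true <- generate_true_genome(6, rep(6e5, 6), seed = 51,
                               segdup_families = 1, segdup_copies = 6,
                               segdup_len = 30000,
                               segdup_placement = "subtelomeric")
  sd <- attr(true, "segdups")
  probe <- substr(true$seq[[sd$chrom[1]]], sd$start[1] + 1, sd$end[1])
  loci <- probe_loci(probe, true)
  expect_equal(nrow(loci), 6)
  expect_setequal(loci$chrom, unique(sd$chrom))
  # homology below the floor is silent: a probe whose only second-locus
  # homology is 4 kbp shows one locus, not two
  uniq <- substr(true$seq[["chr1"]], 100001, 250000)
  g2 <- Assembly("g2", c(chrA = paste0(rand_seq(50000, 52), uniq,
                                       rand_seq(50000, 53)),
                         chrB = paste0(rand_seq(60000, 54),
                                       substr(uniq, 1, 4000),
                                       rand_seq(60000, 55))))
  loci2 <- probe_loci(uniq, g2)
  expect_identical(unique(loci2$chrom), "chrA")
})

test_that("metaphase cells show one signal per visible locus", {
  true <- generate_true_genome(2, c(6e5, 6e5), seed = 56)
  probe <- substr(true$seq[["chr2"]], 200001, 350000)
  probes <- data.frame(probe_id = "P1", seq = probe)
  obs <- simulate_metaphase(probes, true, n_cells = 10, p_drop = 0, seed = 1)
  expect_equal(nrow(obs), 10)                     # one signal per cell
  expect_true(all(obs$chrom == "chr2"))
  expect_setequal(unique(obs$cell), 1:10)
  # a probe absent from the genome yields zero signals
  obs0 <- simulate_metaphase(data.frame(probe_id = "P0",
                                        seq = rand_seq(20000, 57)),
                             true, n_cells = 5, p_drop = 0, seed = 1)
  expect_equal(nrow(obs0), 0)
})

test_that("a probe over a six-copy duplication lights six signals per cell", {
  true <- generate_true_genome(6, rep(6e5, 6), seed = 58,
                               segdup_families = 1, segdup_copies = 6,
                               segdup_len = 30000,
                               segdup_placement = "subtelomeric")
  sd <- attr(true, "segdups")
  probe <- substr(true$seq[[sd$chrom[1]]], sd$start[1] + 1, sd$end[1])
  obs <- simulate_metaphase(data.frame(probe_id = "U", seq = probe), true,
                            n_cells = 4, p_drop = 0, seed = 2)
  per_cell <- table(obs$cell)
  expect_true(all(per_cell == 6))
})

test_that("interphase counts are conserved and hit the closed form", {
  pos <- c(L = 100, I = 300, R = 1000)
  cnt0 <- simulate_interphase_triplet(pos, n_nuclei = 50, disorder_p = 0,
                                      seed = 3)
  expect_equal(sum(cnt0), 50)
  expect_equal(unname(cnt0[["L-I-R"]]), 50)   # I nearer L: proximity-first
  expect_equal(sum(simulate_interphase_triplet(pos, n_nuclei = 0)), 0)
  # at disorder 0.3 the true-arrangement fraction has expectation
  # 0.7 + 0.3/6 = 0.75; check within 3 binomial sigma over 2000 nuclei
  cnt <- simulate_interphase_triplet(pos, n_nuclei = 2000, disorder_p = 0.3,
                                     seed = 4)
  expect_equal(sum(cnt), 2000)
  frac <- cnt[["L-I-R"]] / 2000
  sigma <- sqrt(0.75 * 0.25 / 2000)
  expect_lt(abs(frac - 0.75), 3 * sigma)
  # probes on different chromosomes need the metaphase modality
  expect_error(simulate_interphase_triplet(pos, chroms = c("c1", "c1", "c2")),
               "metaphase")
})

test_that("interphase decisions follow the majority with printed support", {
  counts <- setNames(integer(6),
                     c("L-I-R", "L-R-I", "I-L-R", "I-R-L", "R-L-I", "R-I-L"))
  counts["R-I-L"] <- 45
  counts["L-I-R"] <- 5
  v <- decide(counts, c("L", "I", "R"), c("R", "I", "L"), "interphase")
  expect_identical(v$supported, "hypothesis-B")
  expect_equal(v$support_fraction, 0.90)
  expect_identical(format_verdict(v, "draft1", "draft2"), "draft2 (90%)")
  # identical predictions cannot discriminate
  v2 <- decide(counts, c("R", "I", "L"), c("R", "I", "L"), "interphase")
  expect_identical(v2$supported, "both-consistent")
  # neither hypothesis reaching half the nuclei gives "neither"
  counts3 <- counts; counts3[] <- c(10, 8, 8, 8, 8, 8)
  v3 <- decide(counts3, c("L", "I", "R"), c("R", "I", "L"), "interphase")
  expect_identical(v3$supported, "neither")
  expect_error(decide(setNames(integer(6), names(counts)),
                      c("L", "I", "R"), c("R", "I", "L"), "interphase"),
               "no cells")
})

test_that("metaphase decisions compare modal assignment multisets", {
  obs <- data.frame(cell = rep(1:10, each = 1), probe_id = "P",
                    chrom = "chr7", pos = 1e5)
  class(obs) <- c("FISHObservation", "data.frame")
  v <- decide(obs, list(P = "chr10"), list(P = "chr7"), "metaphase")
  expect_identical(v$supported, "hypothesis-B")
  expect_identical(format_verdict(v, "draft1", "draft2"), "draft2")
  # neither hypothesis matching the modal observation
  v2 <- decide(obs, list(P = "chr10"), list(P = "chr12"), "metaphase")
  expect_identical(v2$supported, "neither")
  # multiset semantics: a duplicated prediction differs from a single one
  obs2 <- rbind(obs, data.frame(cell = 1:10, probe_id = "P", chrom = "chr2",
                                pos = 5e4))
  class(obs2) <- c("FISHObservation", "data.frame")
  v3 <- decide(obs2, list(P = c("chr2", "chr7")), list(P = "chr7"),
               "metaphase")
  expect_identical(v3$supported, "hypothesis-A")
})

test_that("decisions are invariant under consistent probe relabeling", {
  counts <- setNames(integer(6),
                     c("L-I-R", "L-R-I", "I-L-R", "I-R-L", "R-L-I", "R-I-L"))
  counts["R-I-L"] <- 40; counts["L-I-R"] <- 10
  v1 <- decide(counts, c("L", "I", "R"), c("R", "I", "L"), "interphase")
  relabel <- c(L = "x", I = "y", R = "z")
  counts2 <- counts
  names(counts2) <- vapply(strsplit(names(counts), "-"), function(p)
    paste(relabel[p], collapse = "-"), character(1))
  v2 <- decide(counts2, relabel[c("L", "I", "R")], relabel[c("R", "I", "L")],
               "interphase")
  expect_identical(v1$supported, v2$supported)
  expect_equal(v1$support_fraction, v2$support_fraction)
})

test_that("triplet arrangements read proximity-first", {
  expect_identical(triplet_pattern(c(L = 0, I = 200, R = 1000)),
                   c("L", "I", "R"))
  expect_identical(triplet_pattern(c(L = 0, I = 800, R = 1000)),
                   c("R", "I", "L"))
  # an inversion moving the internal probe across the centre flips the
  # arrangement even though the positional order is unchanged
  s <- 1000; e <- 2000; x <- 1200
  expect_false(identical(triplet_pattern(c(L = 900, I = x, R = 2100)),
                         triplet_pattern(c(L = 900, I = s + e - x,
                                           R = 2100))))
})
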