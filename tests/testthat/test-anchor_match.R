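test_that("identity and reverse-complement sequences give one full anchor", {
  x <- rand_seq(100000, seed = 2)
  an <- find_anchors(x, x)
  expect_equal(nrow(an), 1)
  expect_equal(an$a_start, 0)
  expect_equal(an$a_end, 100000)
  expect_identical(an$orientation, "same")
  an2 <- find_anchors(x, reverse_complement(x))
  expect_equal(nrow(an2), 1)
  expect_equal(an2$length, 100000)
  expect_identical(an2$orientation, "inverted")
})

test_that("anchors around a planted shared segment match the brute-force oracle", {
  set.seed(10)
  for (rep in 1:10) {
    a <- rand_seq(8000)
    b <- rand_seq(8000)
    seg <- substr(a, 3001, 4000)
    b <- paste0(substr(b, 1, 2000), seg, substr(b, 3001, 8000))
    k <- 50
    got <- find_anchors(a, b, k)
    want <- oracle_anchors(a, b, k)
    expect_identical(anchor_key(got), anchor_key(want))
  }
})

test_that("anchors are sound, maximal and symmetric", {
  set.seed(20)
  for (rep in 1:8) {
    a <- rand_seq(5000)
    b <- rand_seq(5000)
    seg <- substr(a, 1001, 1600)
    ins <- if (rep %% 2 == 0) reverse_complement(seg) else seg
    b <- paste0(substr(b, 1, 3000), ins, substr(b, 3601, 5000))
    an <- find_anchors(a, b, 50)
    expect_gt(nrow(an), 0)
    for (i in seq_len(nrow(an))) {
      r <- an[i, ]
      sa <- toupper(substr(a, r$a_start + 1, r$a_end))
      sb <- toupper(substr(b, r$b_start + 1, r$b_end))
      if (r$orientation == "inverted") sb <- reverse_complement(sb)
      expect_identical(sa, sb)  # soundness
      # maximality: extending one bp on either side breaks the match
      if (r$orientation == "same") {
        if (r$a_start > 0 && r$b_start > 0)
          expect_false(substr(a, r$a_start, r$a_start) ==
                       substr(b, r$b_start, r$b_start))
        if (r$a_end < nchar(a) && r$b_end < nchar(b))
          expect_false(substr(a, r$a_end + 1, r$a_end + 1) ==
                       substr(b, r$b_end + 1, r$b_end + 1))
      }
    }
    # symmetry: swapping the sequences swaps the coordinate fields
    sw <- find_anchors(b, a, 50)
    expect_identical(anchor_key(sw),
                     sort(paste(an$b_start, an$b_end, an$a_start, an$a_end,
                                an$orientation)))
  }
})

test_that("repeat-only matches are suppressed, unique matches run through repeats", {
  set.seed(30)
  core <- rand_seq(3000)
  rep_unit <- tolower(rand_seq(400))
  # same repeat flanked by different unique sequence in a and b: the
  # repeat-only match must be suppressed, while a unique match running
  # through its own repeat copy is kept in full
  a <- paste0(rand_seq(1000), rep_unit, core)
  b <- paste0(rand_seq(1000), rep_unit, core)
  an <- find_anchors(a, b, 50)
  expect_gte(max(an$length), 3000)       # the shared core (+ repeat run-in)
  # repeat-only matches (both sides almost completely masked) are dropped
  mostly_masked <- vapply(seq_len(nrow(an)), function(i) {
    seg <- substr(a, an$a_start[i] + 1, an$a_end[i])
    nchar(gsub("[A-Z]", "", seg)) / nchar(seg) > 0.75
  }, logical(1))
  expect_false(any(mostly_masked))
})

test_that("chaining joins colinear runs and splits at gaps and orientation", {
  mk <- function(a_start, b_start, len = 100, orientation = "same")
    data.frame(a_seq = "A", a_start = a_start, a_end = a_start + len,
               b_seq = "B", b_start = b_start, b_end = b_start + len,
               orientation = orientation, length = len,
               stringsAsFactors = FALSE)
  # colinear, gaps below max_gap: one block
  an <- rbind(mk(0, 0), mk(200, 200), mk(500, 500))
  bl <- chain_anchors(an, max_gap = 1000, max_drift = 100)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$n_anchors, 3)
  expect_equal(bl$anchor_bp, 300)
  expect_equal(bl$a_start, 0); expect_equal(bl$a_end, 600)
  # a hole of twice max_gap: exactly two blocks
  an2 <- rbind(mk(0, 0), mk(200, 200), mk(2400, 2400), mk(2600, 2600))
  bl2 <- chain_anchors(an2, max_gap = 1000, max_drift = 100)
  expect_equal(nrow(bl2), 2)
  # orientation flip always splits
  an3 <- rbind(mk(0, 0), mk(200, 500, orientation = "inverted"))
  expect_equal(nrow(chain_anchors(an3, 1e6, 1e6)), 2)
  # drift above max_drift splits
  an4 <- rbind(mk(0, 0), mk(200, 400))
  expect_equal(nrow(chain_anchors(an4, 1000, 100)), 2)
  expect_equal(nrow(chain_anchors(an4, 1000, 300)), 1)
  # empty input, empty output
  expect_equal(nrow(chain_anchors(an[0, ])), 0)
})

test_that("chaining equals the exhaustive optimal-partition oracle", {
  set.seed(40)
  for (rep in 1:12) {
    n <- sample(2:12, 1)
    a_start <- cumsum(sample(c(50, 200, 1500), n, replace = TRUE))
    drift <- cumsum(sample(c(0, 0, 400), n, replace = TRUE))
    orientation <- sample(c("same", "same", "inverted"), n, replace = TRUE)
    len <- sample(50:120, n, replace = TRUE)
    an <- data.frame(a_seq = "A", a_start = a_start, a_end = a_start + len,
                     b_seq = "B",
                     b_start = ifelse(orientation == "same",
                                      a_start + drift, 1e6 - a_start),
                     orientation = orientation, length = len,
                     stringsAsFactors = FALSE)
    an$b_end <- an$b_start + len
    got <- chain_anchors(an, max_gap = 700, max_drift = 300)
    want_groups <- oracle_chain_groups(an, max_gap = 700, max_drift = 300)
    expect_equal(nrow(got), max(want_groups))
    # same partition: anchors of one oracle group lie inside one block span
    ord <- order(an$a_start, an$b_start)
    for (g in unique(want_groups)) {
      idx <- ord[want_groups == g]
      hull <- c(min(an$a_start[idx]), max(an$a_end[idx]))
      expect_true(any(got$a_start == hull[1] & got$a_end == hull[2]))
    }
  }
})

test_that("anchor inputs are validated", {
  expect_error(find_anchors("", "ACGT"), "empty")
  expect_error(find_anchors("ACGT", "ACGT", min_anchor = 10), ">= 20")
  mixed <- data.frame(a_seq = c("x", "y"), a_start = c(0, 1), a_end = c(5, 6),
                      b_seq = "z", b_start = c(0, 1), b_end = c(5, 6),
                      orientation = "same", length = 5)
  expect_error(chain_anchors(mixed), "single sequence pair")
})

test_that("anchors export to PAF-like records", {
  x <- rand_seq(60000, seed = 50)
  an <- find_anchors(x, x)
  paf <- anchors_as_paf(an, nchar(x), nchar(x))
  expect_identical(paf$strand, "+")
  expect_equal(paf$nmatch, an$length)
  expect_equal(paf$qstart, an$a_start)
})
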