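# Shared fixtures, built in code and memoised for the duration of the test
# run (the expensive ones are reused across test files).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

rand_seq <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Compact three-chromosome bundle with one event of each headline category,
# used by the classification / probe / pipeline tests.
small_bundle <- function() {
  cached("small_bundle", {
    true <- generate_true_genome(3, rep(1.2e6, 3), repeat_family_count = 1,
                                 repeat_copies = 12, seed = 11,
                                 repeat_len = 1500)
    events <- list(
      event_spec("inversion", "A", "chr1", 300000, 900000),
      event_spec("relocation", "B", "chr2", 150000, 390000,
                 dest_pos = 950000),
      event_spec("unplace", "A", "chr3", 400000, 700000))
    der <- derive_assemblies(true, events)
    bes <- generate_bes_library(true, 500, seed = 12)
    c(list(true = true, bes = bes, events = events), der)
  })
}

small_result <- function() {
  cached("small_result", {
    b <- small_bundle()
    cfg <- run_config(b$a, b$b, bes = b$bes, truth = b$true, seed = 99)
    run_compare(cfg, verbose = FALSE)
  })
}

# Replicated full-pipeline runs under the standard study conditions
# (8 chromosomes x 2 Mbp, 12-13 planted events spanning every kind, 1600
# BES clones, paper cell counts). Used by the planted-event recovery and
# FISH decision tests.
acceptance_replicates <- function(n_rep = 20) {
  cached("acceptance_replicates", {
    lapply(seq_len(n_rep), function(r) {
      b <- simulate_bundle(seed = 1000 + r)
      cfg <- run_config(b$a, b$b, bes = b$bes, truth = b$true,
                        seed = 2000 + r)
      res <- run_compare(cfg, verbose = FALSE)
      rec <- evaluate_recovery(res$kept, b$expected)
      sv <- score_verdicts(res$fish, res$kept, rec, b$truth)
      list(recovery = rec, verdicts = sv,
           fish = res$fish$table,
           counts = res$category_counts)
    })
  })
}

# ---------------------------------------------------------------------------
# Independent oracles
# ---------------------------------------------------------------------------

# Brute-force k-mer-scan oracle for maximal exact matches (both strands,
# uppercase sequences, no masking rules): hash every k-mer of b, scan every
# k-mer of a, extend each seed maximally character by character, and
# deduplicate. Quadratic and entirely independent of the package's
# seed-and-extend implementation.
oracle_anchors <- function(a, b, k) {
  one_strand <- function(a, b, orientation) {
    na <- nchar(a); nb <- nchar(b)
    if (na < k || nb < k) return(NULL)
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    kb <- substring(b, 1:(nb - k + 1), k:nb)
    idx <- split(seq_along(kb), kb)
    ka <- substring(a, 1:(na - k + 1), k:na)
    seen <- new.env(parent = emptyenv())
    out <- NULL
    for (i in seq_along(ka)) {
      js <- idx[[ka[i]]]
      if (is.null(js)) next
      for (j in js) {
        ai <- i - 1; bj <- j - 1   # 0-based seed starts
        while (ai > 0 && bj > 0 && av[ai] == bv[bj]) { ai <- ai - 1; bj <- bj - 1 }
        ae <- i - 1 + k; be <- j - 1 + k
        while (ae < na && be < nb && av[ae + 1] == bv[be + 1]) {
          ae <- ae + 1; be <- be + 1
        }
        key <- paste(ai, bj)
        if (!is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        if (ae - ai >= k)
          out <- rbind(out, data.frame(a_start = ai, a_end = ae,
                                       b_start = bj, b_end = be,
                                       orientation = orientation,
                                       length = ae - ai,
                                       stringsAsFactors = FALSE))
      }
    }
    out
  }
  fw <- one_strand(a, b, "same")
  rcb <- reverse_complement(b)
  rc <- one_strand(a, rcb, "inverted")
  if (!is.null(rc) && nrow(rc)) {
    nb <- nchar(b)
    bs <- nb - rc$b_end
    rc$b_end <- nb - rc$b_start
    rc$b_start <- bs
  }
  out <- rbind(fw, rc)
  if (is.null(out))
    out <- data.frame(a_start = numeric(0), a_end = numeric(0),
                      b_start = numeric(0), b_end = numeric(0),
                      orientation = character(0), length = numeric(0))
  out[order(out$a_start, out$b_start, out$orientation), , drop = FALSE]
}

anchor_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$a_start, df$a_end, df$b_start, df$b_end, df$orientation))
}

# Exhaustive optimal-partition oracle for chaining: over anchors sorted by
# A-start, enumerate every partition into contiguous segments, keep those
# in which every adjacent pair satisfies the joining predicate, and return
# the one with the fewest segments (equivalently, the maximal total
# within-block chained anchor bp). Independent of the greedy implementation.
oracle_chain_groups <- function(anchors, max_gap, max_drift) {
  anchors <- anchors[order(anchors$a_start, anchors$b_start), , drop = FALSE]
  n <- nrow(anchors)
  if (n == 0) return(integer(0))
  joinable <- vapply(seq_len(n - 1), function(i) {
    prev <- anchors[i, ]; cur <- anchors[i + 1, ]
    if (prev$orientation != cur$orientation) return(FALSE)
    if (cur$a_start - prev$a_end > max_gap) return(FALSE)
    if (cur$orientation == "same") {
      if (cur$b_start - prev$b_end > max_gap || cur$b_start < prev$b_start)
        return(FALSE)
      drift <- abs((cur$b_start - cur$a_start) - (prev$b_start - prev$a_start))
    } else {
      if (prev$b_start - cur$b_end > max_gap || cur$b_end > prev$b_end)
        return(FALSE)
      drift <- abs((cur$b_end + cur$a_start) - (prev$b_end + prev$a_start))
    }
    drift <= max_drift
  }, logical(1))
  if (n == 1) return(1L)
  if (n <= 14) {
    best <- NULL
    for (mask in 0:(2^(n - 1) - 1)) {
      breaks <- as.logical(bitwAnd(mask, 2^(0:(n - 2))))
      valid <- all(joinable | breaks)
      if (!valid) next
      groups <- cumsum(c(TRUE, breaks))
      if (is.null(best) || max(groups) < max(best)) best <- groups
    }
    best
  } else {
    # for larger inputs the optimum is the partition breaking exactly at
    # the non-joinable adjacent pairs (the enumeration above verifies this
    # characterization on every input small enough to enumerate)
    cumsum(c(TRUE, !joinable))
  }
}
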