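# Exact-match anchors and colinear synteny blocks between two sequences.

#' Find exact-match anchors between two sequences
#'
#' Reports every maximal exact match of length >= `min_anchor` between
#' `seq_a` and `seq_b`, on both strands. Matching is case-insensitive
#' (soft-masking does not interrupt a match) and `N` never matches; an
#' anchor that is almost completely soft-masked on both sides (masked
#' fraction > 0.75 on the less-masked side) is suppressed as a match
#' between distinct repeat copies, while unique matches running through a
#' repeat are retained in full. For an inverted anchor the A segment
#' equals the reverse complement of the B segment.
#'
#' @param seq_a,seq_b nucleotide strings.
#' @param min_anchor minimal anchor length in bp (>= 20; default 50).
#' @param a_id,b_id sequence ids recorded in the output.
#' @return data.frame with columns
#'   `a_seq,a_start,a_end,b_seq,b_start,b_end,orientation,length`
#'   (0-based half-open; `orientation` is `"same"` or `"inverted"`),
#'   sorted by `a_start`.
#' @export
find_anchors <- function(seq_a, seq_b, min_anchor = 50,
                         a_id = "A", b_id = "B") {
  anchor_scan(seq_a, setNames(seq_b, b_id), min_anchor, q_id = a_id)
}

# multi-target anchor scan: the query is indexed once (both strands) and
# every target scanned against it; output uses the find_anchors() schema
# with the query on the A side.
anchor_scan <- function(query, targets, min_anchor = 50, q_id = "A") {
  if (!nzchar(query) || any(!nzchar(targets))) stop("empty sequence")
  if (min_anchor < 20) stop("min_anchor must be >= 20")
  if (is.null(names(targets))) names(targets) <- seq_along(targets)
  hits <- cpp_anchor_scan(query, unname(targets), min_anchor, TRUE)
  if (nrow(hits) == 0) return(empty_anchor_df())
  nq <- nchar(query)
  inv <- hits$strand == "-"
  a_start <- ifelse(inv, nq - (hits$q_start + hits$length), hits$q_start)
  res <- data.frame(a_seq = q_id, a_start = a_start,
                    a_end = a_start + hits$length,
                    b_seq = names(targets)[hits$target],
                    b_start = hits$t_start,
                    b_end = hits$t_start + hits$length,
                    orientation = ifelse(inv, "inverted", "same"),
                    length = hits$length, stringsAsFactors = FALSE)
  # Masking policy: matching is case-insensitive (a unique match may run
  # straight through a soft-masked repeat), but an anchor that is almost
  # completely masked on both sides carries no positional information -
  # it is a match between distinct copies of a repeat - and is dropped.
  # Taking the minimum of the two sides keeps the rule symmetric under
  # swapping the sequences.
  mf <- vapply(seq_len(nrow(res)), function(i) {
    fa <- cpp_masked_count(query, as.integer(res$a_start[i]),
                           as.integer(res$a_end[i]))
    fb <- cpp_masked_count(targets[[res$b_seq[i]]],
                           as.integer(res$b_start[i]),
                           as.integer(res$b_end[i]))
    min(fa, fb) / res$length[i]
  }, numeric(1))
  res <- res[mf <= 0.75, , drop = FALSE]
  if (nrow(res) == 0) return(empty_anchor_df())
  res <- res[order(res$b_seq, res$a_start, res$b_start, res$orientation), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_anchor_df <- function() {
  data.frame(a_seq = character(0), a_start = numeric(0), a_end = numeric(0),
             b_seq = character(0), b_start = numeric(0), b_end = numeric(0),
             orientation = character(0), length = numeric(0),
             stringsAsFactors = FALSE)
}

# joining predicate for consecutive anchors (sorted by a_start)
anchors_joinable <- function(prev, cur, max_gap, max_drift) {
  if (prev$orientation != cur$orientation) return(FALSE)
  gap_a <- cur$a_start - prev$a_end
  if (gap_a > max_gap) return(FALSE)
  if (cur$orientation == "same") {
    gap_b <- cur$b_start - prev$b_end
    if (gap_b > max_gap || cur$b_start < prev$b_start) return(FALSE)
    drift <- abs((cur$b_start - cur$a_start) - (prev$b_start - prev$a_start))
  } else {
    gap_b <- prev$b_start - cur$b_end
    if (gap_b > max_gap || cur$b_end > prev$b_end) return(FALSE)
    drift <- abs((cur$b_end + cur$a_start) - (prev$b_end + prev$a_start))
  }
  drift <= max_drift
}

#' Chain anchors into colinear synteny blocks
#'
#' Anchors (from one sequence pair) are sorted by A-start and joined into
#' maximal runs in which every consecutive pair shares the orientation,
#' advances colinearly on both genomes with a gap of at most `max_gap`, and
#' changes diagonal offset by at most `max_drift`. Every anchor belongs to
#' exactly one block; this maximal-run partition is the unique partition of
#' the sorted anchor list into the fewest contiguous valid chains. Defaults
#' are deliberately below the 100 kbp reporting floor so chaining artifacts
#' cannot create reportable discordances.
#'
#' @param anchors data.frame from [find_anchors()].
#' @param max_gap maximal gap on either genome between chained anchors (bp).
#' @param max_drift maximal diagonal-offset change between chained anchors.
#' @return data.frame of blocks with columns `block_id,a_seq,a_start,a_end,
#'   b_seq,b_start,b_end,orientation,n_anchors,anchor_bp`, sorted by
#'   `a_start`; spans are the coordinate hulls of the member anchors.
#' @export
chain_anchors <- function(anchors, max_gap = 50000, max_drift = 20000) {
  if (nrow(anchors) == 0)
    return(data.frame(block_id = integer(0), a_seq = character(0),
                      a_start = numeric(0), a_end = numeric(0),
                      b_seq = character(0), b_start = numeric(0),
                      b_end = numeric(0), orientation = character(0),
                      n_anchors = integer(0), anchor_bp = numeric(0),
                      stringsAsFactors = FALSE))
  if (length(unique(anchors$a_seq)) > 1 || length(unique(anchors$b_seq)) > 1)
    stop("anchors must come from a single sequence pair")
  anchors <- anchors[order(anchors$a_start, anchors$b_start), , drop = FALSE]
  n <- nrow(anchors)
  grp <- integer(n)
  grp[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      joined <- anchors_joinable(anchors[i - 1, ], anchors[i, ],
                                 max_gap, max_drift)
      grp[i] <- if (joined) grp[i - 1] else grp[i - 1] + 1L
    }
  }
  blocks <- do.call(rbind, lapply(split(seq_len(n), grp), function(idx) {
    aa <- anchors[idx, , drop = FALSE]
    data.frame(a_seq = aa$a_seq[1], a_start = min(aa$a_start),
               a_end = max(aa$a_end), b_seq = aa$b_seq[1],
               b_start = min(aa$b_start), b_end = max(aa$b_end),
               orientation = aa$orientation[1], n_anchors = nrow(aa),
               anchor_bp = sum(aa$length), stringsAsFactors = FALSE)
  }))
  blocks <- blocks[order(blocks$a_start, blocks$b_start), , drop = FALSE]
  blocks <- cbind(block_id = seq_len(nrow(blocks)), blocks)
  rownames(blocks) <- NULL
  blocks
}

#' Write anchors or blocks as TSV (1-based inclusive coordinates)
#' @param x an anchor or block data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_anchor_tsv <- function(x, path) {
  write_tsv(to_report_coords(x, start_cols = intersect(
    c("a_start", "b_start"), names(x))), path)
}

#' Anchors as PAF-like records
#'
#' Minimal PAF columns (query = A, target = B) for external dot-plot
#' viewers; residue matches equal block length because anchors are exact.
#'
#' @param anchors data.frame from [find_anchors()].
#' @param a_len,b_len total lengths of the two sequences.
#' @return data.frame in PAF column order.
#' @export
anchors_as_paf <- function(anchors, a_len, b_len) {
  data.frame(qname = anchors$a_seq, qlen = a_len, qstart = anchors$a_start,
             qend = anchors$a_end,
             strand = ifelse(anchors$orientation == "same", "+", "-"),
             tname = anchors$b_seq, tlen = b_len, tstart = anchors$b_start,
             tend = anchors$b_end, nmatch = anchors$length,
             alen = anchors$length, mapq = 255L, stringsAsFactors = FALSE)
}
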