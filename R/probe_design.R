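# BAC probe selection from a BES library, inversion triplets, the
# chromosome reference panel, and junction long-PCR assays.

#' Map the end sequences of BAC clones onto an assembly
#'
#' Each end is mapped by seeded, ungapped near-exact search (up to
#' `mm_per_100` mismatches per 100 bp, which tolerates the substitution
#' noise of planted repeat copies). An end is flagged non-unique when two
#' or more hits tie at the best mismatch count. A clone placement implies
#' an insert only when both ends hit the same sequence; the orientation is
#' acceptable when the ends lie on opposite strands facing inward.
#'
#' @param lib a `BESLibrary` data.frame (see [generate_bes_library()]), or
#'   any data.frame with `clone_id, end1, end2`.
#' @param asm target `Assembly`.
#' @param k seed length (bp).
#' @param mm_per_100 mismatch budget per 100 bp of end sequence.
#' @return data.frame, one row per clone: per-end hit coordinates, strand,
#'   hit/unique flags, plus `same_seq, insert_start, insert_end, span,
#'   orientation_ok, usable` (usable = both ends unique, same sequence,
#'   inward opposite orientation).
#' @export
map_bes_library <- function(lib, asm, k = 31, mm_per_100 = 2) {
  n <- nrow(lib)
  queries <- c(lib$end1, lib$end2)
  hits <- cpp_map_queries(unname(asm$seq), queries, as.integer(k), mm_per_100)
  subj_ids <- names(asm$seq)

  best_of <- function(qi) {
    h <- hits[hits$query == qi, , drop = FALSE]
    if (!nrow(h))
      return(list(hit = FALSE, seq = NA_character_, start = NA_real_,
                  end = NA_real_, strand = NA_character_, unique = FALSE,
                  n_best = 0L))
    h <- h[order(h$mismatches, h$subject, h$start), , drop = FALSE]
    b <- h[1, ]
    # unique = no second hit within the mapper's mismatch tolerance: an
    # end inside a repeat family still matches its own copy exactly, so a
    # best-hit tie rule would wrongly call it unique
    list(hit = TRUE, seq = subj_ids[b$subject], start = b$start,
         end = b$start + b$length, strand = b$strand,
         unique = nrow(h) == 1L, n_best = nrow(h))
  }

  rows <- lapply(seq_len(n), function(i) {
    e1 <- best_of(i)
    e2 <- best_of(i + n)
    same <- e1$hit && e2$hit && identical(e1$seq, e2$seq)
    orient_ok <- FALSE
    ins_s <- ins_e <- span <- NA_real_
    if (same && !is.na(e1$strand) && !is.na(e2$strand) &&
        e1$strand != e2$strand) {
      plus <- if (e1$strand == "+") e1 else e2
      minus <- if (e1$strand == "+") e2 else e1
      orient_ok <- plus$start <= minus$start
      if (orient_ok) {
        ins_s <- plus$start
        ins_e <- minus$end
        span <- ins_e - ins_s
      }
    }
    data.frame(clone_id = lib$clone_id[i],
               e1_seq = e1$seq, e1_start = e1$start, e1_end = e1$end,
               e1_strand = e1$strand, e1_unique = e1$unique, e1_hit = e1$hit,
               e2_seq = e2$seq, e2_start = e2$start, e2_end = e2$end,
               e2_strand = e2$strand, e2_unique = e2$unique, e2_hit = e2$hit,
               same_seq = same, insert_start = ins_s, insert_end = ins_e,
               span = span, orientation_ok = orient_ok,
               usable = same && orient_ok && e1$unique && e2$unique,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map a single BAC clone onto an assembly
#' @param clone one-row data.frame with `clone_id, end1, end2`.
#' @param asm target `Assembly`.
#' @param ... passed to [map_bes_library()].
#' @return one-row placement data.frame (see [map_bes_library()]).
#' @export
map_bes <- function(clone, asm, ...) map_bes_library(clone, asm, ...)

#' Select BAC probes for a region
#'
#' Returns the clones passing all three selection criteria - both end
#' sequences unique, opposite inward orientation, insert span within
#' `[bes_span_min, bes_span_max]` - whose implied insert overlaps the
#' region by at least half the insert length, sorted by centrality of the
#' insert midpoint in the region. An empty result mirrors regions where
#' the end sequences give no or inconsistent hits.
#'
#' @param region an [interval()] on the assembly the placements refer to.
#' @param placements data.frame from [map_bes_library()].
#' @param th a [thresholds()] object.
#' @return subset of `placements`, best candidate first.
#' @export
select_probes_for_region <- function(region, placements, th = thresholds()) {
  p <- placements
  keep <- p$usable & !is.na(p$span) &
    p$span >= th$bes_span_min & p$span <= th$bes_span_max &
    p$e1_seq == region$seq_id
  p <- p[which(keep), , drop = FALSE]
  if (!nrow(p)) return(p)
  ov <- pmax(0, pmin(p$insert_end, region$end) - pmax(p$insert_start, region$start))
  p <- p[ov >= 0.5 * p$span, , drop = FALSE]
  if (!nrow(p)) return(p)
  mid <- (p$insert_start + p$insert_end) / 2
  p[order(abs(mid - (region$start + region$end) / 2)), , drop = FALSE]
}

#' Plan the three-probe FISH test of an inversion
#'
#' Needs three distinct non-overlapping BACs: one inside the inverted
#' segment and two outside, close to the opposite borders (within
#' `flank_max` of each breakpoint). The inside probe is chosen as
#' off-centre as possible (subject to `asym_min` of the inversion span)
#' because a centred probe yields the same interphase signal arrangement
#' under both hypotheses and cannot discriminate them.
#'
#' @param inv one row of a discordance table with `category == "INV"` and
#'   eligibility `"test-eligible"`.
#' @param placements data.frame from [map_bes_library()] on the A assembly.
#' @param th a [thresholds()] object.
#' @param flank_max maximal distance of a flanking probe from its
#'   breakpoint (bp).
#' @param asym_min minimal off-centre offset of the inside probe, as a
#'   fraction of the inversion span.
#' @param placements_other optional placements of the same library on the
#'   other assembly; when given, candidate probes must also map to the
#'   same chromosome there, so that a flank does not accidentally sit on
#'   sequence the two assemblies place on different chromosomes.
#' @return a `ProbePlan` list: `target`, `assay = "FISH-interphase"`,
#'   `feasible`, `probes` (role, clone_id, insert coordinates).
#' @export
plan_inversion_test <- function(inv, placements, th = thresholds(),
                                flank_max = 1e6, asym_min = 0.10,
                                placements_other = NULL) {
  if (inv$category != "INV")
    stop("plan_inversion_test needs an INV discordance")
  if (!identical(inv$eligibility, "test-eligible"))
    stop("inversion is not test-eligible (must exceed ",
         th$test_min_inv, " bp)")
  p <- placements[placements$usable & !is.na(placements$span) &
                  placements$span >= th$bes_span_min &
                  placements$span <= th$bes_span_max &
                  placements$e1_seq == inv$a_seq, , drop = FALSE]
  p <- p[p$clone_id %in% concordant_clones(p, placements_other, inv$a_seq), ,
         drop = FALSE]
  span <- inv$a_end - inv$a_start
  center <- (inv$a_start + inv$a_end) / 2
  inside <- p[p$insert_start >= inv$a_start & p$insert_end <= inv$a_end, ,
              drop = FALSE]
  if (nrow(inside)) {
    asym <- abs((inside$insert_start + inside$insert_end) / 2 - center)
    inside <- inside[asym >= asym_min * span, , drop = FALSE]
    asym <- asym[asym >= asym_min * span]
    inside <- inside[order(-asym), , drop = FALSE]
  }
  left <- p[p$insert_end <= inv$a_start &
            p$insert_start >= inv$a_start - flank_max, , drop = FALSE]
  left <- left[order(-left$insert_end), , drop = FALSE]
  right <- p[p$insert_start >= inv$a_end &
             p$insert_end <= inv$a_end + flank_max, , drop = FALSE]
  right <- right[order(right$insert_start), , drop = FALSE]
  feasible <- nrow(inside) > 0 && nrow(left) > 0 && nrow(right) > 0
  probes <- if (feasible)
    data.frame(role = c("flank-left", "inside", "flank-right"),
               clone_id = c(left$clone_id[1], inside$clone_id[1],
                            right$clone_id[1]),
               seq_id = inv$a_seq,
               insert_start = c(left$insert_start[1], inside$insert_start[1],
                                right$insert_start[1]),
               insert_end = c(left$insert_end[1], inside$insert_end[1],
                              right$insert_end[1]),
               stringsAsFactors = FALSE)
  else
    data.frame(role = character(0), clone_id = character(0),
               seq_id = character(0), insert_start = numeric(0),
               insert_end = numeric(0), stringsAsFactors = FALSE)
  structure(list(target = inv$code, assay = "FISH-interphase",
                 feasible = feasible, probes = probes), class = "ProbePlan")
}

#' Plan the single-probe metaphase FISH test of a DCM
#'
#' Picks the clone whose implied insert best overlaps the defining (A-side
#' when present) locus. Uniqueness is not required: a clone inside a
#' duplicated segment legitimately maps twice in one assembly, and that
#' multiplicity is exactly the hypothesis difference the metaphase assay
#' reads out.
#'
#' @param dcm one DCM row of a discordance table.
#' @param placements placements on the assembly owning the defining locus.
#' @param th a [thresholds()] object.
#' @return a `ProbePlan` with assay `"FISH-metaphase"`.
#' @export
plan_dcm_test <- function(dcm, placements, th = thresholds()) {
  if (dcm$category != "DCM") stop("plan_dcm_test needs a DCM discordance")
  # probe from the side NOT carrying the duplicate: there the segment is
  # single-copy, so clone placements are unique and lie in the locus frame
  use_b <- identical(dcm$dup_in, "A") || is.na(dcm$a_seq)
  locus_seq <- if (use_b) dcm$b_seq else dcm$a_seq
  locus <- if (use_b) c(dcm$b_start, dcm$b_end)
           else c(dcm$a_start, dcm$a_end)
  p <- placements[placements$same_seq & placements$orientation_ok &
                  !is.na(placements$span) &
                  placements$span >= th$bes_span_min &
                  placements$span <= th$bes_span_max &
                  placements$e1_seq == locus_seq, , drop = FALSE]
  if (nrow(p)) {
    ov <- pmax(0, pmin(p$insert_end, locus[2]) - pmax(p$insert_start, locus[1]))
    p <- p[ov >= 0.5 * p$span, , drop = FALSE]
  }
  feasible <- nrow(p) > 0
  if (feasible) {
    mid <- (p$insert_start + p$insert_end) / 2
    p <- p[order(abs(mid - mean(locus))), , drop = FALSE]
  }
  probes <- if (feasible)
    data.frame(role = "inside", clone_id = p$clone_id[1], seq_id = locus_seq,
               insert_start = p$insert_start[1], insert_end = p$insert_end[1],
               stringsAsFactors = FALSE)
  else
    data.frame(role = character(0), clone_id = character(0),
               seq_id = character(0), insert_start = numeric(0),
               insert_end = numeric(0), stringsAsFactors = FALSE)
  structure(list(target = dcm$code, assay = "FISH-metaphase",
                 feasible = feasible, probes = probes), class = "ProbePlan")
}

#' Assemble the chromosome-specific reference panel
#'
#' One clone per chromosome, mapping wholly inside a same-orientation block
#' whose raw coordinates agree between the assemblies by at least
#' `min_agree` reciprocal overlap (a highly concordant region), with both
#' ends unique. Chromosomes without a qualifying clone are reported
#' missing.
#'
#' @param blocks block data.frame over all chromosome pairs.
#' @param placements placements on assembly A.
#' @param asm_a assembly A (for the chromosome list).
#' @param th a [thresholds()] object.
#' @param min_agree reciprocal position-agreement cutoff (0.99).
#' @return data.frame `chrom, clone_id, insert_start, insert_end, found`.
#' @export
build_reference_panel <- function(blocks, placements, asm_a,
                                  th = thresholds(), min_agree = 0.99) {
  out <- NULL
  for (ch in chromosomes(asm_a)) {
    bl <- blocks[blocks$a_seq == ch & blocks$orientation == "same", ,
                 drop = FALSE]
    found <- FALSE; clone <- NA_character_; is_ <- ie_ <- NA_real_
    if (nrow(bl)) {
      ov <- pmax(0, pmin(bl$a_end, bl$b_end) - pmax(bl$a_start, bl$b_start))
      recip <- pmin(ov / (bl$a_end - bl$a_start), ov / (bl$b_end - bl$b_start))
      bl <- bl[recip >= min_agree, , drop = FALSE]
      bl <- bl[order(-(bl$a_end - bl$a_start)), , drop = FALSE]
      for (i in seq_len(nrow(bl))) {
        p <- placements[placements$usable & !is.na(placements$span) &
                        placements$span >= th$bes_span_min &
                        placements$span <= th$bes_span_max &
                        placements$e1_seq == ch &
                        placements$insert_start >= bl$a_start[i] &
                        placements$insert_end <= bl$a_end[i], , drop = FALSE]
        if (nrow(p)) {
          mid <- (p$insert_start + p$insert_end) / 2
          p <- p[order(abs(mid - (bl$a_start[i] + bl$a_end[i]) / 2)), ,
                 drop = FALSE]
          found <- TRUE
          clone <- p$clone_id[1]; is_ <- p$insert_start[1]; ie_ <- p$insert_end[1]
          break
        }
      }
    }
    out <- rbind(out, data.frame(chrom = ch, clone_id = clone,
                                 insert_start = is_, insert_end = ie_,
                                 found = found, stringsAsFactors = FALSE))
  }
  out
}

# ---------------------------------------------------------------------------
# Junction long-PCR
# ---------------------------------------------------------------------------

# clones also mapping (both ends, one molecule, inward) to seq_id in the
# other assembly; NULL placements_other disables the filter
concordant_clones <- function(placements, placements_other, seq_id) {
  if (is.null(placements_other)) return(placements$clone_id)
  ok <- placements_other$clone_id[placements_other$same_seq &
                                  placements_other$orientation_ok &
                                  !is.na(placements_other$e1_seq) &
                                  placements_other$e1_seq == seq_id]
  intersect(placements$clone_id, ok)
}

# exact occurrence count of a short sequence in an assembly (both strands)
count_occurrences <- function(asm, pattern) {
  nrow(cpp_find_exact(unname(asm$seq), pattern))
}

#' Design junction PCR assays for an MDP discordance
#'
#' For each assembly hypothesis, a primer pair flanking the predicted left
#' junction of the discordant segment in that assembly: the forward primer
#' `flank` bp upstream of the junction, the reverse primer `flank` bp
#' downstream (on the minus strand), both 25 bp and required to be unique
#' in their assembly (slid outward in 500 bp steps when not). The
#' predicted amplicon, `2*(flank + 25)` bp, must not exceed
#' `th$pcr_amplicon_max`.
#'
#' @param mdp one MDP row of a discordance table.
#' @param asm_a,asm_b the two assemblies.
#' @param th a [thresholds()] object.
#' @param flank primer distance from the junction (bp).
#' @param primer_len primer length (bp, fixed 25 by the site model).
#' @return data.frame of class `PCRAssay`, one row per hypothesis:
#'   `target, hypothesis, fwd, rev, seq_id, fwd_start, rev_end,
#'   predicted_amplicon, feasible`.
#' @export
design_junction_pcr <- function(mdp, asm_a, asm_b, th = thresholds(),
                                flank = 2000, primer_len = 25) {
  if (mdp$category != "MDP") stop("design_junction_pcr needs an MDP")
  amplicon <- 2 * (flank + primer_len)
  rows <- NULL
  for (hyp in c("A", "B")) {
    asm <- if (hyp == "A") asm_a else asm_b
    seq_id <- if (hyp == "A") mdp$a_seq else mdp$b_seq
    j <- if (hyp == "A") mdp$a_start else mdp$b_start
    s <- asm$seq[[seq_id]]
    feasible <- FALSE
    fwd <- rev_ <- NA_character_; fs <- re <- NA_real_
    if (amplicon <= th$pcr_amplicon_max) {
      for (slide in seq(0, 5000, by = 500)) {
        fs_try <- j - flank - primer_len - slide
        re_try <- j + flank + primer_len + slide
        if (fs_try < 0 || re_try > nchar(s)) break
        f <- substr(s, fs_try + 1, fs_try + primer_len)
        rsite <- substr(s, re_try - primer_len + 1, re_try)
        if (grepl("[nN]", f) || grepl("[nN]", rsite)) next
        if (count_occurrences(asm, f) == 1 &&
            count_occurrences(asm, rsite) == 1) {
          feasible <- TRUE
          fwd <- toupper(f)
          rev_ <- toupper(reverse_complement(rsite))
          fs <- fs_try; re <- re_try
          break
        }
      }
    }
    rows <- rbind(rows, data.frame(
      target = mdp$code, hypothesis = hyp, fwd = fwd, rev = rev_,
      seq_id = seq_id, fwd_start = fs, rev_end = re,
      predicted_amplicon = if (feasible) re - fs else amplicon,
      feasible = feasible, stringsAsFactors = FALSE))
  }
  class(rows) <- c("PCRAssay", "data.frame")
  rows
}

#' Run a PCR assay in silico on a genome
#'
#' The assay amplifies when the forward primer and the reverse-primer
#' annealing site both occur on the same molecule, facing inward, with the
#' product not exceeding `max_amplicon`.
#'
#' @param assay one row of a `PCRAssay`.
#' @param genome the `Assembly` amplified from (typically the true genome).
#' @param max_amplicon product-size ceiling in bp.
#' @return logical: does the assay produce a product?
#' @export
in_silico_pcr <- function(assay, genome, max_amplicon = 12000) {
  if (!isTRUE(assay$feasible)) return(FALSE)
  m <- nchar(assay$fwd)
  fhits <- cpp_find_exact(unname(genome$seq), assay$fwd)
  rhits <- cpp_find_exact(unname(genome$seq), assay$rev)
  if (!nrow(fhits) || !nrow(rhits)) return(FALSE)
  for (i in seq_len(nrow(fhits))) for (j in seq_len(nrow(rhits))) {
    if (fhits$subject[i] != rhits$subject[j]) next
    f <- fhits[i, ]; r <- rhits[j, ]
    # plus-strand product: fwd anneals "+", rev anneals minus (its reverse
    # complement occurs on "+", reported as strand "-")
    if (f$strand == "+" && r$strand == "-" && f$start < r$start + m &&
        (r$start + m) - f$start <= max_amplicon) return(TRUE)
    # minus-strand product (the same pair read from the other strand)
    if (f$strand == "-" && r$strand == "+" && r$start < f$start + m &&
        (f$start + m) - r$start <= max_amplicon) return(TRUE)
  }
  FALSE
}

#' Decide an MDP by junction PCR against the true genome
#'
#' @param assays a `PCRAssay` (both hypotheses) from
#'   [design_junction_pcr()].
#' @param truth the true genome `Assembly`.
#' @param th a [thresholds()] object.
#' @return a `Verdict` list (see [decide()]); `support_fraction` is 1 for
#'   a clean single-hypothesis product, and the verdict is `"neither"`
#'   when every primer combination is negative (the signature of both
#'   assemblies being wrong at the junction).
#' @export
pcr_verdict <- function(assays, truth, th = thresholds()) {
  pos <- vapply(seq_len(nrow(assays)), function(i)
    in_silico_pcr(assays[i, ], truth, th$pcr_amplicon_max), logical(1))
  names(pos) <- assays$hypothesis
  supported <- if (all(pos)) "both-consistent"
  else if (pos[["A"]]) "hypothesis-A"
  else if (pos[["B"]]) "hypothesis-B"
  else "neither"
  structure(list(supported = supported,
                 support_fraction = if (any(pos)) 1 else 0,
                 n_cells = NA_integer_, modality = "PCR"),
            class = "Verdict")
}

#' Write probe plans as TSV
#' @param plans list of `ProbePlan`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_probes <- function(plans, path) {
  rows <- do.call(rbind, lapply(plans, function(pl) {
    if (!pl$feasible)
      return(data.frame(target = pl$target, assay = pl$assay, role = "none",
                        clone_id = NA, seq_id = NA, insert_start = NA,
                        insert_end = NA, feasible = FALSE,
                        stringsAsFactors = FALSE))
    cbind(target = pl$target, assay = pl$assay,
          pl$probes[, c("role", "clone_id", "seq_id", "insert_start",
                        "insert_end")],
          feasible = TRUE)
  }))
  if (is.null(rows))
    rows <- data.frame(target = character(0), assay = character(0))
  write_tsv(to_report_coords(rows, start_cols = intersect("insert_start",
                                                          names(rows))), path)
}
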