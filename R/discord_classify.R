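# Classification of synteny-block layouts into the discordance taxonomy:
#   INV - same position, discordant orientation
#   MDP - mapped in distinct positions along the same chromosome
#   ODS - present in one draft's chromosome, absent from the other's
#   DCM - paired ODSs lying on different chromosomes
# Reporting floor and test-eligibility are strict ("larger than"): a
# discordance of exactly 100 kbp stays sub-threshold.

discord_cols <- function() {
  data.frame(code = character(0), category = character(0),
             a_seq = character(0), a_start = numeric(0), a_end = numeric(0),
             b_seq = character(0), b_start = numeric(0), b_end = numeric(0),
             size = numeric(0), source = character(0),
             eligibility = character(0), gap_repeat_flag = logical(0),
             dcm_partner = character(0), dup_in = character(0),
             displacement = numeric(0), stringsAsFactors = FALSE)
}

new_discord <- function(category, a_seq = NA, a_start = NA, a_end = NA,
                        b_seq = NA, b_start = NA, b_end = NA, size,
                        source = NA_character_, displacement = NA_real_) {
  data.frame(code = NA_character_, category = category,
             a_seq = a_seq, a_start = a_start, a_end = a_end,
             b_seq = b_seq, b_start = b_start, b_end = b_end,
             size = size, source = source, eligibility = NA_character_,
             gap_repeat_flag = FALSE, dcm_partner = NA_character_,
             dup_in = NA_character_, displacement = displacement,
             stringsAsFactors = FALSE)
}

#' Eligibility tier of a discordance size
#'
#' Strict thresholds, as the reporting rules are phrased "larger than":
#' sizes above `report_min` (100 kbp) are reportable; sizes above the
#' category's testing floor - 500 kbp for INV, 200 kbp for MDP/ODS/DCM -
#' are test-eligible; a size exactly at a threshold stays in the lower
#' tier.
#'
#' @param category `"INV"`, `"MDP"`, `"ODS"` or `"DCM"`.
#' @param size discordance size in bp.
#' @param th a [thresholds()] object.
#' @return `"sub-threshold"`, `"reportable"` or `"test-eligible"`.
#' @export
eligibility_of <- function(category, size, th = thresholds()) {
  test_min <- if (category == "INV") th$test_min_inv else th$test_min_mdp_dcm
  if (size > test_min) "test-eligible"
  else if (size > th$report_min) "reportable"
  else "sub-threshold"
}

# maximal uncovered regions of [0, len) given covered spans
uncovered_regions <- function(starts, ends, len) {
  if (length(starts) == 0)
    return(data.frame(start = 0, end = len))
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  ms <- starts[1]; me <- ends[1]
  merged <- NULL
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { merged <- rbind(merged, c(ms, me)); ms <- starts[i]; me <- ends[i] }
  }
  merged <- rbind(merged, c(ms, me))
  gaps <- data.frame(start = c(0, merged[, 2]), end = c(merged[, 1], len))
  gaps[gaps$end > gaps$start, , drop = FALSE]
}

# anchor_bp-weighted longest increasing subsequence of b_start over blocks
# sorted by a_start: the dominant colinear backbone of a chromosome pair.
# Returns logical vector: block belongs to the backbone.
colinear_backbone <- function(bl) {
  n <- nrow(bl)
  if (n == 0) return(logical(0))
  ord <- order(bl$a_start, bl$b_start)
  bs <- bl$b_start[ord]
  w <- bl$anchor_bp[ord]
  best <- w
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (bs[j] <= bs[i] && best[j] + w[i] > best[i]) {
        best[i] <- best[j] + w[i]
        prev[i] <- j
      }
    }
  }
  in_lis <- logical(n)
  i <- which.max(best)
  while (!is.na(i)) { in_lis[i] <- TRUE; i <- prev[i] }
  out <- logical(n)
  out[ord] <- in_lis
  out
}

# diagonal offset (b_start - a_start) of the nearest backbone block at or
# before a_pos (falling back to the next one, then to 0)
local_offset <- function(backbone_bl, a_pos) {
  if (nrow(backbone_bl) == 0) return(0)
  before <- backbone_bl[backbone_bl$a_start <= a_pos, , drop = FALSE]
  if (nrow(before)) {
    b <- before[which.max(before$a_start), ]
  } else {
    b <- backbone_bl[which.min(backbone_bl$a_start), ]
  }
  b$b_start - b$a_start
}

#' Classify synteny blocks of homologous chromosome pairs into discordances
#'
#' For each like-named chromosome pair, the dominant colinear order is
#' first established as the anchor-bp-weighted longest increasing
#' subsequence (by B-position, over blocks sorted by A-position) of the
#' same-orientation blocks - the backbone. Indels (one-draft-only
#' sequence) shift every downstream block of one assembly without
#' breaking the backbone order, so they never masquerade as position
#' discordances. Then:
#' * an inverted-orientation block whose A-span and B-span (projected into
#'   the A frame through the nearest backbone diagonal) reciprocally
#'   overlap by at least `inv_recip` is an INV; an inverted block failing
#'   the overlap test is treated as position-discordant (MDP);
#' * a same-orientation block outside the backbone whose centre is
#'   displaced from the locally predicted colinear position by more than
#'   the block's own length is an MDP;
#' * a maximal region of either chromosome covered by no block is an ODS
#'   of that assembly (regions shorter than `ods_emit_min` are ignored as
#'   chaining noise).
#'
#' Sizes are measured on the A span for INV/MDP and on the source locus for
#' ODS. Eligibility is strict: reportable above 100 kbp, test-eligible
#' above 200 kbp (MDP/ODS/DCM) or 500 kbp (INV).
#'
#' @param blocks block data.frame from [chain_anchors()], possibly row-bound
#'   over several chromosome pairs; every row must have `a_seq == b_seq`.
#' @param asm_a,asm_b the two assemblies.
#' @param th a [thresholds()] object.
#' @param inv_recip reciprocal projected-overlap cutoff for INV (0.8).
#' @param ods_emit_min smallest uncovered region emitted as an ODS
#'   candidate (bp).
#' @return a discordance data.frame (codes assigned run-wide, see
#'   [assign_codes()]).
#' @export
classify_discordances <- function(blocks, asm_a, asm_b, th = thresholds(),
                                  inv_recip = 0.8, ods_emit_min = 10000) {
  if (nrow(blocks) && any(blocks$a_seq != blocks$b_seq))
    stop("blocks from mismatched chromosome pairs: ",
         paste(unique(blocks$a_seq[blocks$a_seq != blocks$b_seq]),
               collapse = ", "))
  pairs <- intersect(chromosomes(asm_a), chromosomes(asm_b))
  len_a <- seq_lengths(asm_a)
  len_b <- seq_lengths(asm_b)
  out <- discord_cols()
  for (ch in pairs) {
    bl <- blocks[blocks$a_seq == ch, , drop = FALSE]
    same <- bl[bl$orientation == "same", , drop = FALSE]
    backbone <- same[colinear_backbone(same), , drop = FALSE]
    in_backbone <- bl$block_id %in% backbone$block_id
    for (i in seq_len(nrow(bl))) {
      b <- bl[i, ]
      size <- b$a_end - b$a_start
      off <- local_offset(backbone, b$a_start)
      if (b$orientation == "inverted") {
        proj <- c(b$b_start - off, b$b_end - off)
        ov <- max(0, min(b$a_end, proj[2]) - max(b$a_start, proj[1]))
        recip <- min(ov / (b$a_end - b$a_start), ov / (proj[2] - proj[1]))
        cat_i <- if (recip >= inv_recip) "INV" else "MDP"
        disp_i <- if (cat_i == "MDP")
          abs((b$b_start + b$b_end) / 2 - ((b$a_start + b$a_end) / 2 + off))
        else NA_real_
        out <- rbind(out, new_discord(cat_i, ch, b$a_start, b$a_end,
                                      ch, b$b_start, b$b_end, size,
                                      displacement = disp_i))
      } else if (!in_backbone[i]) {
        pred_center <- (b$a_start + b$a_end) / 2 + off
        disp <- abs((b$b_start + b$b_end) / 2 - pred_center)
        if (disp > (b$a_end - b$a_start))
          out <- rbind(out, new_discord("MDP", ch, b$a_start, b$a_end,
                                        ch, b$b_start, b$b_end, size,
                                        displacement = disp))
      }
    }
    gaps_a <- uncovered_regions(bl$a_start, bl$a_end, len_a[[ch]])
    gaps_a <- gaps_a[gaps_a$end - gaps_a$start >= ods_emit_min, , drop = FALSE]
    for (i in seq_len(nrow(gaps_a)))
      out <- rbind(out, new_discord("ODS", ch, gaps_a$start[i], gaps_a$end[i],
                                    size = gaps_a$end[i] - gaps_a$start[i],
                                    source = "A"))
    gaps_b <- uncovered_regions(bl$b_start, bl$b_end, len_b[[ch]])
    gaps_b <- gaps_b[gaps_b$end - gaps_b$start >= ods_emit_min, , drop = FALSE]
    for (i in seq_len(nrow(gaps_b)))
      out <- rbind(out, new_discord("ODS", b_seq = ch, b_start = gaps_b$start[i],
                                    b_end = gaps_b$end[i],
                                    size = gaps_b$end[i] - gaps_b$start[i],
                                    source = "B"))
  }
  if (nrow(out)) {
    out$eligibility <- vapply(seq_len(nrow(out)), function(i)
      eligibility_of(out$category[i], out$size[i], th), character(1))
    out <- assign_codes(out)
  }
  rownames(out) <- NULL
  out
}

# union coverage (bp) of [s, e) by intervals
covered_bp <- function(s, e, starts, ends) {
  starts <- pmax(starts, s); ends <- pmin(ends, e)
  keep <- ends > starts
  if (!any(keep)) return(0)
  starts <- starts[keep] - s; ends <- ends[keep] - s
  unc <- uncovered_regions(starts, ends, e - s)
  (e - s) - sum(unc$end - unc$start)
}

#' Pair one-draft-only sequences across assemblies into DCMs
#'
#' An ODS of assembly A and an ODS of assembly B that match each other
#' (reciprocal anchor coverage >= `min_recip`) while lying on different
#' chromosome names form a Discordant Chromosome Mapping pair (DCM). An ODS
#' whose sequence maps (>= `min_recip` of it) to a different chromosome of
#' the other assembly at a locus that is *not* an ODS is emitted as a
#' one-sided DCM: the segment is present twice in the ODS's own assembly
#' and once in the other, so it is flagged duplicated in the ODS's
#' assembly.
#'
#' @param discord discordance data.frame containing the ODS rows.
#' @param asm_a,asm_b the two assemblies.
#' @param th a [thresholds()] object.
#' @param min_anchor anchor length for the cross-assembly matching.
#' @param min_recip reciprocal-coverage cutoff (0.5).
#' @return the input data.frame with DCM rows appended and `dcm_partner`
#'   filled in on the member ODSs.
#' @export
pair_odss <- function(discord, asm_a, asm_b, th = thresholds(),
                      min_anchor = 50, min_recip = 0.5) {
  ods <- which(discord$category == "ODS" &
               discord$eligibility != "sub-threshold")
  if (!length(ods)) return(discord)
  # cross-match every ODS sequence against the other assembly's chromosomes
  match_ods <- function(i) {
    d <- discord[i, ]
    if (d$source == "A") {
      seqv <- substr(asm_a$seq[[d$a_seq]], d$a_start + 1, d$a_end)
      tasm <- asm_b
    } else {
      seqv <- substr(asm_b$seq[[d$b_seq]], d$b_start + 1, d$b_end)
      tasm <- asm_a
    }
    anchor_scan(seqv, tasm$seq[chromosomes(tasm)], min_anchor, q_id = "ods")
  }
  hits <- lapply(ods, match_ods)
  names(hits) <- as.character(ods)

  dcm_new <- discord_cols()
  paired <- rep(NA_character_, nrow(discord))
  ods_a <- ods[discord$source[ods] == "A"]
  ods_b <- ods[discord$source[ods] == "B"]

  locus_of <- function(i) {
    d <- discord[i, ]
    if (d$source == "A") c(d$a_seq, d$a_start, d$a_end)
    else c(d$b_seq, d$b_start, d$b_end)
  }

  add_dcm <- function(ia, ib, a_locus, b_locus, dup_in = NA_character_) {
    size <- max(as.numeric(a_locus[3]) - as.numeric(a_locus[2]),
                as.numeric(b_locus[3]) - as.numeric(b_locus[2]))
    row <- new_discord("DCM", a_locus[1], as.numeric(a_locus[2]),
                       as.numeric(a_locus[3]), b_locus[1],
                       as.numeric(b_locus[2]), as.numeric(b_locus[3]), size)
    row$dup_in <- dup_in
    row$eligibility <- eligibility_of("DCM", size, th)
    attr(row, "members") <- c(ia, ib)
    row
  }

  done <- logical(nrow(discord))
  rows <- list()
  for (ia in ods_a) {
    ha <- hits[[as.character(ia)]]
    if (is.null(ha) || !nrow(ha)) next
    la <- locus_of(ia)
    len_a_ods <- as.numeric(la[3]) - as.numeric(la[2])
    matched <- FALSE
    for (ib in ods_b) {
      lb <- locus_of(ib)
      if (lb[1] == la[1]) next  # DCM loci must be on different chromosomes
      sub <- ha[ha$b_seq == lb[1] &
                ha$b_end > as.numeric(lb[2]) &
                ha$b_start < as.numeric(lb[3]), , drop = FALSE]
      if (!nrow(sub)) next
      cov_a <- covered_bp(0, len_a_ods, sub$a_start, sub$a_end) / len_a_ods
      len_b_ods <- as.numeric(lb[3]) - as.numeric(lb[2])
      cov_b <- covered_bp(as.numeric(lb[2]), as.numeric(lb[3]),
                          sub$b_start, sub$b_end) / len_b_ods
      if (cov_a >= min_recip && cov_b >= min_recip) {
        rows[[length(rows) + 1]] <- add_dcm(ia, ib, la, lb)
        done[ia] <- done[ib] <- TRUE
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      # one-sided: substantial match on a different chromosome, no ODS there
      bychrom <- split(seq_len(nrow(ha)), ha$b_seq)
      for (tg in names(bychrom)) {
        if (tg == la[1]) next
        sub <- ha[bychrom[[tg]], , drop = FALSE]
        cov_a <- covered_bp(0, len_a_ods, sub$a_start, sub$a_end) / len_a_ods
        if (cov_a >= min_recip) {
          hull <- c(tg, min(sub$b_start), max(sub$b_end))
          rows[[length(rows) + 1]] <- add_dcm(ia, NA, la, hull, dup_in = "A")
          done[ia] <- TRUE
          break
        }
      }
    }
  }
  for (ib in ods_b) {
    if (done[ib]) next
    hb <- hits[[as.character(ib)]]
    if (is.null(hb) || !nrow(hb)) next
    lb <- locus_of(ib)
    len_b_ods <- as.numeric(lb[3]) - as.numeric(lb[2])
    bychrom <- split(seq_len(nrow(hb)), hb$b_seq)
    for (tg in names(bychrom)) {
      if (tg == lb[1]) next
      sub <- hb[bychrom[[tg]], , drop = FALSE]
      cov_b <- covered_bp(0, len_b_ods, sub$a_start, sub$a_end) / len_b_ods
      if (cov_b >= min_recip) {
        hull <- c(tg, min(sub$b_start), max(sub$b_end))
        rows[[length(rows) + 1]] <- add_dcm(NA, ib, hull, lb, dup_in = "B")
        done[ib] <- TRUE
        break
      }
    }
  }
  if (length(rows)) {
    for (row in rows) {
      members <- attr(row, "members")
      code <- dcm_code(row$a_seq, row$b_seq,
                       existing = c(discord$code, dcm_new$code))
      row$code <- code
      for (m in members[!is.na(members)]) discord$dcm_partner[m] <- code
      row$dcm_partner <- paste(discord$code[members[!is.na(members)]],
                               collapse = ";")
      dcm_new <- rbind(dcm_new, row)
    }
    discord <- rbind(discord, dcm_new)
    rownames(discord) <- NULL
  }
  discord
}

#' Exclude discordances that are almost completely gaps and/or repeats
#'
#' The locus that defines the discordance (the source locus of an ODS; the
#' A locus otherwise, falling back to B when the A side is absent) is
#' excluded when its masked fraction strictly exceeds
#' `th$masked_frac_max`. Excluded discordances are retained with
#' `gap_repeat_flag = TRUE` so they can still be listed.
#'
#' @param discord discordance data.frame.
#' @param asm_a,asm_b the two assemblies.
#' @param th a [thresholds()] object.
#' @return list with elements `kept` and `excluded`.
#' @export
filter_gap_repeat <- function(discord, asm_a, asm_b, th = thresholds()) {
  if (!nrow(discord))
    return(list(kept = discord, excluded = discord))
  frac <- vapply(seq_len(nrow(discord)), function(i) {
    d <- discord[i, ]
    use_a <- if (d$category == "ODS") identical(d$source, "A") else !is.na(d$a_seq)
    if (use_a)
      masked_fraction(interval(d$a_seq, d$a_start, d$a_end), asm_a)
    else
      masked_fraction(interval(d$b_seq, d$b_start, d$b_end), asm_b)
  }, numeric(1))
  excl <- frac > th$masked_frac_max
  discord$gap_repeat_flag <- excl
  list(kept = discord[!excl, , drop = FALSE],
       excluded = discord[excl, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Codes
# ---------------------------------------------------------------------------

chrom_label <- function(seq_id) sub("^chr", "", seq_id)

format_mbp <- function(pos) {
  s <- sprintf("%.1f", pos / 1e6)
  sub("\\.0$", "", s)
}

dcm_code <- function(a_seq, b_seq, existing = character(0)) {
  base <- sprintf("DCM_%s-%s", chrom_label(a_seq), chrom_label(b_seq))
  uniquify_code(base, existing)
}

uniquify_code <- function(base, existing) {
  if (!base %in% existing) return(base)
  k <- 2
  while (sprintf("%s.%d", base, k) %in% existing) k <- k + 1
  sprintf("%s.%d", base, k)
}

#' Code string for a single discordance
#'
#' INV/MDP/ODS codes are `<CAT>_<chrom>_<pos>` with the position the locus
#' start in Mbp to one decimal (a trailing `.0` is dropped, so a start at
#' 24.0 Mbp prints as `24`); DCM codes are `DCM_<chromA>-<chromB>`.
#'
#' @param category `"INV"`, `"MDP"`, `"ODS"` or `"DCM"`.
#' @param seq_id chromosome id of the defining locus (A side for DCM).
#' @param start 0-based locus start in bp.
#' @param b_seq_id B-side chromosome id (DCM only).
#' @param existing codes already assigned in this run (for `.2`, `.3`
#'   collision suffixes).
#' @return the code string.
#' @export
assign_code <- function(category, seq_id, start, b_seq_id = NULL,
                        existing = character(0)) {
  if (is.na(seq_id)) stop("cannot code a discordance with an absent locus")
  if (category == "DCM") {
    if (is.null(b_seq_id)) stop("DCM code needs both chromosomes")
    return(dcm_code(seq_id, b_seq_id, existing))
  }
  uniquify_code(sprintf("%s_%s_%s", category, chrom_label(seq_id),
                        format_mbp(start)), existing)
}

#' Assign codes to every row of a discordance table
#' @param discord discordance data.frame.
#' @return the data.frame with unique `code`s filled in.
#' @export
assign_codes <- function(discord) {
  codes <- character(0)
  for (i in seq_len(nrow(discord))) {
    d <- discord[i, ]
    use_a <- if (d$category == "ODS") identical(d$source, "B") == FALSE
             else !is.na(d$a_seq)
    code <- if (d$category == "DCM")
      assign_code("DCM", d$a_seq, d$a_start, d$b_seq, existing = codes)
    else if (use_a && !is.na(d$a_seq))
      assign_code(d$category, d$a_seq, d$a_start, existing = codes)
    else
      assign_code(d$category, d$b_seq, d$b_start, existing = codes)
    codes <- c(codes, code)
    discord$code[i] <- code
  }
  discord
}

#' Write a discordance table as TSV (1-based inclusive coordinates)
#' @param discord discordance data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_discordances <- function(discord, path) {
  write_tsv(to_report_coords(discord,
                             start_cols = c("a_start", "b_start")), path)
}
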