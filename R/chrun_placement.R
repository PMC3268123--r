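# Placement of unassigned scaffolds (and ODS sequences) onto the other
# assembly's chromosomes, with Table-2-style verdicts.

#' Place a scaffold onto a target assembly
#'
#' The scaffold is anchored against every sequence of the target and the
#' anchors are chained into blocks; each block becomes a placement (target
#' interval, scaffold sub-interval, coverage fraction). The verdict is:
#' * `single-locus` - one chained block covers >= `min_cov` of the scaffold;
#' * `split-multi-chromosome` - at least two chromosomes each receive a
#'   distinct scaffold sub-interval longer than the reporting floor;
#' * `multi-site-dispersed` - some scaffold sub-interval matches three or
#'   more distinct target loci (the signature of a low-copy repeat or a
#'   collapsed duplication);
#' * `unplaced` - total scaffold coverage below `unplaced_max`;
#' * otherwise the verdict falls back to `split-multi-chromosome` when two
#'   or more chromosomes are hit, else `single-locus` (partial placement).
#'
#' Placements on the target's own unassigned scaffolds are reported but
#' never contribute to a chromosome verdict.
#'
#' @param scaffold_seq scaffold nucleotide string.
#' @param target target `Assembly`.
#' @param min_anchor anchor length (bp).
#' @param min_cov single-locus coverage cutoff (0.90).
#' @param unplaced_max unplaced coverage ceiling (0.10).
#' @param th a [thresholds()] object (reporting floor for the split rule).
#' @param max_gap,max_drift chaining parameters.
#' @param scaffold_id id recorded in the report.
#' @return list of class `PlacementReport`: `scaffold_id`, `verdict`,
#'   `placements` (data.frame: target_seq, target_start, target_end,
#'   scaffold_start, scaffold_end, coverage, target_role),
#'   `residual_unplaced_bp`, `collapse_flag` (placement count on
#'   chromosomes < distinct matched loci would suggest; set by
#'   [crosslink_ods_chrun()] users when truth is known).
#' @export
place_scaffold <- function(scaffold_seq, target, min_anchor = 50,
                           min_cov = 0.90, unplaced_max = 0.10,
                           th = thresholds(), max_gap = 50000,
                           max_drift = 20000, scaffold_id = "scaffold") {
  if (!inherits(target, "Assembly") || length(target$seq) == 0)
    stop("empty target assembly")
  slen <- nchar(scaffold_seq)
  if (slen < min_anchor) stop("scaffold shorter than min_anchor")
  placements <- NULL
  all_an <- anchor_scan(scaffold_seq, target$seq, min_anchor,
                        q_id = "scaffold")
  for (tg in unique(all_an$b_seq)) {
    an <- all_an[all_an$b_seq == tg, , drop = FALSE]
    bl <- chain_anchors(an, max_gap, max_drift)
    for (i in seq_len(nrow(bl))) {
      b <- bl[i, ]
      placements <- rbind(placements, data.frame(
        target_seq = tg, target_start = b$b_start, target_end = b$b_end,
        scaffold_start = b$a_start, scaffold_end = b$a_end,
        coverage = (b$a_end - b$a_start) / slen,
        target_role = unname(target$role[tg]), stringsAsFactors = FALSE))
    }
  }
  if (is.null(placements))
    placements <- data.frame(target_seq = character(0),
                             target_start = numeric(0), target_end = numeric(0),
                             scaffold_start = numeric(0),
                             scaffold_end = numeric(0), coverage = numeric(0),
                             target_role = character(0),
                             stringsAsFactors = FALSE)
  chrom_pl <- placements[placements$target_role == "chromosome", , drop = FALSE]
  covered <- if (nrow(chrom_pl))
    slen - sum(uncovered_regions(chrom_pl$scaffold_start,
                                 chrom_pl$scaffold_end, slen)$end -
               uncovered_regions(chrom_pl$scaffold_start,
                                 chrom_pl$scaffold_end, slen)$start)
  else 0
  total_cov <- covered / slen

  # multi-site: a scaffold sub-interval matched by >= 3 distinct loci
  multi_site <- FALSE
  if (nrow(chrom_pl) >= 3) {
    for (i in seq_len(nrow(chrom_pl))) {
      hits <- sum(chrom_pl$scaffold_start < chrom_pl$scaffold_end[i] &
                  chrom_pl$scaffold_end > chrom_pl$scaffold_start[i])
      if (hits >= 3) { multi_site <- TRUE; break }
    }
  }
  # split: >= 2 chromosomes each owning a distinct sub-interval > floor
  by_chrom <- split(chrom_pl, chrom_pl$target_seq)
  big <- vapply(by_chrom, function(p)
    max(p$scaffold_end - p$scaffold_start) >= th$report_min, logical(1))
  split_multi <- sum(big) >= 2

  verdict <-
    if (nrow(chrom_pl) && max(chrom_pl$coverage) >= min_cov) "single-locus"
    else if (multi_site) "multi-site-dispersed"
    else if (split_multi) "split-multi-chromosome"
    else if (total_cov < unplaced_max) "unplaced"
    else if (length(by_chrom) >= 2) "split-multi-chromosome"
    else "single-locus"

  structure(list(scaffold_id = scaffold_id, verdict = verdict,
                 placements = placements,
                 residual_unplaced_bp = slen - covered,
                 scaffold_length = slen),
            class = "PlacementReport")
}

#' @export
print.PlacementReport <- function(x, ...) {
  cat(sprintf("PlacementReport %s: %s (%d placement(s), %.0f kb unplaced)\n",
              x$scaffold_id, x$verdict, nrow(x$placements),
              x$residual_unplaced_bp / 1000))
  invisible(x)
}

#' Place every scaffold of one assembly onto the other
#'
#' @param asm the assembly whose unassigned scaffolds are placed.
#' @param target the assembly placed onto.
#' @param ... passed to [place_scaffold()].
#' @return named list of `PlacementReport`s.
#' @export
place_all_scaffolds <- function(asm, target, ...) {
  ids <- scaffolds(asm)
  setNames(lapply(ids, function(sid)
    place_scaffold(asm$seq[[sid]], target, scaffold_id = sid, ...)), ids)
}

#' Cross-link ODS discordances with unassigned scaffolds
#'
#' For each ODS, reports the scaffolds that cover at least `min_recip` of
#' its sequence (by exact anchors), or `"NS"` (no substantial match) when
#' none does - mirroring how one draft's chromosome-only sequence usually
#' turns out to live in the other draft's unassigned scaffolds.
#'
#' @param discord discordance data.frame (ODS rows used).
#' @param asm_a,asm_b the two assemblies; an ODS of A is matched against
#'   the scaffolds of B and vice versa.
#' @param min_anchor anchor length.
#' @param min_recip coverage cutoff (0.5).
#' @return data.frame `code, scaffolds` (`;`-separated ids or `"NS"`).
#' @export
crosslink_ods_chrun <- function(discord, asm_a, asm_b, min_anchor = 50,
                                min_recip = 0.5) {
  ods <- discord[discord$category == "ODS" &
                 discord$eligibility != "sub-threshold", , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(ods))) {
    d <- ods[i, ]
    if (d$source == "A") {
      seqv <- substr(asm_a$seq[[d$a_seq]], d$a_start + 1, d$a_end)
      scaf_asm <- asm_b
    } else {
      seqv <- substr(asm_b$seq[[d$b_seq]], d$b_start + 1, d$b_end)
      scaf_asm <- asm_a
    }
    len <- nchar(seqv)
    hits <- character(0)
    sids <- scaffolds(scaf_asm)
    if (length(sids)) {
      an_all <- anchor_scan(seqv, scaf_asm$seq[sids], min_anchor,
                            q_id = "ods")
      for (sid in unique(an_all$b_seq)) {
        an <- an_all[an_all$b_seq == sid, , drop = FALSE]
        cov <- covered_bp(0, len, an$a_start, an$a_end) / len
        if (cov >= min_recip) hits <- c(hits, sid)
      }
    }
    out <- rbind(out, data.frame(
      code = d$code,
      scaffolds = if (length(hits)) paste(hits, collapse = ";") else "NS",
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(code = character(0), scaffolds = character(0),
                      stringsAsFactors = FALSE)
  out
}

#' Write placement reports as TSV (1-based inclusive coordinates)
#' @param reports list of `PlacementReport`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_placements <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    if (nrow(r$placements) == 0)
      return(data.frame(scaffold_id = r$scaffold_id, verdict = r$verdict,
                        target_seq = NA, target_start = NA, target_end = NA,
                        scaffold_start = NA, scaffold_end = NA, coverage = NA,
                        stringsAsFactors = FALSE))
    cbind(scaffold_id = r$scaffold_id, verdict = r$verdict,
          r$placements[, c("target_seq", "target_start", "target_end",
                           "scaffold_start", "scaffold_end", "coverage")])
  }))
  if (is.null(rows))
    rows <- data.frame(scaffold_id = character(0), verdict = character(0))
  rows$coverage <- round(rows$coverage, 4)
  write_tsv(to_report_coords(rows, start_cols = intersect(
    c("target_start", "scaffold_start"), names(rows))), path)
}
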