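# Synthetic genomes with planted rearrangements.
#
# A "true" genome is generated first; two assemblies A and B are then derived
# from it, each equal to the truth except over the footprints of the events
# planted into it. The truth table records, for every event, its true
# coordinates, its realized coordinates in each assembly, the discordance
# category the comparison stage is expected to call, and which assembly is
# the correct one (always the one the event was NOT applied to).

#' Generate a "true" genome
#'
#' Chromosomes are i.i.d. uniform A/C/G/T (which makes long anchors unique
#' with overwhelming probability at desk scale), with two kinds of planted
#' structure:
#' * interspersed repeat families: lowercase (soft-masked) copies of a
#'   family consensus, each copy carrying independent substitution noise so
#'   that uniqueness filters have something to reject;
#' * low-copy segmental duplications: exact uppercase copies of a segment
#'   placed on distinct chromosomes (optionally pinned to subtelomeric or
#'   pericentromeric ends), reproducing the multi-signal FISH phenomena of
#'   real pericentromeric/subtelomeric duplications.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_lengths bp lengths (recycled to `n_chrom`); each >= 200 kbp.
#' @param repeat_family_count,repeat_copies number of interspersed repeat
#'   families and of copies per family.
#' @param seed integer seed; the genome is byte-identical for a fixed seed.
#' @param repeat_len repeat unit length in bp.
#' @param repeat_noise per-copy substitution rate in `[0, 0.02]`.
#' @param segdup_families,segdup_copies,segdup_len low-copy duplication
#'   families (exact uppercase copies), copies per family, copy length.
#' @param segdup_placement `"random"`, `"subtelomeric"` (last 15% of the
#'   chromosome) or `"pericentromeric"` (first 15%; cow autosomes are
#'   acrocentric, so the centromere sits at the start).
#' @return an `Assembly` named `"truth"` with attributes `repeats` and
#'   `segdups` (data.frames of planted copy coordinates).
#' @export
generate_true_genome <- function(n_chrom, chrom_lengths, repeat_family_count = 0,
                                 repeat_copies = 0, seed = 1,
                                 repeat_len = 2000, repeat_noise = 0.01,
                                 segdup_families = 0, segdup_copies = 2,
                                 segdup_len = 220000,
                                 segdup_placement = c("random", "subtelomeric",
                                                      "pericentromeric")) {
  segdup_placement <- match.arg(segdup_placement)
  chrom_lengths <- rep_len(chrom_lengths, n_chrom)
  if (any(chrom_lengths < 200000))
    stop("chromosome lengths must be >= 200 kbp")
  rep_bp <- repeat_family_count * repeat_copies * repeat_len
  dup_bp <- segdup_families * segdup_copies * segdup_len
  if (rep_bp + dup_bp > 0.4 * sum(chrom_lengths))
    stop("infeasible packing: planted repeats/duplications exceed 40% of the genome")
  with_seed(seed, {
    ids <- paste0("chr", seq_len(n_chrom))
    seqs <- setNames(vapply(chrom_lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)), ids)
    reserved <- lapply(ids, function(i) data.frame(start = numeric(0),
                                                   end = numeric(0)))
    names(reserved) <- ids

    pick_slot <- function(len, placement = "random", chrom = NULL, pad = 1000) {
      for (try in 1:2000) {
        ci <- if (is.null(chrom))
          sample(ids, 1, prob = chrom_lengths) else chrom
        L <- nchar(seqs[[ci]])
        rng <- switch(placement,
          random = c(pad, L - len - pad),
          subtelomeric = c(floor(0.85 * L), L - len - pad),
          pericentromeric = c(pad, floor(0.15 * L) - len))
        if (rng[2] <= rng[1]) next
        s <- floor(runif(1, rng[1], rng[2]))
        r <- reserved[[ci]]
        if (!any(s < r$end + pad & s + len > r$start - pad))
          return(list(chrom = ci, start = s))
      }
      stop("infeasible packing: could not place a planted segment")
    }

    mutate <- function(s, rate) {
      if (rate <= 0) return(s)
      v <- strsplit(s, "")[[1]]
      n_mut <- rbinom(1, length(v), rate)
      if (n_mut > 0) {
        pos <- sample(length(v), n_mut)
        v[pos] <- vapply(v[pos], function(b)
          sample(setdiff(c("a", "c", "g", "t"), tolower(b)), 1), character(1))
      }
      paste(v, collapse = "")
    }

    segdups <- NULL
    for (f in seq_len(segdup_families)) {
      unit <- paste(sample(c("A", "C", "G", "T"), segdup_len, replace = TRUE),
                    collapse = "")
      free <- ids
      for (cp in seq_len(segdup_copies)) {
        ch <- if (length(free)) sample(free, 1) else NULL
        slot <- pick_slot(segdup_len, segdup_placement, chrom = ch)
        free <- setdiff(free, slot$chrom)
        substr(seqs[[slot$chrom]], slot$start + 1,
               slot$start + segdup_len) <- unit
        reserved[[slot$chrom]] <- rbind(reserved[[slot$chrom]],
          data.frame(start = slot$start, end = slot$start + segdup_len))
        segdups <- rbind(segdups, data.frame(
          family = f, copy = cp, chrom = slot$chrom, start = slot$start,
          end = slot$start + segdup_len, stringsAsFactors = FALSE))
      }
    }

    repeats <- NULL
    for (f in seq_len(repeat_family_count)) {
      consensus <- paste(sample(c("a", "c", "g", "t"), repeat_len,
                                replace = TRUE), collapse = "")
      for (cp in seq_len(repeat_copies)) {
        slot <- pick_slot(repeat_len)
        copy <- mutate(consensus, repeat_noise)
        substr(seqs[[slot$chrom]], slot$start + 1,
               slot$start + repeat_len) <- copy
        reserved[[slot$chrom]] <- rbind(reserved[[slot$chrom]],
          data.frame(start = slot$start, end = slot$start + repeat_len))
        repeats <- rbind(repeats, data.frame(
          family = f, copy = cp, chrom = slot$chrom, start = slot$start,
          end = slot$start + repeat_len, stringsAsFactors = FALSE))
      }
    }

    frac_upper <- vapply(ids, function(i) {
      L <- nchar(seqs[[i]])
      1 - cpp_masked_count(seqs[[i]], 0L, L) / L
    }, numeric(1))
    if (any(frac_upper < 0.6))
      stop("infeasible packing: < 60% unique uppercase sequence on ",
           paste(ids[frac_upper < 0.6], collapse = ", "))

    asm <- Assembly("truth", seqs, setNames(rep("chromosome", n_chrom), ids))
    attr(asm, "repeats") <- repeats
    attr(asm, "segdups") <- segdups
    asm
  })
}

# ---------------------------------------------------------------------------
# Event specifications
# ---------------------------------------------------------------------------

#' Specify a planted rearrangement event
#'
#' Event kinds and their semantics (the event is applied to one assembly;
#' the other assembly equals the truth over the footprint):
#' * `inversion`: the segment is reverse-complemented in place.
#' * `relocation`: the segment is excised and re-inserted at `dest_pos` on
#'   the same chromosome (a segment "mapped in distinct positions").
#' * `unplace`: the segment is removed from its chromosome and emitted as an
#'   unassigned scaffold record.
#' * `cross_move`: the segment is excised and inserted at `dest_pos` on
#'   `dest_chrom` (a discordant chromosome assignment).
#' * `dup_insert`: an extra copy of the segment is inserted at
#'   `dest_pos`/`dest_chrom`; the original locus is untouched (a false
#'   duplication in the applied assembly).
#' * `dup_collapse`: the truth carries several exact copies of the segment;
#'   the applied assembly keeps only the `start`/`end` copy and the copies
#'   listed in `copies` are deleted (a collapsed duplication).
#' * `deletion`: the segment is deleted outright.
#'
#' @param kind one of the kinds above.
#' @param assembly `"A"` or `"B"`: the assembly the event is applied to.
#' @param chrom,start,end target segment on the true genome (0-based
#'   half-open).
#' @param dest_chrom,dest_pos destination for
#'   `relocation`/`cross_move`/`dup_insert`.
#' @param scaffold_id scaffold name for `unplace` (auto-generated if `NA`).
#' @param copies data.frame `chrom,start,end` of the additional exact copies
#'   removed by `dup_collapse`.
#' @return an `event_spec` list.
#' @export
event_spec <- function(kind, assembly, chrom, start, end,
                       dest_chrom = NA_character_, dest_pos = NA_real_,
                       scaffold_id = NA_character_, copies = NULL) {
  kinds <- c("inversion", "relocation", "unplace", "cross_move",
             "dup_insert", "dup_collapse", "deletion")
  if (!kind %in% kinds) stop("unknown event kind: ", kind)
  stopifnot(assembly %in% c("A", "B"), end > start)
  if (kind %in% c("relocation", "cross_move", "dup_insert") && is.na(dest_pos))
    stop(kind, " requires dest_pos")
  if (kind %in% c("cross_move", "dup_insert") && is.na(dest_chrom))
    stop(kind, " requires dest_chrom")
  if (kind == "relocation" && is.na(dest_chrom)) dest_chrom <- chrom
  structure(list(kind = kind, assembly = assembly, chrom = chrom,
                 start = start, end = end, dest_chrom = dest_chrom,
                 dest_pos = dest_pos, scaffold_id = scaffold_id,
                 copies = copies),
            class = "event_spec")
}

# footprint intervals (on the true genome) that an event modifies in its
# assembly; insertion points are zero-length and padded by 1 bp
event_footprints <- function(ev) {
  fp <- data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                   stringsAsFactors = FALSE)
  if (!is.na(ev$dest_pos))
    fp <- rbind(fp, data.frame(chrom = ev$dest_chrom, start = ev$dest_pos,
                               end = ev$dest_pos + 1))
  if (!is.null(ev$copies))
    fp <- rbind(fp, ev$copies[, c("chrom", "start", "end")])
  fp
}

validate_events <- function(events, true) {
  len <- seq_lengths(true)
  for (side in c("A", "B")) {
    fps <- do.call(rbind, lapply(Filter(function(e) e$assembly == side, events),
                                 event_footprints))
    if (is.null(fps) || nrow(fps) < 2) next
    for (ch in unique(fps$chrom)) {
      f <- fps[fps$chrom == ch, , drop = FALSE]
      f <- f[order(f$start), , drop = FALSE]
      if (any(f$start[-1] < f$end[-nrow(f)]))
        stop("specification error: overlapping events on assembly ", side,
             " chromosome ", ch)
    }
  }
  for (ev in events) {
    for (i in seq_len(nrow(event_footprints(ev)))) {
      fp <- event_footprints(ev)[i, ]
      if (!fp$chrom %in% names(len) || fp$start < 0 || fp$end > len[[fp$chrom]])
        stop("specification error: event footprint out of bounds on ",
             fp$chrom)
    }
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Deriving the two assemblies
# ---------------------------------------------------------------------------

# per-chromosome edit application; edits have true coordinates.
# types: del [start,end); inv [start,end); ins at start with $payload.
# Returns new sequence plus realized [start,end) of every edit.
apply_edits <- function(seq, edits) {
  if (length(edits) == 0)
    return(list(seq = seq, realized = list()))
  ord <- order(vapply(edits, `[[`, numeric(1), "start"))
  edits <- edits[ord]
  pieces <- character(0)
  realized <- vector("list", length(edits))
  cursor <- 0
  out_len <- 0
  emit <- function(s) {
    pieces[[length(pieces) + 1]] <<- s
    out_len <<- out_len + nchar(s)
  }
  for (i in seq_along(edits)) {
    ed <- edits[[i]]
    if (ed$start > cursor)
      emit(substr(seq, cursor + 1, ed$start))
    rs <- out_len
    if (ed$type == "del") {
      cursor <- ed$end
      realized[[i]] <- c(rs, rs)
    } else if (ed$type == "inv") {
      emit(reverse_complement(substr(seq, ed$start + 1, ed$end)))
      cursor <- ed$end
      realized[[i]] <- c(rs, out_len)
    } else if (ed$type == "ins") {
      emit(ed$payload)
      cursor <- ed$start
      realized[[i]] <- c(rs, out_len)
    } else stop("unknown edit type")
  }
  emit(substr(seq, cursor + 1, nchar(seq)))
  realized_orig <- vector("list", length(edits))
  realized_orig[ord] <- realized
  list(seq = paste(pieces, collapse = ""), realized = realized_orig)
}

# map a true-genome position through a chromosome's edit list
map_true_pos <- function(edits, pos) {
  shift <- 0
  for (ed in edits) {
    if (ed$type == "del") {
      if (pos >= ed$end) shift <- shift - (ed$end - ed$start)
      else if (pos > ed$start) return(NA_real_)
    } else if (ed$type == "ins") {
      if (pos >= ed$start) shift <- shift + nchar(ed$payload)
    }
  }
  pos + shift
}

#' Derive two assemblies from a true genome by applying planted events
#'
#' Each event is applied to exactly one assembly; the other assembly equals
#' the truth over the event footprint. The returned truth table records
#' per-event realized coordinates in both assemblies and the discordance the
#' comparison stage is expected to call.
#'
#' @param true an `Assembly` from [generate_true_genome()].
#' @param events list of [event_spec()] objects.
#' @param seed unused (the derivation is deterministic); kept so bundle
#'   front-ends can pass a single seed everywhere.
#' @return list with elements `a`, `b` (Assemblies), `truth` (data.frame,
#'   one row per event) and `expected` (data.frame of expected discordances,
#'   primary and secondary).
#' @export
derive_assemblies <- function(true, events, seed = NULL) {
  validate_events(events, true)
  chroms <- chromosomes(true)
  scaffold_n <- 0

  build_side <- function(side) {
    evs <- Filter(function(e) e$assembly == side, events)
    edit_map <- setNames(vector("list", length(chroms)), chroms)
    scaffs <- character(0)
    ev_edit_idx <- list()  # event id -> (chrom, index) of its defining edit
    add_edit <- function(ch, ed) {
      edit_map[[ch]][[length(edit_map[[ch]]) + 1]] <<- ed
      length(edit_map[[ch]])
    }
    for (ev in evs) {
      seg <- substr(true$seq[[ev$chrom]], ev$start + 1, ev$end)
      id <- attr(ev, "event_id")
      if (ev$kind == "inversion") {
        i <- add_edit(ev$chrom, list(type = "inv", start = ev$start, end = ev$end))
        ev_edit_idx[[id]] <- list(chrom = ev$chrom, idx = i)
      } else if (ev$kind %in% c("relocation", "cross_move")) {
        add_edit(ev$chrom, list(type = "del", start = ev$start, end = ev$end))
        i <- add_edit(ev$dest_chrom,
                      list(type = "ins", start = ev$dest_pos, payload = seg))
        ev_edit_idx[[id]] <- list(chrom = ev$dest_chrom, idx = i)
      } else if (ev$kind == "dup_insert") {
        i <- add_edit(ev$dest_chrom,
                      list(type = "ins", start = ev$dest_pos, payload = seg))
        ev_edit_idx[[id]] <- list(chrom = ev$dest_chrom, idx = i)
      } else if (ev$kind %in% c("deletion", "unplace")) {
        i <- add_edit(ev$chrom, list(type = "del", start = ev$start, end = ev$end))
        ev_edit_idx[[id]] <- list(chrom = ev$chrom, idx = i)
        if (ev$kind == "unplace") {
          sid <- ev$scaffold_id
          if (is.na(sid)) {
            scaffold_n <<- scaffold_n + 1
            sid <- sprintf("scaffold_%d", scaffold_n)
          }
          scaffs[sid] <- seg
          ev_edit_idx[[id]]$scaffold <- sid
        }
      } else if (ev$kind == "dup_collapse") {
        for (j in seq_len(nrow(ev$copies))) {
          cpy <- ev$copies[j, ]
          add_edit(cpy$chrom, list(type = "del", start = cpy$start,
                                   end = cpy$end))
        }
        ev_edit_idx[[id]] <- list(chrom = ev$chrom, idx = NA)
      }
    }
    applied <- lapply(chroms, function(ch)
      apply_edits(true$seq[[ch]], edit_map[[ch]]))
    names(applied) <- chroms
    seqs <- c(vapply(applied, `[[`, character(1), "seq"), scaffs)
    role <- setNames(c(rep("chromosome", length(chroms)),
                       rep("scaffold", length(scaffs))), names(seqs))
    list(asm = Assembly(side, seqs, role),
         edits = edit_map, applied = applied, ev_edit_idx = ev_edit_idx)
  }

  for (i in seq_along(events)) attr(events[[i]], "event_id") <- i
  A <- build_side("A")
  B <- build_side("B")

  realized_applied <- function(side_obj, ev) {
    id <- attr(ev, "event_id")
    info <- side_obj$ev_edit_idx[[id]]
    if (!is.null(info$scaffold))
      return(list(seq = info$scaffold, start = 0, end = ev$end - ev$start))
    if (is.na(info$idx[1])) return(list(seq = NA, start = NA, end = NA))
    r <- side_obj$applied[[info$chrom]]$realized[[info$idx]]
    list(seq = info$chrom, start = r[1], end = r[2])
  }
  realized_other <- function(side_obj, chrom, start, end) {
    eds <- side_obj$edits[[chrom]]
    if (is.null(eds)) eds <- list()
    s <- map_true_pos(eds, start); e <- map_true_pos(eds, end)
    list(seq = chrom, start = s, end = e)
  }

  truth <- NULL
  expected <- NULL
  for (ev in events) {
    id <- attr(ev, "event_id")
    applied_obj <- if (ev$assembly == "A") A else B
    other_obj <- if (ev$assembly == "A") B else A
    other_side <- if (ev$assembly == "A") "B" else "A"
    ra <- realized_applied(applied_obj, ev)
    if (ev$kind %in% c("deletion", "dup_collapse")) ra <- list(seq = NA, start = NA, end = NA)
    ro <- realized_other(other_obj, ev$chrom, ev$start, ev$end)
    coords <- if (ev$assembly == "A") list(a = ra, b = ro) else list(a = ro, b = ra)
    truth <- rbind(truth, data.frame(
      event_id = id, kind = ev$kind, applies_to = ev$assembly,
      chrom = ev$chrom, start = ev$start, end = ev$end,
      dest_chrom = ev$dest_chrom, dest_pos = ev$dest_pos,
      scaffold_id = if (!is.null(applied_obj$ev_edit_idx[[id]]$scaffold))
        applied_obj$ev_edit_idx[[id]]$scaffold else NA_character_,
      a_seq = coords$a$seq, a_start = coords$a$start, a_end = coords$a$end,
      b_seq = coords$b$seq, b_start = coords$b$start, b_end = coords$b$end,
      correct_assembly = other_side, stringsAsFactors = FALSE))

    add_exp <- function(category, a, b, source = NA_character_,
                        primary = TRUE) {
      expected <<- rbind(expected, data.frame(
        event_id = id, kind = ev$kind, category = category,
        a_seq = a$seq, a_start = a$start, a_end = a$end,
        b_seq = b$seq, b_start = b$start, b_end = b$end,
        source = source, primary = primary,
        correct_assembly = other_side, stringsAsFactors = FALSE))
    }
    none <- list(seq = NA_character_, start = NA_real_, end = NA_real_)
    size <- ev$end - ev$start
    if (ev$kind == "inversion") {
      add_exp("INV", coords$a, coords$b)
    } else if (ev$kind == "relocation") {
      add_exp("MDP", coords$a, coords$b)
    } else if (ev$kind %in% c("unplace", "deletion")) {
      # segment retained only by the other assembly
      if (other_side == "A") add_exp("ODS", ro, none, source = "A")
      else add_exp("ODS", none, ro, source = "B")
    } else if (ev$kind == "cross_move") {
      if (other_side == "A") {
        add_exp("DCM", ro, ra)
        add_exp("ODS", ro, none, source = "A", primary = FALSE)
        add_exp("ODS", none, ra, source = "B", primary = FALSE)
      } else {
        add_exp("DCM", ra, ro)
        add_exp("ODS", none, ro, source = "B", primary = FALSE)
        add_exp("ODS", ra, none, source = "A", primary = FALSE)
      }
    } else if (ev$kind == "dup_insert") {
      # extra copy present only in the applied assembly
      if (ev$assembly == "A") add_exp("ODS", ra, none, source = "A")
      else add_exp("ODS", none, ra, source = "B")
      if (ev$assembly == "A") add_exp("DCM", ra, none, primary = FALSE)
      else add_exp("DCM", none, ra, primary = FALSE)
    } else if (ev$kind == "dup_collapse") {
      for (j in seq_len(nrow(ev$copies))) {
        cpy <- ev$copies[j, ]
        roc <- realized_other(other_obj, cpy$chrom, cpy$start, cpy$end)
        if (other_side == "A") {
          add_exp("ODS", roc, none, source = "A")
          add_exp("DCM", roc, none, primary = FALSE)
        } else {
          add_exp("ODS", none, roc, source = "B")
          add_exp("DCM", none, roc, primary = FALSE)
        }
      }
    }
  }
  list(a = A$asm, b = B$asm, truth = truth, expected = expected)
}

# ---------------------------------------------------------------------------
# BES library
# ---------------------------------------------------------------------------

#' Generate a BAC-end-sequence library from the true genome
#'
#' Clone inserts are placed uniformly over the chromosomes with lengths
#' uniform in `insert_range`; each clone carries the two end sequences of
#' its insert, facing inward on opposite strands (end 1 is the plus-strand
#' prefix of the insert, end 2 the reverse complement of its suffix).
#'
#' @param true an `Assembly`.
#' @param n_clones number of clones.
#' @param insert_range `(min, max)` insert length in bp.
#' @param end_len end-sequence read length (>= 100 bp).
#' @param seed integer seed.
#' @return a `BESLibrary` data.frame with columns
#'   `clone_id, chrom, start, end, end1, end2`.
#' @export
generate_bes_library <- function(true, n_clones, insert_range = c(50000, 300000),
                                 end_len = 600, seed = 1) {
  stopifnot(inherits(true, "Assembly"))
  if (end_len < 100) stop("end_len must be >= 100 bp")
  lens <- seq_lengths(true)[chromosomes(true)]
  if (max(insert_range) > max(lens))
    stop("insert_range infeasible: exceeds chromosome lengths")
  with_seed(seed, {
    ok <- names(lens)[lens >= max(insert_range) + 2]
    chrom <- sample(ok, n_clones, replace = TRUE, prob = lens[ok])
    L <- floor(runif(n_clones, insert_range[1], insert_range[2] + 1))
    L <- pmin(L, insert_range[2])
    start <- floor(runif(n_clones, 0, lens[chrom] - L))
    end <- start + L
    end1 <- substr(true$seq[chrom], start + 1, start + end_len)
    end2 <- vapply(seq_len(n_clones), function(i)
      reverse_complement(substr(true$seq[[chrom[i]]], end[i] - end_len + 1,
                                end[i])), character(1))
    lib <- data.frame(clone_id = sprintf("C%05d", seq_len(n_clones)),
                      chrom = chrom, start = start, end = end,
                      end1 = end1, end2 = end2, stringsAsFactors = FALSE)
    class(lib) <- c("BESLibrary", "data.frame")
    lib
  })
}

#' Write a BES library as TSV + FASTA
#' @param lib a `BESLibrary`.
#' @param tsv,fasta output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_bes_library <- function(lib, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv))
    write_tsv(to_report_coords(lib[, c("clone_id", "chrom", "start", "end")]),
              tsv)
  if (!is.null(fasta)) {
    seqs <- setNames(c(lib$end1, lib$end2),
                     c(paste0(lib$clone_id, ".1"), paste0(lib$clone_id, ".2")))
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), fasta, width = 80)
  }
  invisible(c(tsv, fasta))
}

# ---------------------------------------------------------------------------
# Study-condition bundle
# ---------------------------------------------------------------------------

#' Sample a default menu of planted events for a synthetic genome
#'
#' Builds 12-13 events spanning every event kind, with sizes chosen so that
#' every intended discordance clears its reporting/testing threshold
#' (inversions > 500 kbp, relocations and cross-chromosome moves > 200 kbp,
#' unplaced/deleted segments > 200 kbp), one deliberately sub-threshold
#' 90 kbp inversion, and relocation displacements >= 2.5x the segment length
#' so the moved segment (not the intervening sequence) is the flagged one.
#' Event boundaries snap to unmasked (uppercase) positions and avoid planted
#' repeats and duplications.
#'
#' @param true an `Assembly` from [generate_true_genome()].
#' @param seed integer seed.
#' @return list of [event_spec()] objects.
#' @export
default_event_menu <- function(true, seed = 1) {
  lens <- seq_lengths(true)[chromosomes(true)]
  chroms <- names(lens)
  if (length(chroms) < 8)
    stop("default event menu needs >= 8 chromosomes")
  reserved <- attr(true, "repeats")
  segdups <- attr(true, "segdups")
  reserved <- rbind(if (!is.null(reserved)) reserved[, c("chrom", "start", "end")],
                    if (!is.null(segdups)) segdups[, c("chrom", "start", "end")])
  with_seed(seed, {
    # Interspersed repeats may lie inside event footprints (boundaries are
    # snapped off them); segmental duplications and other events are hard
    # exclusions so footprints never interfere, with a 100 kb mutual
    # spacing keeping flanking anchors separable.
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), pad = numeric(0))
    if (!is.null(segdups))
      res <- rbind(res, data.frame(chrom = segdups$chrom,
                                   start = segdups$start, end = segdups$end,
                                   pad = 2000))
    reserve <- function(ch, s, e, pad = 100000) {
      res <<- rbind(res, data.frame(chrom = ch, start = s, end = e, pad = pad,
                                    stringsAsFactors = FALSE))
    }
    snap_up <- function(ch, p) {
      s <- true$seq[[ch]]
      while (p < nchar(s) && grepl("[acgtnN]", substr(s, p + 1, p + 1)))
        p <- p + 1
      p
    }
    free_slot <- function(ch, len, lo = 120000, hi = lens[[ch]] - 120000,
                          pad = 100000) {
      for (try in 1:500) {
        if (hi - len <= lo) break
        s <- snap_up(ch, floor(runif(1, lo, hi - len)))
        e <- snap_up(ch, s + len)
        r <- res[res$chrom == ch, , drop = FALSE]
        clearance <- pmax(r$pad, pad)
        if (!any(s < r$end + clearance & e > r$start - clearance) && e <= hi) {
          reserve(ch, s, e, pad)
          return(c(s, e))
        }
      }
      stop("could not place event of ", len, " bp on ", ch)
    }
    side <- function() sample(c("A", "B"), 1)
    evs <- list()
    add <- function(ev) evs[[length(evs) + 1]] <<- ev

    # inversions on chr1, chr2, chr4 (+ one sub-threshold on chr6)
    for (spec in list(c(1, 600000), c(2, 900000), c(4, 520000))) {
      ch <- chroms[spec[1]]
      se <- free_slot(ch, spec[2])
      add(event_spec("inversion", side(), ch, se[1], se[2]))
    }
    se <- free_slot(chroms[6], 90000)
    add(event_spec("inversion", side(), chroms[6], se[1], se[2]))

    # relocations on chr3 and chr7: destination 1.6-1.9x the segment
    # length beyond it, so the intervening sequence stays longer than the
    # moved segment and the moved segment is the one flagged as displaced;
    # the whole segment-to-destination span is reserved in one piece
    for (spec in list(c(3, 240000), c(7, 300000))) {
      ch <- chroms[spec[1]]
      len <- spec[2]
      gap <- floor(runif(1, 1.6 * len, 1.9 * len))
      span <- free_slot(ch, len + gap + 2000)
      s <- span[1]
      e <- snap_up(ch, s + len)
      d <- snap_up(ch, s + len + gap)
      add(event_spec("relocation", side(), ch, s, e, dest_pos = d))
    }

    # unplaced scaffolds on chr5 (800 kbp) and chr6 (400 kbp)
    se <- free_slot(chroms[5], 800000)
    add(event_spec("unplace", side(), chroms[5], se[1], se[2]))
    se <- free_slot(chroms[6], 400000)
    add(event_spec("unplace", side(), chroms[6], se[1], se[2]))

    # deletion on chr4
    se <- free_slot(chroms[4], 220000)
    add(event_spec("deletion", side(), chroms[4], se[1], se[2]))

    # cross-chromosome move chr8 -> chr7
    se <- free_slot(chroms[8], 500000)
    d <- free_slot(chroms[7], 1000, pad = 150000)[1]
    add(event_spec("cross_move", side(), chroms[8], se[1], se[2],
                   dest_chrom = chroms[7], dest_pos = d))

    # false duplication: chr1 segment copied onto chr8
    se <- free_slot(chroms[1], 260000)
    d <- free_slot(chroms[8], 1000)[1]
    add(event_spec("dup_insert", side(), chroms[1], se[1], se[2],
                   dest_chrom = chroms[8], dest_pos = d))

    # collapsed duplication: keep segdup copy 1, lose the others
    if (!is.null(segdups) && nrow(segdups) >= 2) {
      fam <- segdups[segdups$family == segdups$family[1], ]
      add(event_spec("dup_collapse", side(), fam$chrom[1], fam$start[1],
                     fam$end[1],
                     copies = fam[-1, c("chrom", "start", "end")]))
    }
    evs
  })
}

#' Simulate a complete study bundle
#'
#' One call generating the true genome, the two derived assemblies with the
#' default planted-event menu, and the BES library, under the package's
#' standard study conditions: 8 chromosomes of 2 Mbp, two interspersed
#' repeat families of 40 noisy lowercase copies, one 2-copy exact segmental
#' duplication of 220 kbp, 12-13 planted events spanning every event kind,
#' and 1600 BAC clones with 50-300 kb inserts.
#'
#' @param seed single integer driving every source of randomness.
#' @param n_chrom,chrom_len genome shape.
#' @param n_clones BES library size.
#' @param events optional explicit event list (default: [default_event_menu()]).
#' @return list with `true`, `a`, `b`, `truth`, `expected`, `bes`.
#' @export
simulate_bundle <- function(seed = 1, n_chrom = 8, chrom_len = 2e6,
                            n_clones = 1600, events = NULL) {
  true <- generate_true_genome(n_chrom, rep(chrom_len, n_chrom),
                               repeat_family_count = 2, repeat_copies = 40,
                               seed = seed, repeat_len = 2000,
                               repeat_noise = 0.01, segdup_families = 1,
                               segdup_copies = 2, segdup_len = 220000,
                               segdup_placement = "pericentromeric")
  if (is.null(events)) events <- default_event_menu(true, seed = seed + 1)
  der <- derive_assemblies(true, events)
  bes <- generate_bes_library(true, n_clones, seed = seed + 2)
  c(list(true = true, bes = bes, events = events), der)
}
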