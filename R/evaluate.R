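# Recovery evaluation of a comparison against a synthetic truth table.

#' Evaluate planted-event recovery
#'
#' Matches the reportable, non-gap-flagged discordances of a comparison
#' against the expected-discordance table of a synthetic bundle. A
#' detection matches an expectation when the categories agree and every
#' expected locus boundary is reproduced within `tol` bp on its assembly.
#' Expected discordances whose size does not exceed the reporting floor
#' count as true negatives (they must NOT be reported).
#'
#' @param kept reportable discordance data.frame (e.g. `res$kept`).
#' @param expected expected-discordance table from [derive_assemblies()].
#' @param th a [thresholds()] object.
#' @param tol breakpoint tolerance in bp (defaults to
#'   `min_anchor + max_gap` of the standard parameters).
#' @return list: `events` (per expected primary row: detected flag, matched
#'   code, max breakpoint error), `precision`, `recall`,
#'   `max_breakpoint_error`, `false_positives` (codes).
#' @export
evaluate_recovery <- function(kept, expected, th = thresholds(),
                              tol = 50000 + 50) {
  rep_rows <- kept[kept$eligibility != "sub-threshold" &
                   !kept$gap_repeat_flag, , drop = FALSE]
  side_err <- function(exp_row, det_row, side) {
    es <- exp_row[[paste0(side, "_start")]]
    ee <- exp_row[[paste0(side, "_end")]]
    eq <- exp_row[[paste0(side, "_seq")]]
    if (is.na(eq)) return(0)
    ds <- det_row[[paste0(side, "_start")]]
    de <- det_row[[paste0(side, "_end")]]
    dq <- det_row[[paste0(side, "_seq")]]
    if (is.na(dq) || dq != eq) return(Inf)
    max(abs(ds - es), abs(de - ee))
  }
  match_one <- function(exp_row) {
    cand <- rep_rows[rep_rows$category == exp_row$category, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    errs <- vapply(seq_len(nrow(cand)), function(i)
      max(side_err(exp_row, cand[i, ], "a"),
          side_err(exp_row, cand[i, ], "b")), numeric(1))
    if (all(errs > tol)) return(NULL)
    i <- which.min(errs)
    list(code = cand$code[i], err = errs[i])
  }

  prim <- expected[expected$primary, , drop = FALSE]
  exp_size <- function(r)
    max(r$a_end - r$a_start, r$b_end - r$b_start, na.rm = TRUE)
  rows <- NULL
  matched_codes <- character(0)
  for (i in seq_len(nrow(prim))) {
    er <- prim[i, ]
    should_report <- exp_size(er) > th$report_min
    m <- match_one(er)
    rows <- rbind(rows, data.frame(
      event_id = er$event_id, kind = er$kind, category = er$category,
      should_report = should_report, detected = !is.null(m),
      code = if (is.null(m)) NA_character_ else m$code,
      bp_error = if (is.null(m)) NA_real_ else m$err,
      stringsAsFactors = FALSE))
    if (!is.null(m)) matched_codes <- c(matched_codes, m$code)
  }
  # secondary expectations (member ODSs of a cross-move, one-sided DCMs)
  # absorb additional detections without counting as false positives
  sec <- expected[!expected$primary, , drop = FALSE]
  sec_rows <- NULL
  for (i in seq_len(nrow(sec))) {
    m <- match_one(sec[i, ])
    if (!is.null(m)) {
      matched_codes <- c(matched_codes, m$code)
      sec_rows <- rbind(sec_rows, data.frame(
        event_id = sec$event_id[i], code = m$code, stringsAsFactors = FALSE))
    }
  }

  pos <- rows[rows$should_report, , drop = FALSE]
  recall <- if (nrow(pos)) mean(pos$detected) else 1
  fp <- setdiff(rep_rows$code[rep_rows$category %in%
                              c("INV", "MDP", "ODS", "DCM")], matched_codes)
  n_det <- length(unique(rep_rows$code))
  precision <- if (n_det) (n_det - length(fp)) / n_det else 1
  over_reported <- rows$detected & !rows$should_report
  if (any(over_reported)) precision <- min(precision, 1 - mean(over_reported))
  list(events = rows, precision = precision, recall = recall,
       max_breakpoint_error = suppressWarnings(
         max(c(0, pos$bp_error[pos$detected]), na.rm = TRUE)),
       false_positives = fp, secondary = sec_rows)
}

#' Score simulated-experiment verdicts against the truth table
#'
#' @param fish the `fish` element of a `CompareResult`.
#' @param kept the reportable discordances of the result.
#' @param recovery output of [evaluate_recovery()] (to map detection codes
#'   back to events).
#' @param truth_table the per-event truth table of the bundle.
#' @return data.frame per tested code: the verdict, the correct assembly,
#'   and whether the verdict names it.
#' @export
score_verdicts <- function(fish, kept, recovery, truth_table) {
  if (is.null(fish) || is.null(fish$table) || !nrow(fish$table))
    return(data.frame(code = character(0), supported = character(0),
                      correct = character(0), ok = logical(0)))
  ev <- recovery$events
  rows <- NULL
  for (i in seq_len(nrow(fish$table))) {
    code <- fish$table$code[i]
    hit <- ev[!is.na(ev$code) & ev$code == code, , drop = FALSE]
    eid <- if (nrow(hit)) hit$event_id[1]
           else if (!is.null(recovery$secondary) &&
                    code %in% recovery$secondary$code)
             recovery$secondary$event_id[recovery$secondary$code == code][1]
           else NA_integer_
    if (is.na(eid)) next
    if (is.null(fish$verdicts[[code]])) next   # infeasible: nothing decided
    correct <- truth_table$correct_assembly[truth_table$event_id == eid][1]
    v <- fish$verdicts[[code]]
    named <- switch(v$supported, "hypothesis-A" = "A", "hypothesis-B" = "B",
                    "neither" = "neither", "both-consistent" = "both")
    rows <- rbind(rows, data.frame(
      code = code, supported = named, correct = correct,
      ok = identical(named, correct), stringsAsFactors = FALSE))
  }
  if (is.null(rows))
    rows <- data.frame(code = character(0), supported = character(0),
                       correct = character(0), ok = logical(0))
  rows
}
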