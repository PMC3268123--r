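# Simulated metaphase / interphase FISH on the true genome, and the
# support-fraction verdict between two assembly hypotheses.
#
# The interphase observable is the proximity-canonical arrangement of a
# probe triplet: the three labels written from the flank nearest the
# internal probe to the far flank. Reading the arrangement proximity-first
# fixes the otherwise arbitrary reading direction of a nucleus, keeps the
# sample space at the 6 label permutations, and is what actually
# discriminates an inversion: a positional ordering alone never changes
# when a segment between two outside probes is inverted - only which flank
# the internal probe sits nearest does.

#' Loci of a probe sequence on a genome
#'
#' Finds every locus where the probe has at least
#' `th$fish_visibility_min` contiguous matching bp (exact, either strand);
#' anchors within `cluster_gap` are merged into one locus. Loci below the
#' visibility floor are silent - sequences shorter than the floor are not
#' visualized by FISH.
#'
#' @param probe_seq probe nucleotide string.
#' @param genome an `Assembly`.
#' @param th a [thresholds()] object.
#' @param cluster_gap merge distance for anchors of one locus (bp).
#' @return data.frame `chrom, start, end`.
#' @export
probe_loci <- function(probe_seq, genome, th = thresholds(),
                       cluster_gap = 50000) {
  out <- NULL
  all_an <- anchor_scan(probe_seq, genome$seq,
                        min_anchor = th$fish_visibility_min, q_id = "probe")
  for (ch in unique(all_an$b_seq)) {
    an <- all_an[all_an$b_seq == ch, , drop = FALSE]
    an <- an[order(an$b_start), , drop = FALSE]
    cs <- an$b_start[1]; ce <- an$b_end[1]
    for (i in seq_len(nrow(an))[-1]) {
      if (an$b_start[i] <= ce + cluster_gap) ce <- max(ce, an$b_end[i])
      else { out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce));
             cs <- an$b_start[i]; ce <- an$b_end[i] }
    }
    out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  out
}

#' Simulate metaphase FISH
#'
#' Each cell reports one signal per true-genome locus of each probe (see
#' [probe_loci()]); signals drop out independently with probability
#' `p_drop` per locus per cell. A probe absent from the genome yields zero
#' signals.
#'
#' @param probes data.frame `probe_id, seq` (probe sequences).
#' @param true_genome the true `Assembly`.
#' @param n_cells number of metaphases inspected.
#' @param th a [thresholds()] object.
#' @param p_drop per-locus per-cell dropout probability.
#' @param seed integer seed.
#' @return data.frame of class `FISHObservation`:
#'   `cell, probe_id, chrom, pos` (one row per retained signal), with the
#'   per-probe locus table in attribute `loci`.
#' @export
simulate_metaphase <- function(probes, true_genome, n_cells = 10,
                               th = thresholds(), p_drop = 0.05, seed = 1) {
  loci <- lapply(seq_len(nrow(probes)), function(i)
    probe_loci(probes$seq[i], true_genome, th))
  names(loci) <- probes$probe_id
  with_seed(seed, {
    rows <- NULL
    for (cell in seq_len(n_cells)) {
      for (i in seq_len(nrow(probes))) {
        lc <- loci[[i]]
        if (!nrow(lc)) next
        keep <- runif(nrow(lc)) >= p_drop
        if (!any(keep)) next
        rows <- rbind(rows, data.frame(
          cell = cell, probe_id = probes$probe_id[i],
          chrom = lc$chrom[keep],
          pos = (lc$start[keep] + lc$end[keep]) / 2,
          stringsAsFactors = FALSE))
      }
    }
    if (is.null(rows))
      rows <- data.frame(cell = integer(0), probe_id = character(0),
                         chrom = character(0), pos = numeric(0),
                         stringsAsFactors = FALSE)
    attr(rows, "loci") <- loci
    class(rows) <- c("FISHObservation", "data.frame")
    rows
  })
}

#' Proximity-canonical arrangement of a probe triplet
#'
#' Given named positions of three co-linear probes, returns the labels
#' ordered from the flank nearest the middle probe to the far flank.
#'
#' @param positions named numeric vector of length 3 (probe positions on
#'   one chromosome).
#' @return character vector of the three labels in canonical order.
#' @export
triplet_pattern <- function(positions) {
  stopifnot(length(positions) == 3, !is.null(names(positions)))
  ord <- names(sort(positions))
  d_left <- sort(positions)[2] - sort(positions)[1]
  d_right <- sort(positions)[3] - sort(positions)[2]
  if (d_left <= d_right) ord else base::rev(ord)
}

pattern_key <- function(labels) paste(labels, collapse = "-")

all_permutations <- function(labels) {
  idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
              c(3, 1, 2), c(3, 2, 1))
  vapply(idx, function(i) pattern_key(labels[i]), character(1))
}

#' Simulate interphase FISH of a probe triplet
#'
#' Each nucleus reports the true proximity-canonical arrangement with
#' probability `1 - disorder_p`, and otherwise a uniformly random
#' permutation of the three labels (so the chance of accidentally
#' reproducing the true arrangement under disorder is 1/6).
#'
#' @param positions named true positions of the three probes; all three
#'   must lie on one chromosome (pass the per-chromosome positions - a
#'   triplet spread over several chromosomes needs the metaphase modality).
#' @param chroms optional chromosome ids of the probes, checked for
#'   equality.
#' @param n_nuclei number of nuclei inspected.
#' @param disorder_p probability that a nucleus shows a random arrangement.
#' @param seed integer seed.
#' @return named integer vector of counts over the 6 possible
#'   arrangements (keys `"L-I-R"` style); sums to `n_nuclei`.
#' @export
simulate_interphase_triplet <- function(positions, chroms = NULL,
                                        n_nuclei = 50, disorder_p = 0.15,
                                        seed = 1) {
  stopifnot(length(positions) == 3)
  if (!is.null(chroms) && length(unique(chroms)) != 1)
    stop("probes lie on different chromosomes: metaphase modality required")
  labels <- names(positions)
  perms <- all_permutations(labels)
  counts <- setNames(integer(6), perms)
  if (n_nuclei == 0) return(counts)
  truth <- pattern_key(triplet_pattern(positions))
  with_seed(seed, {
    disordered <- runif(n_nuclei) < disorder_p
    obs <- ifelse(disordered,
                  sample(perms, n_nuclei, replace = TRUE),
                  truth)
    tab <- table(factor(obs, levels = perms))
    counts[names(tab)] <- as.integer(tab)
    counts
  })
}

#' Decide between two assembly hypotheses from FISH observations
#'
#' Interphase: each hypothesis predicts a triplet arrangement; the winner
#' is the hypothesis matched by the majority of nuclei and the support
#' fraction is its matching share. If neither pattern reaches half the
#' nuclei the verdict is `"neither"`; identical predictions give
#' `"both-consistent"`. Metaphase: each hypothesis predicts a
#' chromosome-assignment multiset per probe; the winner is the hypothesis
#' whose prediction equals the modal per-cell observation (an
#' all-or-nothing readout), `"neither"` if no prediction matches.
#'
#' @param observations interphase counts from
#'   [simulate_interphase_triplet()], or a `FISHObservation` from
#'   [simulate_metaphase()].
#' @param hypothesis_a,hypothesis_b predicted patterns: a character vector
#'   of 3 labels (interphase) or a named list `probe_id -> character
#'   vector of chromosomes` (metaphase).
#' @param modality `"interphase"` or `"metaphase"`.
#' @return a `Verdict` list: `supported` (`"hypothesis-A"`,
#'   `"hypothesis-B"`, `"neither"`, `"both-consistent"`),
#'   `support_fraction`, `n_cells`, `modality`.
#' @export
decide <- function(observations, hypothesis_a, hypothesis_b,
                   modality = c("interphase", "metaphase")) {
  modality <- match.arg(modality)
  if (modality == "interphase") {
    n <- sum(observations)
    if (n == 0) stop("undefined verdict: no cells observed")
    ka <- pattern_key(hypothesis_a)
    kb <- pattern_key(hypothesis_b)
    ca <- if (ka %in% names(observations)) observations[[ka]] else 0
    cb <- if (kb %in% names(observations)) observations[[kb]] else 0
    if (identical(ka, kb))
      return(verdict("both-consistent", ca / n, n, modality))
    if (max(ca, cb) / n < 0.5)
      return(verdict("neither", max(ca, cb) / n, n, modality))
    if (ca >= cb) verdict("hypothesis-A", ca / n, n, modality)
    else verdict("hypothesis-B", cb / n, n, modality)
  } else {
    obs <- observations
    n <- length(unique(obs$cell))
    if (n == 0) stop("undefined verdict: no cells observed")
    sig <- function(hyp) {
      ids <- sort(names(hyp))
      paste(vapply(ids, function(p)
        paste0(p, ":", paste(sort(hyp[[p]]), collapse = ",")),
        character(1)), collapse = ";")
    }
    cell_sigs <- vapply(split(obs, obs$cell), function(oc) {
      ids <- sort(unique(oc$probe_id))
      paste(vapply(ids, function(p)
        paste0(p, ":", paste(sort(oc$chrom[oc$probe_id == p]), collapse = ",")),
        character(1)), collapse = ";")
    }, character(1))
    modal <- names(sort(table(cell_sigs), decreasing = TRUE))[1]
    sa <- sig(hypothesis_a); sb <- sig(hypothesis_b)
    frac <- function(s) mean(cell_sigs == s)
    if (identical(sa, sb))
      return(verdict(if (modal == sa) "both-consistent" else "neither",
                     frac(sa), n, modality))
    if (modal == sa) verdict("hypothesis-A", frac(sa), n, modality)
    else if (modal == sb) verdict("hypothesis-B", frac(sb), n, modality)
    else verdict("neither", max(frac(sa), frac(sb)), n, modality)
  }
}

verdict <- function(supported, support_fraction, n_cells, modality) {
  structure(list(supported = supported,
                 support_fraction = support_fraction,
                 n_cells = n_cells, modality = modality),
            class = "Verdict")
}

#' Format a verdict the way the disambiguation tables print it
#'
#' Interphase verdicts print as `"<assembly> (<pct>%)"`; metaphase and PCR
#' verdicts print the supported assembly alone; `"neither"` prints `"-"`.
#'
#' @param v a `Verdict`.
#' @param name_a,name_b display names of the two assemblies.
#' @return character string.
#' @export
format_verdict <- function(v, name_a = "A", name_b = "B") {
  name <- switch(v$supported,
                 "hypothesis-A" = name_a,
                 "hypothesis-B" = name_b,
                 "both-consistent" = paste0(name_a, "=", name_b),
                 "neither" = "-")
  if (identical(v$modality, "interphase") &&
      v$supported %in% c("hypothesis-A", "hypothesis-B"))
    sprintf("%s (%.0f%%)", name, 100 * v$support_fraction)
  else name
}

#' @export
print.Verdict <- function(x, ...) {
  cat(sprintf("Verdict: %s (support %.0f%%, n = %s, %s)\n", x$supported,
              100 * x$support_fraction,
              if (is.na(x$n_cells)) "-" else x$n_cells, x$modality))
  invisible(x)
}
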