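#' draftcompare: comparison and disambiguation of alternate genome assemblies
#'
#' Compares two alternate assemblies of the same genome, classifies their
#' structural discordances (inversions, segments mapped in distinct
#' positions, one-draft-only sequences, discordant chromosome assignments),
#' places unassigned scaffolds, designs BAC probe panels and junction
#' long-PCR assays, and decides between the assemblies with simulated
#' metaphase/interphase FISH and in silico PCR.
#'
#' @useDynLib draftcompare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom median setNames aggregate
#' @importFrom utils write.table read.table head tail
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Assembly container
# ---------------------------------------------------------------------------

#' Create an assembly object
#'
#' An assembly is a named set of nucleotide sequences partitioned into
#' chromosomes and unassigned scaffolds. Sequences are plain character
#' strings over `A,C,G,T,N` with lowercase letters marking soft-masked
#' (repeat) bases; case is preserved throughout the package because the
#' masking state drives the anchor-seeding policy and the gap/repeat filter.
#'
#' @param name assembly label (e.g. `"A"`, `"B"`, `"truth"`).
#' @param seq named character vector of sequences.
#' @param role character vector parallel to `seq`, each `"chromosome"` or
#'   `"scaffold"`. Defaults to `"chromosome"` for ids starting with `"chr"`
#'   and `"scaffold"` otherwise.
#' @return an object of class `Assembly`.
#' @export
Assembly <- function(name, seq, role = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.character(seq))
  ids <- names(seq)
  if (is.null(ids) || anyDuplicated(ids) || any(ids == ""))
    stop("sequences must have unique non-empty names")
  bad <- grepl("[^ACGTNacgtn]", seq)
  if (any(bad))
    stop("non-nucleotide characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  if (is.null(role))
    role <- ifelse(grepl("^chr", ids), "chromosome", "scaffold")
  if (is.null(names(role))) names(role) <- ids
  role <- role[ids]
  if (!all(role %in% c("chromosome", "scaffold")))
    stop("role must be 'chromosome' or 'scaffold'")
  structure(list(name = name, seq = seq, role = role), class = "Assembly")
}

#' @export
print.Assembly <- function(x, ...) {
  cat(sprintf("Assembly '%s': %d chromosome(s), %d scaffold(s), %.2f Mbp\n",
              x$name, sum(x$role == "chromosome"), sum(x$role == "scaffold"),
              sum(nchar(x$seq)) / 1e6))
  invisible(x)
}

#' Sequence lengths of an assembly
#' @param asm an `Assembly`.
#' @return named integer vector of sequence lengths.
#' @export
seq_lengths <- function(asm) {
  stopifnot(inherits(asm, "Assembly"))
  setNames(nchar(asm$seq), names(asm$seq))
}

#' Chromosome ids of an assembly
#' @param asm an `Assembly`.
#' @return character vector of chromosome sequence ids.
#' @export
chromosomes <- function(asm) names(asm$seq)[asm$role == "chromosome"]

#' Unassigned scaffold ids of an assembly
#' @param asm an `Assembly`.
#' @return character vector of scaffold sequence ids.
#' @export
scaffolds <- function(asm) names(asm$seq)[asm$role == "scaffold"]

# ---------------------------------------------------------------------------
# Intervals
#
# Coordinates are 0-based half-open internally; all emitted reports are
# 1-based inclusive (see `to_report_coords()`), matching the positions the
# field's genome browsers print.
# ---------------------------------------------------------------------------

#' Construct an interval
#'
#' @param seq_id sequence id.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return a one-row data.frame with columns `seq_id,start,end,strand`.
#' @export
interval <- function(seq_id, start, end, strand = "+") {
  stopifnot(start >= 0, start < end, strand %in% c("+", "-"))
  data.frame(seq_id = seq_id, start = as.numeric(start),
             end = as.numeric(end), strand = strand,
             stringsAsFactors = FALSE)
}

check_interval <- function(iv, asm) {
  len <- seq_lengths(asm)
  if (!iv$seq_id %in% names(len))
    stop("unknown sequence id: ", iv$seq_id)
  if (iv$start < 0 || iv$end > len[[iv$seq_id]] || iv$start >= iv$end)
    stop(sprintf("interval out of bounds: %s:%d-%d (length %d)",
                 iv$seq_id, iv$start, iv$end, len[[iv$seq_id]]))
  invisible(TRUE)
}

#' Convert internal 0-based half-open starts/ends to 1-based inclusive
#'
#' @param df data.frame with `*start`/`*end` coordinate columns.
#' @param start_cols,end_cols names of the start and end columns to convert.
#' @return `df` with converted coordinates (start + 1; end unchanged, which
#'   is the inclusive end in 1-based coordinates).
#' @export
to_report_coords <- function(df, start_cols = grep("start", names(df), value = TRUE),
                             end_cols = grep("end", names(df), value = TRUE)) {
  for (cc in start_cols) df[[cc]] <- df[[cc]] + 1
  df
}

#' Convert 1-based inclusive starts back to internal 0-based half-open
#' @param df data.frame with report coordinates.
#' @param start_cols names of the start columns to convert.
#' @return `df` in internal coordinates.
#' @export
from_report_coords <- function(df, start_cols = grep("start", names(df), value = TRUE)) {
  for (cc in start_cols) df[[cc]] <- df[[cc]] - 1
  df
}

# ---------------------------------------------------------------------------
# Thresholds
# ---------------------------------------------------------------------------

#' Numeric thresholds used across the pipeline
#'
#' Houses every size constant of the comparison/testing procedure, all in bp
#' unless noted:
#' * `report_min` (100 kbp): discordances at or below this size are recorded
#'   as sub-threshold, strictly larger ones are reportable.
#' * `test_min_mdp_dcm` (200 kbp): MDP and DCM discordances must exceed this
#'   to be eligible for experimental testing (BAC clones are 50-300 kb, so
#'   smaller targets cannot be resolved).
#' * `test_min_inv` (500 kbp): inversions must exceed this to be testable,
#'   because the disambiguating design needs three distinct non-overlapping
#'   BACs (one inside, two outside near opposite borders).
#' * `bes_span_min`/`bes_span_max` (50/300 kb): plausible BAC insert span
#'   implied by its two end sequences.
#' * `fish_visibility_min` (5 kbp): minimal contiguous homology a FISH probe
#'   needs at a locus to produce a visible signal (conservative end of the
#'   5-10 kbp range).
#' * `metaphase_cells` (10) / `interphase_nuclei` (50): signal counts
#'   inspected per experiment.
#' * `masked_frac_max` (0.75): a discordance whose defining locus exceeds
#'   this masked (lowercase + N) fraction is excluded as "almost completely
#'   gaps and/or repeats".
#' * `pcr_amplicon_max` (12 kbp): largest amplicon considered reachable by
#'   long-PCR.
#'
#' @param report_min,test_min_mdp_dcm,test_min_inv,bes_span_min,bes_span_max,fish_visibility_min,metaphase_cells,interphase_nuclei,masked_frac_max,pcr_amplicon_max see description.
#' @return an object of class `Thresholds` (a validated named list).
#' @export
thresholds <- function(report_min = 100000, test_min_mdp_dcm = 200000,
                       test_min_inv = 500000, bes_span_min = 50000,
                       bes_span_max = 300000, fish_visibility_min = 5000,
                       metaphase_cells = 10, interphase_nuclei = 50,
                       masked_frac_max = 0.75, pcr_amplicon_max = 12000) {
  th <- list(report_min = report_min, test_min_mdp_dcm = test_min_mdp_dcm,
             test_min_inv = test_min_inv, bes_span_min = bes_span_min,
             bes_span_max = bes_span_max,
             fish_visibility_min = fish_visibility_min,
             metaphase_cells = metaphase_cells,
             interphase_nuclei = interphase_nuclei,
             masked_frac_max = masked_frac_max,
             pcr_amplicon_max = pcr_amplicon_max)
  if (any(unlist(th) <= 0))
    stop("all thresholds must be positive")
  if (th$bes_span_min >= th$bes_span_max)
    stop("bes_span_min must be < bes_span_max")
  if (!(th$report_min <= th$test_min_mdp_dcm &&
        th$test_min_mdp_dcm <= th$test_min_inv))
    stop("need report_min <= test_min_mdp_dcm <= test_min_inv")
  structure(th, class = "Thresholds")
}

#' Read thresholds from a flat key=value config file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Unknown keys are an error; missing keys keep their defaults.
#'
#' @param path file path.
#' @return a `Thresholds` object.
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    if (!key %in% names(formals(thresholds)))
      stop("unknown threshold key: ", key)
    args[[key]] <- as.numeric(trimws(kv[2]))
  }
  do.call(thresholds, args)
}

# ---------------------------------------------------------------------------
# Sequence primitives
# ---------------------------------------------------------------------------

#' Case-preserving reverse complement
#'
#' Complements `A<->T`, `C<->G` (and their lowercase forms), leaves `N`/`n`,
#' and reverses. The soft-masking case of every base is preserved, so the
#' masked fraction of a segment is invariant under reverse complement.
#'
#' @param s nucleotide string.
#' @return the reverse complement of `s`.
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  cpp_revcomp(s)
}

#' Masked fraction of an interval
#'
#' Fraction of bases in the interval that are soft-masked (lowercase) or
#' ambiguous (`N`/`n`). Gaps and repeats are lumped together because both
#' disqualify a locus from experimental follow-up.
#'
#' @param iv an [interval()] on `asm`.
#' @param asm an `Assembly`.
#' @return fraction in `[0, 1]`.
#' @export
masked_fraction <- function(iv, asm) {
  check_interval(iv, asm)
  s <- asm$seq[[iv$seq_id]]
  cpp_masked_count(s, as.integer(iv$start), as.integer(iv$end)) /
    (iv$end - iv$start)
}

#' Extract the sequence of an interval (forward strand)
#' @param iv an [interval()].
#' @param asm an `Assembly`.
#' @return character string; reverse-complemented when `iv$strand == "-"`.
#' @export
extract_seq <- function(iv, asm) {
  check_interval(iv, asm)
  s <- substr(asm$seq[[iv$seq_id]], iv$start + 1, iv$end)
  if (iv$strand == "-") s <- reverse_complement(s)
  s
}

# ---------------------------------------------------------------------------
# FASTA I/O (case-preserving, via Biostrings BStringSet)
# ---------------------------------------------------------------------------

#' Read an assembly from a soft-masked FASTA file
#'
#' @param path FASTA file.
#' @param name assembly label (defaults to the file base name).
#' @param role optional named role vector; by default ids starting with
#'   `"chr"` are chromosomes, everything else a scaffold.
#' @return an `Assembly`.
#' @export
read_assembly_fasta <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                                role = NULL) {
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  seq <- setNames(as.character(ss), sub("\\s.*", "", names(ss)))
  Assembly(name, seq, role)
}

#' Write an assembly to FASTA (preserving soft-mask case)
#' @param asm an `Assembly`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(asm, path) {
  ss <- Biostrings::BStringSet(asm$seq)
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Internal helpers
# ---------------------------------------------------------------------------

# Evaluate expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable TSV writer: fixed column order, no quoting, no scientific notation
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (cc in names(df)[num])
    df[[cc]] <- format(df[[cc]], scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
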