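# End-to-end orchestration: compare two assemblies, design probes, and
# (when the true genome is available, i.e. on synthetic bundles) simulate
# the FISH/PCR experiments and produce the disambiguation table.

#' Build a run configuration
#'
#' Inputs may be `Assembly`/`BESLibrary` objects or file paths (FASTA /
#' BES TSV+FASTA written by [run_simulate()]); paths must exist at
#' configuration time.
#'
#' @param assembly_a,assembly_b the two assemblies (objects or FASTA paths).
#' @param bes optional BES library (object or TSV path with the end FASTA
#'   next to it).
#' @param truth optional true genome for simulated experiments.
#' @param out_dir optional output directory for the report bundle.
#' @param th a [thresholds()] object.
#' @param min_anchor,max_gap,max_drift anchor/chaining parameters (bp).
#' @param disorder_p,p_drop FISH noise parameters.
#' @param seed integer seed for every stochastic stage.
#' @return a `RunConfig` list.
#' @export
run_config <- function(assembly_a, assembly_b, bes = NULL, truth = NULL,
                       out_dir = NULL, th = thresholds(), min_anchor = 50,
                       max_gap = 50000, max_drift = 20000, disorder_p = 0.15,
                       p_drop = 0.05, seed = 1) {
  load_asm <- function(x, name) {
    if (inherits(x, "Assembly")) return(x)
    if (!file.exists(x)) stop("input path does not exist: ", x)
    read_assembly_fasta(x, name = name)
  }
  cfg <- list(
    asm_a = load_asm(assembly_a, "A"),
    asm_b = load_asm(assembly_b, "B"),
    truth = if (is.null(truth)) NULL else load_asm(truth, "truth"),
    bes = if (is.null(bes) || is.data.frame(bes)) bes else read_bes_tsv(bes),
    out_dir = out_dir, th = th, min_anchor = min_anchor, max_gap = max_gap,
    max_drift = max_drift, disorder_p = disorder_p, p_drop = p_drop,
    seed = seed)
  class(cfg) <- "RunConfig"
  cfg
}

read_bes_tsv <- function(tsv) {
  fasta <- sub("\\.tsv$", ".fa", tsv)
  if (!file.exists(fasta)) stop("BES end FASTA not found next to ", tsv)
  tab <- read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tab <- from_report_coords(tab, start_cols = "start")
  ends <- Biostrings::readBStringSet(fasta)
  ends <- setNames(as.character(ends), names(ends))
  tab$end1 <- unname(ends[paste0(tab$clone_id, ".1")])
  tab$end2 <- unname(ends[paste0(tab$clone_id, ".2")])
  class(tab) <- c("BESLibrary", "data.frame")
  tab
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[draftcompare] ", fmt), ...))
}

#' Run the full assembly comparison
#'
#' Stages: chromosome pairing by name, anchoring and chaining per pair,
#' discordance classification, ODS pairing into DCMs, gap/repeat
#' exclusion, scaffold placement and ODS/scaffold cross-linking, BES
#' mapping and probe/assay design for every test-eligible discordance,
#' and - when a true genome is configured - simulated FISH/PCR with the
#' final supported-assembly table. Deterministic given the seed.
#'
#' @param config a `RunConfig` from [run_config()].
#' @param verbose log stage progress and the parameters used.
#' @return a `CompareResult` list: `blocks`, `discordances` (with
#'   gap/repeat flags), `kept`, `excluded`, `scaffold_placements`,
#'   `ods_crosslinks`, `placements_a/b`, `plans`, `assays`,
#'   `reference_panel`, `fish`, `summary`, `category_counts`, `config`.
#' @export
run_compare <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  asm_a <- config$asm_a; asm_b <- config$asm_b
  th <- config$th
  stage_log(verbose,
            "compare: min_anchor=%d max_gap=%d max_drift=%d seed=%d",
            config$min_anchor, config$max_gap, config$max_drift, config$seed)
  chr_a <- chromosomes(asm_a); chr_b <- chromosomes(asm_b)
  unpaired <- c(setdiff(chr_a, chr_b), setdiff(chr_b, chr_a))
  if (length(unpaired))
    stop("pairing error: chromosome names not present in both assemblies: ",
         paste(unpaired, collapse = ", "))

  blocks <- NULL
  for (ch in chr_a) {
    an <- find_anchors(asm_a$seq[[ch]], asm_b$seq[[ch]], config$min_anchor,
                       a_id = ch, b_id = ch)
    bl <- chain_anchors(an, config$max_gap, config$max_drift)
    blocks <- rbind(blocks, bl)
  }
  if (is.null(blocks)) blocks <- chain_anchors(empty_anchor_df())
  stage_log(verbose, "anchored %d chromosome pair(s): %d block(s)",
            length(chr_a), nrow(blocks))

  disc <- classify_discordances(blocks, asm_a, asm_b, th)
  disc <- pair_odss(disc, asm_a, asm_b, th, config$min_anchor)
  fl <- filter_gap_repeat(disc, asm_a, asm_b, th)
  kept <- fl$kept
  stage_log(verbose, "classified %d discordance(s) (%d excluded as gap/repeat)",
            nrow(disc), nrow(fl$excluded))

  scaffold_placements <- c(
    place_all_scaffolds(asm_a, asm_b, min_anchor = config$min_anchor,
                        th = th, max_gap = config$max_gap,
                        max_drift = config$max_drift),
    place_all_scaffolds(asm_b, asm_a, min_anchor = config$min_anchor,
                        th = th, max_gap = config$max_gap,
                        max_drift = config$max_drift))
  crosslinks <- crosslink_ods_chrun(kept, asm_a, asm_b, config$min_anchor)

  placements_a <- placements_b <- NULL
  plans <- list()
  assays <- NULL
  panel <- NULL
  if (!is.null(config$bes)) {
    placements_a <- map_bes_library(config$bes, asm_a)
    placements_b <- map_bes_library(config$bes, asm_b)
    stage_log(verbose, "mapped %d BES clone(s) on both assemblies",
              nrow(config$bes))
    panel <- build_reference_panel(blocks, placements_a, asm_a, th)
    test_rows <- kept[kept$eligibility == "test-eligible" &
                      kept$category %in% c("INV", "MDP", "DCM"), ,
                      drop = FALSE]
    for (i in seq_len(nrow(test_rows))) {
      d <- test_rows[i, ]
      if (d$category == "INV") {
        plans[[d$code]] <- plan_inversion_test(d, placements_a, th,
                                               placements_other = placements_b)
      } else if (d$category == "DCM") {
        pl <- if (identical(d$dup_in, "A")) placements_b else placements_a
        plans[[d$code]] <- plan_dcm_test(d, pl, th)
      } else if (d$category == "MDP") {
        dist <- if (!is.na(d$displacement)) d$displacement
                else abs((d$a_start + d$a_end) / 2 -
                         (d$b_start + d$b_end) / 2)
        if (dist < 1e6) {
          assays <- rbind(assays, design_junction_pcr(d, asm_a, asm_b, th))
        } else {
          plans[[d$code]] <- plan_mdp_interphase(d, placements_a, th,
                                                 placements_other = placements_b)
        }
      }
    }
    stage_log(verbose, "planned %d FISH target(s), %d PCR assay pair(s)",
              length(plans), if (is.null(assays)) 0 else nrow(assays) / 2)
  }

  fish <- NULL
  if (!is.null(config$truth)) {
    fish <- simulate_experiments(kept, plans, assays, config, placements_b,
                                 verbose)
  }

  counts <- table(factor(kept$category[kept$eligibility != "sub-threshold"],
                         levels = c("INV", "MDP", "ODS", "DCM")))
  summary_df <- if (!is.null(fish)) fish$table else NULL
  res <- list(blocks = blocks, discordances = disc, kept = kept,
              excluded = fl$excluded,
              scaffold_placements = scaffold_placements,
              ods_crosslinks = crosslinks, placements_a = placements_a,
              placements_b = placements_b, plans = plans, assays = assays,
              reference_panel = panel, fish = fish, summary = summary_df,
              category_counts = counts, config = config)
  class(res) <- "CompareResult"
  if (!is.null(config$out_dir)) write_report_bundle(res, config$out_dir)
  res
}

# interphase plan for an MDP whose two candidate positions are >= 1 Mbp
# apart: probe on the segment plus two flanks bracketing the positions hull
plan_mdp_interphase <- function(mdp, placements, th = thresholds(),
                                flank_max = 1e6, placements_other = NULL) {
  hull <- c(min(mdp$a_start, mdp$b_start), max(mdp$a_end, mdp$b_end))
  region <- interval(mdp$a_seq, mdp$a_start, mdp$a_end)
  inside <- select_probes_for_region(region, placements, th)
  p <- placements[placements$usable & !is.na(placements$span) &
                  placements$span >= th$bes_span_min &
                  placements$span <= th$bes_span_max &
                  placements$e1_seq == mdp$a_seq, , drop = FALSE]
  p <- p[p$clone_id %in% concordant_clones(p, placements_other, mdp$a_seq), ,
         drop = FALSE]
  left <- p[p$insert_end <= hull[1] & p$insert_start >= hull[1] - flank_max, ,
            drop = FALSE]
  left <- left[order(-left$insert_end), , drop = FALSE]
  right <- p[p$insert_start >= hull[2] & p$insert_end <= hull[2] + flank_max, ,
             drop = FALSE]
  right <- right[order(right$insert_start), , drop = FALSE]
  feasible <- nrow(inside) > 0 && nrow(left) > 0 && nrow(right) > 0
  probes <- if (feasible)
    data.frame(role = c("flank-left", "inside", "flank-right"),
               clone_id = c(left$clone_id[1], inside$clone_id[1],
                            right$clone_id[1]),
               seq_id = mdp$a_seq,
               insert_start = c(left$insert_start[1], inside$insert_start[1],
                                right$insert_start[1]),
               insert_end = c(left$insert_end[1], inside$insert_end[1],
                              right$insert_end[1]), stringsAsFactors = FALSE)
  else data.frame()
  structure(list(target = mdp$code, assay = "FISH-interphase",
                 feasible = feasible, probes = probes), class = "ProbePlan")
}

# run the simulated experiments for every planned target
simulate_experiments <- function(kept, plans, assays, config, placements_b,
                                 verbose = TRUE) {
  truth <- config$truth
  th <- config$th
  bes <- config$bes
  verdicts <- list()
  rows <- NULL
  seed_i <- config$seed

  clone_row <- function(id) bes[bes$clone_id == id, , drop = FALSE]
  probe_seq_of <- function(id) {
    cr <- clone_row(id)
    substr(truth$seq[[cr$chrom]], cr$start + 1, cr$end)
  }

  for (code in names(plans)) {
    pl <- plans[[code]]
    seed_i <- seed_i + 1
    if (!pl$feasible) {
      rows <- rbind(rows, data.frame(code = code, test = pl$assay,
                                     supported = "infeasible",
                                     stringsAsFactors = FALSE))
      next
    }
    if (pl$assay == "FISH-interphase") {
      pos_a <- setNames((pl$probes$insert_start + pl$probes$insert_end) / 2,
                        pl$probes$clone_id)
      pb <- placements_b[match(pl$probes$clone_id, placements_b$clone_id), ]
      pos_b <- setNames((pb$insert_start + pb$insert_end) / 2,
                        pl$probes$clone_id)
      pos_true <- vapply(pl$probes$clone_id, function(cid) {
        cr <- clone_row(cid)
        (cr$start + cr$end) / 2
      }, numeric(1))
      names(pos_true) <- pl$probes$clone_id
      if (anyNA(pos_b)) {
        rows <- rbind(rows, data.frame(code = code, test = "FISH/int",
                                       supported = "infeasible",
                                       stringsAsFactors = FALSE))
        next
      }
      counts <- simulate_interphase_triplet(pos_true,
                                            n_nuclei = th$interphase_nuclei,
                                            disorder_p = config$disorder_p,
                                            seed = seed_i)
      v <- decide(counts, triplet_pattern(pos_a), triplet_pattern(pos_b),
                  modality = "interphase")
    } else {  # FISH-metaphase
      cid <- pl$probes$clone_id[1]
      pseq <- probe_seq_of(cid)
      probes <- data.frame(probe_id = cid, seq = pseq,
                           stringsAsFactors = FALSE)
      obs <- simulate_metaphase(probes, truth, n_cells = th$metaphase_cells,
                                th = th, p_drop = config$p_drop,
                                seed = seed_i)
      hyp <- function(asm) {
        loci <- probe_loci(pseq, asm, th)
        loci <- loci[asm$role[loci$chrom] == "chromosome", , drop = FALSE]
        setNames(list(loci$chrom), cid)
      }
      v <- decide(obs, hyp(config$asm_a), hyp(config$asm_b),
                  modality = "metaphase")
    }
    verdicts[[code]] <- v
    rows <- rbind(rows, data.frame(
      code = code,
      test = if (pl$assay == "FISH-interphase") "FISH/int" else "FISH/met",
      supported = format_verdict(v, config$asm_a$name, config$asm_b$name),
      stringsAsFactors = FALSE))
  }

  for (code in unique(if (is.null(assays)) character(0) else assays$target)) {
    asy <- assays[assays$target == code, , drop = FALSE]
    v <- pcr_verdict(asy, truth, th)
    verdicts[[code]] <- v
    rows <- rbind(rows, data.frame(
      code = code, test = "PCR",
      supported = format_verdict(v, config$asm_a$name, config$asm_b$name),
      stringsAsFactors = FALSE))
  }
  stage_log(verbose, "simulated %d experiment(s)", length(verdicts))
  list(verdicts = verdicts, table = rows)
}

#' @export
print.CompareResult <- function(x, ...) {
  cat("CompareResult\n")
  cat("  reportable discordances:",
      paste(names(x$category_counts), as.integer(x$category_counts),
            sep = "=", collapse = " "), "\n")
  if (!is.null(x$summary) && nrow(x$summary)) {
    cat("  disambiguation table:\n")
    print(x$summary, row.names = FALSE)
  }
  invisible(x)
}

#' Write the report bundle of a comparison
#'
#' Emits `blocks.tsv`, `discordances.tsv` (all rows, gap/repeat flag set),
#' `placements.tsv`, `ods_chrun.tsv`, `probes.tsv`, `assays.tsv`,
#' `reference_panel.tsv`, `fish_results.tsv` and `summary.txt` into
#' `out_dir`. All coordinates 1-based inclusive; byte-identical for the
#' same configuration and seed.
#'
#' @param res a `CompareResult`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_anchor_tsv(res$blocks, fp("blocks.tsv"))
  write_discordances(res$discordances, fp("discordances.tsv"))
  write_placements(res$scaffold_placements, fp("placements.tsv"))
  write_tsv(res$ods_crosslinks, fp("ods_chrun.tsv"))
  write_probes(res$plans, fp("probes.tsv"))
  if (!is.null(res$assays))
    write_tsv(to_report_coords(res$assays, start_cols = "fwd_start"),
              fp("assays.tsv"))
  if (!is.null(res$reference_panel))
    write_tsv(to_report_coords(res$reference_panel,
                               start_cols = "insert_start"),
              fp("reference_panel.tsv"))
  if (!is.null(res$fish) && !is.null(res$fish$table))
    write_tsv(res$fish$table, fp("fish_results.tsv"))
  con <- file(fp("summary.txt"), "w")
  on.exit(close(con))
  writeLines(c("draftcompare run summary",
               sprintf("seed: %d", res$config$seed),
               sprintf("thresholds: %s",
                       paste(names(res$config$th), unlist(res$config$th),
                             sep = "=", collapse = " ")),
               sprintf("reportable: %s",
                       paste(names(res$category_counts),
                             as.integer(res$category_counts), sep = "=",
                             collapse = " "))), con)
  if (!is.null(res$fish) && !is.null(res$fish$table) &&
      nrow(res$fish$table)) {
    writeLines("", con)
    writeLines("code\ttest\tsupported", con)
    writeLines(sprintf("%s\t%s\t%s", res$fish$table$code,
                       res$fish$table$test, res$fish$table$supported), con)
  }
  invisible(out_dir)
}

#' Generate and write a synthetic bundle
#'
#' Front end to the synthetic-data generator: writes `true.fa`,
#' `assemblyA.fa`, `assemblyB.fa`, `truth.tsv` (one row per planted
#' event), `bes.tsv` and `bes.fa` into `out_dir` and prints the event
#' manifest.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param ... passed to [simulate_bundle()].
#' @param verbose print the event manifest.
#' @return the bundle list from [simulate_bundle()], invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1, ..., verbose = TRUE) {
  bundle <- simulate_bundle(seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_assembly_fasta(bundle$true, file.path(out_dir, "true.fa"))
  write_assembly_fasta(bundle$a, file.path(out_dir, "assemblyA.fa"))
  write_assembly_fasta(bundle$b, file.path(out_dir, "assemblyB.fa"))
  write_tsv(to_report_coords(bundle$truth,
                             start_cols = c("start", "a_start", "b_start")),
            file.path(out_dir, "truth.tsv"))
  write_bes_library(bundle$bes, tsv = file.path(out_dir, "bes.tsv"),
                    fasta = file.path(out_dir, "bes.fa"))
  if (verbose) {
    stage_log(TRUE, "simulated bundle: %d event(s), %d clone(s), seed=%d",
              nrow(bundle$truth), nrow(bundle$bes), seed)
    for (i in seq_len(nrow(bundle$truth)))
      stage_log(TRUE, "  event %d: %s on %s %s:%d-%d",
                bundle$truth$event_id[i], bundle$truth$kind[i],
                bundle$truth$applies_to[i], bundle$truth$chrom[i],
                bundle$truth$start[i], bundle$truth$end[i])
  }
  invisible(bundle)
}
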