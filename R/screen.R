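#' Configure the KZFP/PBS screen
#'
#' Collects inputs and thresholds for [run_screen()]. Every sequence/table
#' argument accepts either an in-memory object (the formats produced by the
#' readers and the simulator) or a file path.
#'
#' @param trnas named tRNA sequences, a FASTA path, or `NULL` to use the
#'   bundled catalog.
#' @param genome target genome: named DNA character vector or FASTA path.
#'   Either `genome` or `pbs_hits` must be given.
#' @param pbs_hits precomputed PBS annotations (data.frame from
#'   [scan_pbs()] or a BED path) used instead of scanning.
#' @param proteins KZFP protein sequences (named vector or FASTA path).
#' @param peaks named list of peak data.frames (or BED paths), one entry
#'   per KZFP with ChIP data; KZFPs absent from this list go to arm B.
#' @param ltr_ends optional 0-based 5'-LTR end coordinates for the PBS
#'   score bonus.
#' @param ltr_pairs LTR pairs for the invasion profile (see
#'   [date_ltr_pairs()]), or `NULL` when `erv_ages` is given.
#' @param erv_ages precomputed ERV insertion ages (Myr) for the invasion
#'   profile.
#' @param orthologs ortholog table (list or TSV path) for arm B ages.
#' @param divergence_times divergence times (data.frame, named vector or
#'   TSV path).
#' @param reference reference species (default `"human"`).
#' @param reference_binders named protein sequences of known PBS binders
#'   for the fingerprint-similarity report (may be empty).
#' @param pbs_type PBS type targeted by the screen (default `"Pro"`).
#' @param pbs_min_score keep PBS annotations with score strictly greater
#'   (default 100).
#' @param strong_peak strong-peak score threshold (default 500).
#' @param fingerprint_sim_max fingerprint similarity (%) below which a
#'   candidate is called dissimilar to the reference binders (default 50).
#' @param motif_match_min minimum predicted-motif/PBS match fraction for
#'   arm B candidates (default 0.7).
#' @param cooccur_tolerance co-occurrence tolerance in Myr (default 10).
#' @param max_mismatch PBS scan mismatch ceiling (default 3).
#' @param seed recorded in the report for provenance (the screen itself is
#'   deterministic).
#' @return Object of class `"screen_config"`.
#' @export
screen_config <- function(trnas = NULL, genome = NULL, pbs_hits = NULL,
                          proteins = NULL, peaks = NULL, ltr_ends = NULL,
                          ltr_pairs = NULL, erv_ages = NULL,
                          orthologs = NULL, divergence_times = NULL,
                          reference = "human", reference_binders = NULL,
                          pbs_type = "Pro", pbs_min_score = 100,
                          strong_peak = 500, fingerprint_sim_max = 50,
                          motif_match_min = 0.7, cooccur_tolerance = 10,
                          max_mismatch = 3L, seed = 1L) {
  if (is.null(genome) && is.null(pbs_hits))
    stop("provide a genome to scan or precomputed pbs_hits")
  if (is.null(proteins) && is.null(peaks))
    stop("provide protein sequences and/or peak sets")
  structure(as.list(environment()), class = "screen_config")
}

load_if_path <- function(x, loader) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) loader(x) else x
}

#' Run the two-arm KZFP/PBS screen
#'
#' Stage 1 annotates high-confidence PBS loci (scan or load, then filter at
#' `score > pbs_min_score`). KZFPs with ChIP peak sets form arm A: strong
#' peaks are kept, overlaps with the PBS loci counted, and the panel ranked
#' by overlap count. The remaining KZFPs form arm B: ortholog-based ages
#' are screened for co-occurrence with the ERV invasion peak, each
#' surviving candidate's recognition-code motif is compared against the
#' target PBS (kept at a match fraction of at least `motif_match_min`,
#' on either strand), and fingerprint similarity to the declared reference
#' binders is reported alongside (similarity below `fingerprint_sim_max`
#' flagged dissimilar). The report is deterministic given the inputs.
#'
#' @param config a [screen_config()].
#' @return Object of class `"screen_report"`: list with `pbs` (filtered
#'   annotations), `arm_a` (ranking), `arm_b` (candidate table),
#'   `arm_assignment`, `invasion` (profile or `NULL`), `thresholds`,
#'   `log` (per-step counts), `no_targets` flag.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  log <- list()
  catalog <- if (is.null(config$trnas)) default_pbs_catalog() else
    pbs_catalog(load_if_path(config$trnas,
                             function(p) read_fasta(p, "dna")))

  # --- stage 1: PBS annotation -------------------------------------------
  hits <- if (!is.null(config$pbs_hits)) {
    h <- load_if_path(config$pbs_hits, read_bed)
    if (!"type" %in% names(h) && "name" %in% names(h)) {
      h$type <- h$name
      names(h)[names(h) == "chrom"] <- "seqname"
    }
    h
  } else {
    genome <- load_if_path(config$genome, function(p) read_fasta(p, "dna"))
    scan_pbs(genome, catalog, max_mismatch = config$max_mismatch,
             ltr_ends = config$ltr_ends)
  }
  log$pbs_scanned <- nrow(hits)
  pbs <- hits[hits$score > config$pbs_min_score &
                hits$type == config$pbs_type, , drop = FALSE]
  log$pbs_kept <- nrow(pbs)
  if (nrow(pbs) == 0L) {
    return(structure(list(pbs = pbs, arm_a = NULL, arm_b = NULL,
                          arm_assignment = NULL, invasion = NULL,
                          thresholds = screen_thresholds(config), log = log,
                          no_targets = TRUE), class = "screen_report"))
  }

  proteins <- if (!is.null(config$proteins))
    load_if_path(config$proteins, function(p) read_fasta(p, "protein"))
  peak_sets <- config$peaks
  if (!is.null(peak_sets))
    peak_sets <- lapply(peak_sets, load_if_path, loader = read_bed)
  all_kzfps <- union(names(proteins), names(peak_sets))
  arm <- ifelse(all_kzfps %in% names(peak_sets), "A", "B")
  names(arm) <- all_kzfps

  # --- arm A: ChIP overlap ranking ---------------------------------------
  arm_a <- NULL
  if (length(peak_sets)) {
    reports <- do.call(rbind, lapply(names(peak_sets), function(id) {
      strong <- filter_peaks(peak_sets[[id]], config$strong_peak)
      count_overlaps_report(strong, pbs, kzfp = id)
    }))
    log$arm_a_strong_peaks <- sum(reports$n_peaks)
    arm_a <- rank_binders(reports)
  }

  # --- arm B: age co-occurrence + motif prediction -----------------------
  arm_b <- NULL
  invasion <- NULL
  arm_b_ids <- names(arm)[arm == "B"]
  if (length(arm_b_ids) && !is.null(proteins)) {
    ages_available <- !is.null(config$orthologs) &&
      !is.null(config$divergence_times)
    erv_ages <- config$erv_ages
    if (is.null(erv_ages) && !is.null(config$ltr_pairs))
      erv_ages <- date_ltr_pairs(config$ltr_pairs)$age
    if (!is.null(erv_ages)) invasion <- invasion_profile(erv_ages)
    cand_ids <- arm_b_ids
    ages <- NULL
    if (ages_available && !is.null(invasion)) {
      table <- load_if_path(config$orthologs, read_ortholog_table)
      times <- load_if_path(config$divergence_times, read_divergence_times)
      table <- table[intersect(names(table), arm_b_ids)]
      ages <- estimate_ages(table, times, reference = config$reference)
      cand <- cooccurrence_screen(ages, invasion,
                                  tolerance = config$cooccur_tolerance)
      cand_ids <- cand$gene
      log$arm_b_cooccurring <- length(cand_ids)
    }
    ref_arrays <- NULL
    if (!is.null(config$reference_binders)) {
      refs <- load_if_path(config$reference_binders,
                           function(p) read_fasta(p, "protein"))
      ref_arrays <- lapply(names(refs), function(id)
        find_c2h2(refs[[id]], id))
      names(ref_arrays) <- names(refs)
    }
    target_pbs <- catalog[[config$pbs_type]]
    rows <- lapply(cand_ids, function(id) {
      zfa <- find_c2h2(proteins[[id]], id)
      if (!nrow(zfa$fingers)) return(NULL)
      pm <- suppressWarnings(predict_motif(zfa))
      mv <- motif_vs_pbs(pm, target_pbs)
      fp_sim <- if (length(ref_arrays))
        max(vapply(ref_arrays, function(r)
          fingerprint_similarity(zfa, r), 0)) else NA_real_
      data.frame(gene = id,
                 age = if (!is.null(ages))
                   ages$age[match(id, ages$gene)] else NA_real_,
                 n_fingers = nrow(zfa$fingers),
                 motif = pm$consensus,
                 motif_match = mv$fraction,
                 motif_strand = if (is.na(mv$strand)) "." else mv$strand,
                 fingerprint_similarity = fp_sim,
                 dissimilar_to_refs = if (is.na(fp_sim)) NA else
                   fp_sim < config$fingerprint_sim_max,
                 stringsAsFactors = FALSE)
    })
    arm_b <- do.call(rbind, rows)
    if (!is.null(arm_b)) {
      arm_b <- arm_b[arm_b$motif_match >= config$motif_match_min, ,
                     drop = FALSE]
      arm_b <- arm_b[order(-arm_b$motif_match, arm_b$gene), , drop = FALSE]
      rownames(arm_b) <- NULL
    }
    log$arm_b_candidates <- if (is.null(arm_b)) 0L else nrow(arm_b)
  }

  structure(list(pbs = pbs, arm_a = arm_a, arm_b = arm_b,
                 arm_assignment = arm, invasion = invasion,
                 thresholds = screen_thresholds(config), log = log,
                 no_targets = FALSE),
            class = "screen_report")
}

screen_thresholds <- function(config) {
  config[c("pbs_min_score", "strong_peak", "fingerprint_sim_max",
           "motif_match_min", "cooccur_tolerance", "max_mismatch",
           "pbs_type", "seed")]
}

#' @export
print.screen_report <- function(x, ...) {
  cat("KZFP/PBS screen report\n")
  cat(sprintf("  PBS-%s loci kept: %d (score > %g)\n", x$thresholds$pbs_type,
              nrow(x$pbs), x$thresholds$pbs_min_score))
  if (isTRUE(x$no_targets)) {
    cat("  no PBS targets after filtering; screen not run\n")
    return(invisible(x))
  }
  if (!is.null(x$arm_a)) {
    cat(sprintf("  arm A (ChIP): %d KZFPs; top binder %s (%d overlaps)\n",
                nrow(x$arm_a), x$arm_a$kzfp[1L], x$arm_a$n_overlap[1L]))
  }
  if (!is.null(x$arm_b)) {
    cat(sprintf("  arm B (no ChIP): %d candidate(s)\n", nrow(x$arm_b)))
  } else if (!is.null(x$arm_assignment) && any(x$arm_assignment == "B")) {
    cat("  arm B: no candidates\n")
  }
  invisible(x)
}

#' Write a screen report to a directory
#'
#' Emits `report.json`, `armA_ranking.tsv`, `armB_candidates.tsv` and
#' `pbs_annotations.bed`.
#'
#' @param report `screen_report` from [run_screen()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(report$pbs))
    write_pbs_bed(report$pbs, file.path(dir, "pbs_annotations.bed"))
  if (!is.null(report$arm_a))
    write.table(report$arm_a, file.path(dir, "armA_ranking.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$arm_b))
    write.table(report$arm_b, file.path(dir, "armB_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    thresholds = report$thresholds, log = report$log,
    no_targets = report$no_targets,
    n_pbs = nrow(report$pbs),
    arm_a_top = if (!is.null(report$arm_a)) report$arm_a$kzfp[1L],
    arm_b_candidates = if (!is.null(report$arm_b)) report$arm_b$gene,
    invasion_peak = if (!is.null(report$invasion))
      report$invasion$peak_window)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
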