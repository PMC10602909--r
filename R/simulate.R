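#' @name simulate
#' @title Seeded synthetic inputs with ground truth
#' @description
#' Generators emulating every input of the screen on a small scale: a
#' genome with planted proviruses (paired LTRs mutated according to the
#' molecular clock, an embedded 18-nt PBS of chosen type), a KZFP protein
#' panel with one true binder whose fingers are built by inverting the
#' recognition code against the planted PBS, ChIP-like peak sets
#' concentrated on PBS loci for the binder and uniform for decoys, and
#' ortholog tables encoding known gene ages. Each generator is a pure
#' function of its parameters and `seed`, and returns a `truth` component
#' sufficient to verify the corresponding pipeline stage.
NULL

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# per-LTR per-site mutation probability q such that the expected observed
# p-distance between the two independently mutated copies equals d
# (each mutated site moves to one of the three other bases uniformly):
#   P(differ) = 1 - (1-q)^2 - q^2/3 = d  =>  (4/3) q^2 - 2 q + d = 0
ltr_mutation_rate <- function(d) {
  if (d == 0) return(0)
  (2 - sqrt(4 - 16 * d / 3)) / (8 / 3)
}

mutate_sites <- function(seq, q) {
  n <- nchar(seq)
  hit <- which(runif(n) < q)
  if (!length(hit)) return(seq)
  res <- strsplit(seq, "")[[1]]
  for (i in hit) {
    res[i] <- sample(setdiff(c("A", "C", "G", "T"), res[i]), 1L)
  }
  paste(res, collapse = "")
}

#' Simulate a genome with planted ERV proviruses
#'
#' Each provirus is laid out as 5'LTR + PBS (18 nt immediately downstream
#' of the 5'LTR) + internal sequence + 3'LTR. The two LTR copies start
#' identical and are mutated independently at a per-site rate calibrated so
#' that their expected pairwise divergence equals `age * 0.4%` (the linear
#' clock used by [insertion_age()]). The PBS carries the requested number
#' of mismatches, placed by default outside the conserved first nine
#' nucleotides.
#'
#' @param n_ervs number of proviruses.
#' @param genome_len genome length (nt).
#' @param ages true insertion ages in Myr (recycled over ERVs).
#' @param pbs_types PBS type per ERV (recycled; must be in `catalog`).
#' @param pbs_mismatches planted PBS mismatch count (recycled).
#' @param seed RNG seed.
#' @param ltr_len,internal_len provirus geometry (defaults 1000 / 1500 nt).
#' @param catalog PBS catalog (default [default_pbs_catalog()]).
#' @return List with `genome` (named character), `erv_bed` (0-based
#'   half-open provirus intervals), `pbs_truth` (planted PBS intervals with
#'   type and mismatches), `ltr_pairs` (mutated LTR copies per ERV),
#'   `ltr_ends` (0-based 5'-LTR end coordinates) and `truth` (all planted
#'   parameters).
#' @export
simulate_genome <- function(n_ervs = 10L, genome_len = 100000L,
                            ages = 30, pbs_types = "Pro",
                            pbs_mismatches = 0L, seed = 1L,
                            ltr_len = 1000L, internal_len = 1500L,
                            catalog = default_pbs_catalog()) {
  set.seed(seed)
  ages <- rep_len(ages, n_ervs)
  pbs_types <- rep_len(pbs_types, n_ervs)
  pbs_mismatches <- rep_len(as.integer(pbs_mismatches), n_ervs)
  if (any(ages < 0)) stop("ages must be >= 0")
  if (!all(pbs_types %in% names(catalog)))
    stop("unknown PBS type(s): ",
         paste(setdiff(pbs_types, names(catalog)), collapse = ", "))
  unit <- 2L * ltr_len + 18L + internal_len
  slot <- genome_len %/% n_ervs
  if (unit >= slot)
    stop(sprintf("infeasible packing: provirus length %d does not fit slot %d",
                 unit, slot))
  genome <- random_dna(genome_len)
  erv_rows <- vector("list", n_ervs)
  pbs_rows <- vector("list", n_ervs)
  ltr_pairs <- vector("list", n_ervs)
  for (i in seq_len(n_ervs)) {
    erv_id <- sprintf("ERV%02d", i)
    start0 <- (i - 1L) * slot + sample.int(slot - unit, 1L)  # 0-based
    anc <- random_dna(ltr_len)
    q <- ltr_mutation_rate(ages[i] * 0.004)
    ltr5 <- mutate_sites(anc, q)
    ltr3 <- mutate_sites(anc, q)
    pbs <- catalog[[pbs_types[i]]]$consensus
    if (pbs_mismatches[i] > 0L) {
      cand <- if (pbs_mismatches[i] <= 9L) 10:18 else 1:18
      pos <- sample(cand, pbs_mismatches[i])
      res <- strsplit(pbs, "")[[1]]
      for (p in pos) res[p] <- sample(setdiff(c("A", "C", "G", "T"), res[p]), 1L)
      pbs <- paste(res, collapse = "")
    }
    prov <- paste0(ltr5, pbs, random_dna(internal_len), ltr3)
    substr(genome, start0 + 1L, start0 + unit) <- prov
    erv_rows[[i]] <- data.frame(erv_id = erv_id, start = start0,
                                end = start0 + unit, age = ages[i],
                                stringsAsFactors = FALSE)
    pbs_rows[[i]] <- data.frame(seqname = "chrS", erv_id = erv_id,
                                start = start0 + ltr_len,
                                end = start0 + ltr_len + 18L,
                                type = pbs_types[i], sequence = pbs,
                                mismatches = pbs_mismatches[i],
                                strand = "+", stringsAsFactors = FALSE)
    ltr_pairs[[i]] <- list(ltr5 = ltr5, ltr3 = ltr3)
  }
  erv_bed <- do.call(rbind, erv_rows)
  names(ltr_pairs) <- erv_bed$erv_id
  list(genome = c(chrS = genome),
       erv_bed = erv_bed,
       pbs_truth = do.call(rbind, pbs_rows),
       ltr_pairs = ltr_pairs,
       ltr_ends = erv_bed$start + ltr_len,
       truth = list(seed = seed, n_ervs = n_ervs, genome_len = genome_len,
                    ages = ages, pbs_types = pbs_types,
                    pbs_mismatches = pbs_mismatches, ltr_len = ltr_len,
                    internal_len = internal_len))
}

# KRAB-like N-terminal scaffold and finger filler; deliberately free of C
# and H so the C2H2 scanner sees exactly the constructed fingers
KRAB_SCAFFOLD <- "MDAKSLTAWSRTLVTFKDVFVDFTREEWKLLDTAQQIVYRNVMLENYKNLVSLGLAVSKPDLITLLEQGKEPWNVKR"
ZF_LINKER <- "TGEKP"

build_finger <- function(fingerprint) {
  f <- strsplit(fingerprint, "")[[1]]
  stopifnot(length(f) == 4L)
  spacer <- paste0("GKAFS", f[1L], "S", f[2L], f[3L], "LT", f[4L])
  paste0("C", "AE", "C", spacer, "H", "LRA", "H")
}

build_kzfp <- function(fingerprints) {
  paste0(KRAB_SCAFFOLD, "SGE",
         paste(vapply(fingerprints, build_finger, ""),
               collapse = ZF_LINKER), "STGSQ")
}

#' Simulate a KZFP protein panel with one planted binder
#'
#' The binder's fingers are built by inverting the recognition code against
#' consecutive triplets of the target PBS (finger order reversed, since the
#' C-terminal finger binds the 5'-most triplet), so its predicted motif
#' reproduces the PBS exactly. Decoys receive random code-table
#' fingerprints and are regenerated until their predicted motif matches the
#' PBS at a fraction below 0.5. All proteins are a KRAB-like scaffold plus
#' a C2H2 array that [find_c2h2()] detects exactly.
#'
#' @param n panel size (default 20).
#' @param pbs target PBS (`pbs_motif` or 18-nt string; default PBS-Pro).
#' @param code recognition code (default [default_recognition_code()];
#'   must be invertible for the PBS triplets).
#' @param seed RNG seed.
#' @param n_decoy_fingers finger count for decoys (default 6).
#' @return List with `proteins` (named character vector), `truth` (binder
#'   id, per-protein fingerprints and true ages of none -- ages are
#'   assigned by [simulate_ortholog_table()]).
#' @export
simulate_kzfp_panel <- function(n = 20L, pbs = NULL,
                                code = default_recognition_code(),
                                seed = 1L, n_decoy_fingers = 6L) {
  set.seed(seed + 1L)
  if (is.null(pbs)) pbs <- default_pbs_catalog()[["Pro"]]
  pseq <- if (inherits(pbs, "pbs_motif")) pbs$consensus else
    check_sequence(pbs, "dna")
  n_trip <- nchar(pseq) %/% 3L
  trip <- substring(pseq, 3L * seq_len(n_trip) - 2L, 3L * seq_len(n_trip))
  # finger i (N->C) binds triplet n-i+1, so prediction in reverse finger
  # order reads the PBS 5'->3'
  binder_fp <- invert_recognition_code(rev(trip), code)
  ids <- sprintf("KZFP%02d", seq_len(n))
  binder_id <- sample(ids, 1L)
  fingerprints <- vector("list", n)
  names(fingerprints) <- ids
  proteins <- character(n)
  names(proteins) <- ids
  for (id in ids) {
    if (id == binder_id) {
      fingerprints[[id]] <- binder_fp
    } else {
      repeat {
        fp <- sample(code$fingerprint, n_decoy_fingers, replace = TRUE)
        motif <- paste(rev(code$triplet[match(fp, code$fingerprint)]),
                       collapse = "")
        if (motif_vs_pbs(motif, pseq)$fraction < 0.5) break
      }
      fingerprints[[id]] <- fp
    }
    proteins[[id]] <- build_kzfp(fingerprints[[id]])
  }
  list(proteins = proteins,
       truth = list(seed = seed, binder = binder_id, pbs = pseq,
                    fingerprints = fingerprints))
}

#' Simulate per-KZFP ChIP-like peak sets
#'
#' The binder's peaks are centred on a fraction (default 0.9, at least
#' 0.8) of the planted PBS loci with widths of 200-400 bp and scores of
#' 600-1000; each decoy receives the same number of uniformly placed peaks
#' with scores of 100-1000.
#'
#' @param binder binder KZFP id.
#' @param decoys character vector of decoy ids.
#' @param pbs data.frame of PBS intervals (`seqname`/`chrom`, `start`,
#'   `end`).
#' @param genome_len genome length.
#' @param seed RNG seed.
#' @param frac_bound fraction of PBS loci the binder occupies (default
#'   0.9).
#' @return List with `peaks` (named list of BED-style data.frames) and
#'   `truth`.
#' @export
simulate_peaks <- function(binder, decoys, pbs, genome_len, seed = 1L,
                           frac_bound = 0.9) {
  set.seed(seed + 2L)
  chrom <- if ("seqname" %in% names(pbs)) pbs$seqname else pbs$chrom
  n_pbs <- nrow(pbs)
  n_bound <- ceiling(frac_bound * n_pbs)
  bound <- sort(sample.int(n_pbs, n_bound))
  width <- function(k) sample(200:400, k, replace = TRUE)
  mk_peaks <- function(starts, w, scores, prefix) {
    starts <- pmax(0L, pmin(starts, genome_len - w))
    data.frame(chrom = chrom[1L], start = as.integer(starts),
               end = as.integer(starts + w),
               name = sprintf("%s_peak%03d", prefix, seq_along(starts)),
               score = round(scores, 1), strand = ".",
               stringsAsFactors = FALSE)
  }
  peaks <- list()
  w <- width(n_bound)
  mid <- (pbs$start[bound] + pbs$end[bound]) %/% 2L
  peaks[[binder]] <- mk_peaks(mid - w %/% 2L, w, runif(n_bound, 600, 1000),
                              binder)
  for (d in decoys) {
    w <- width(n_bound)
    peaks[[d]] <- mk_peaks(sample.int(genome_len - 400L, n_bound), w,
                           runif(n_bound, 100, 1000), d)
  }
  list(peaks = peaks,
       truth = list(seed = seed, binder = binder, bound_pbs = bound,
                    frac_bound = frac_bound))
}

#' Simulate an ortholog table encoding known gene ages
#'
#' A gene of planted age A has orthologs exactly in the species whose
#' divergence from the reference is at most A (ages are snapped to the
#' nearest attainable species divergence, which is what an ortholog-based
#' estimator can recover). Patchiness removes each strictly younger
#' species' ortholog with the given probability (never the oldest), to
#' exercise the reliability flag.
#'
#' @param gene_ages named numeric vector: requested age in Myr per gene.
#' @param species_times named numeric vector: divergence time from the
#'   reference species per species.
#' @param patchiness dropout probability in \[0, 1\] (default 0).
#' @param seed RNG seed.
#' @param reference reference species name (default `"human"`).
#' @return List with `table` (gene -> species list), `times`
#'   (long-format data.frame), `truth` (snapped true ages per gene).
#' @export
simulate_ortholog_table <- function(gene_ages, species_times,
                                    patchiness = 0, seed = 1L,
                                    reference = "human") {
  set.seed(seed + 3L)
  stopifnot(!is.null(names(gene_ages)), !is.null(names(species_times)))
  snapped <- vapply(gene_ages, function(a) {
    ok <- species_times[species_times <= a]
    if (length(ok)) max(ok) else 0
  }, 0)
  table <- lapply(names(gene_ages), function(g) {
    a <- snapped[[g]]
    sp <- names(species_times)[species_times <= a]
    if (!length(sp)) return(reference)
    oldest <- names(species_times)[which(species_times == a)][1L]
    younger <- setdiff(sp, oldest)
    drop <- younger[runif(length(younger)) < patchiness]
    c(reference, setdiff(sp, drop))
  })
  names(table) <- names(gene_ages)
  times <- data.frame(species_a = reference,
                      species_b = names(species_times),
                      myr = unname(species_times),
                      stringsAsFactors = FALSE)
  list(table = table, times = times,
       truth = list(seed = seed, requested_ages = gene_ages,
                    ages = snapped, patchiness = patchiness,
                    reference = reference))
}

#' Default species divergence times used by the simulator
#'
#' A small primate-anchored ladder of divergence times from human (Myr),
#' in the spirit of TimeTree medians, spanning 6-160 Myr.
#'
#' @return Named numeric vector.
#' @export
default_species_times <- function() {
  c(chimpanzee = 6, gorilla = 9, orangutan = 16, gibbon = 20,
    macaque = 30, marmoset = 43, tarsier = 58, lemur = 74,
    mouse = 90, cow = 96, opossum = 160)
}

#' Simulate a full screen input set
#'
#' Combines the genome, panel, peak and ortholog generators into one
#' coherent dataset: proviruses of the target PBS type with insertion ages
#' drawn from a truncated Normal(30, 3) (the invasion peak of the
#' PBS-Pro-utilising subfamily sits around 30 Myr), a panel with one true
#' binder whose planted gene age (30 Myr) co-occurs with that peak, peaks
#' for every KZFP, and an ortholog table for the whole panel. Decoy gene
#' ages are drawn uniformly over the species ladder.
#'
#' @param n_kzfps panel size (default 20).
#' @param n_ervs provirus count (default 10).
#' @param genome_len genome length (default 100000).
#' @param seed RNG seed.
#' @param pbs_type target PBS type (default `"Pro"`).
#' @param catalog PBS catalog.
#' @return List with all generator outputs plus a merged `truth`.
#' @export
simulate_screen_inputs <- function(n_kzfps = 20L, n_ervs = 10L,
                                   genome_len = 100000L, seed = 1L,
                                   pbs_type = "Pro",
                                   catalog = default_pbs_catalog()) {
  set.seed(seed)
  ages <- pmax(0, rnorm(n_ervs, mean = 30, sd = 3))
  genome <- simulate_genome(n_ervs = n_ervs, genome_len = genome_len,
                            ages = ages, pbs_types = pbs_type,
                            pbs_mismatches = 0L, seed = seed,
                            catalog = catalog)
  panel <- simulate_kzfp_panel(n = n_kzfps, pbs = catalog[[pbs_type]],
                               seed = seed)
  binder <- panel$truth$binder
  decoys <- setdiff(names(panel$proteins), binder)
  peaks <- simulate_peaks(binder, decoys, genome$pbs_truth, genome_len,
                          seed = seed)
  st <- default_species_times()
  set.seed(seed + 4L)
  gene_ages <- setNames(sample(unname(st), n_kzfps, replace = TRUE),
                        names(panel$proteins))
  gene_ages[binder] <- 30
  orth <- simulate_ortholog_table(gene_ages, st, patchiness = 0,
                                  seed = seed)
  list(genome = genome, panel = panel, peaks = peaks, orthologs = orth,
       truth = list(seed = seed, binder = binder,
                    erv_ages = genome$truth$ages,
                    gene_ages = orth$truth$ages,
                    pbs_type = pbs_type))
}

#' Write a simulated dataset to a directory
#'
#' Emits `genome.fa`, `ervs.bed`, `pbs_truth.bed`, `kzfps.fa`,
#' `peaks/<kzfp>.bed`, `orthologs.tsv`, `divergence_times.tsv` and
#' `truth.json`.
#'
#' @param sim output of [simulate_screen_inputs()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome$genome, file.path(dir, "genome.fa"))
  write.table(data.frame("chrS", sim$genome$erv_bed$start,
                         sim$genome$erv_bed$end, sim$genome$erv_bed$erv_id),
              file.path(dir, "ervs.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  pt <- sim$genome$pbs_truth
  write.table(data.frame(pt$seqname, pt$start, pt$end, pt$type, 0L,
                         pt$strand),
              file.path(dir, "pbs_truth.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_fasta(sim$panel$proteins, file.path(dir, "kzfps.fa"))
  for (id in names(sim$peaks$peaks))
    write_bed(sim$peaks$peaks[[id]], file.path(dir, "peaks",
                                               paste0(id, ".bed")))
  orth <- sim$orthologs
  long <- do.call(rbind, lapply(names(orth$table), function(g)
    data.frame(gene = g, species = orth$table[[g]], present = 1L)))
  write.table(long, file.path(dir, "orthologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(orth$times, file.path(dir, "divergence_times.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
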