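test_that("generators are pure functions of parameters and seed", {
  a <- simulate_genome(n_ervs = 3, genome_len = 20000, ages = c(1, 5, 10),
                       seed = 99, ltr_len = 300, internal_len = 300)
  b <- simulate_genome(n_ervs = 3, genome_len = 20000, ages = c(1, 5, 10),
                       seed = 99, ltr_len = 300, internal_len = 300)
  expect_identical(a, b)
  c <- simulate_genome(n_ervs = 3, genome_len = 20000, ages = c(1, 5, 10),
                       seed = 100, ltr_len = 300, internal_len = 300)
  expect_false(identical(a$genome, c$genome))
  p1 <- simulate_kzfp_panel(n = 5, seed = 4)
  p2 <- simulate_kzfp_panel(n = 5, seed = 4)
  expect_identical(p1, p2)
})

test_that("age-zero proviruses carry identical LTR pairs", {
  sim <- simulate_genome(n_ervs = 2, genome_len = 10000, ages = 0,
                         seed = 2, ltr_len = 400, internal_len = 200)
  for (pair in sim$ltr_pairs)
    expect_identical(pair$ltr5, pair$ltr3)
})

test_that("planted PBS loci are recovered exactly by scanning", {
  sim <- simulate_genome(n_ervs = 4, genome_len = 30000, ages = 10,
                         pbs_mismatches = c(0, 1, 2, 3), seed = 8,
                         ltr_len = 400, internal_len = 300)
  hits <- scan_pbs(sim$genome, max_mismatch = 3)
  expect_equal(hits$start, sim$pbs_truth$start)
  expect_equal(hits$end, sim$pbs_truth$end)
  expect_equal(hits$mismatches, sim$pbs_truth$mismatches)
  # planted mismatches spare the conserved first nine nucleotides
  for (i in seq_len(nrow(sim$pbs_truth)))
    expect_equal(substr(sim$pbs_truth$sequence[i], 1, 9),
                 substr(default_pbs_catalog()$Pro$consensus, 1, 9))
})

test_that("infeasible provirus packing is rejected", {
  expect_error(simulate_genome(n_ervs = 5, genome_len = 5000,
                               ltr_len = 1000, internal_len = 1500),
               "infeasible packing")
})

test_that("every simulated protein yields exactly its constructed fingers", {
  panel <- simulate_kzfp_panel(n = 12, seed = 3)
  for (id in names(panel$proteins)) {
    zfa <- find_c2h2(panel$proteins[[id]], id)
    expect_equal(nrow(zfa$fingers), length(panel$truth$fingerprints[[id]]))
    expect_equal(zfa$fingers$fingerprint, panel$truth$fingerprints[[id]])
  }
})

test_that("decoy predicted motifs stay below a 0.5 match to the planted PBS", {
  panel <- simulate_kzfp_panel(n = 12, seed = 1)
  decoys <- setdiff(names(panel$proteins), panel$truth$binder)
  for (id in decoys) {
    pm <- suppressWarnings(predict_motif(find_c2h2(panel$proteins[[id]], id)))
    expect_lt(motif_vs_pbs(pm, panel$truth$pbs)$fraction, 0.5)
  }
})

test_that("binder peaks hit at least 80% of PBS loci; decoys roughly at coverage rate", {
  sim <- simulate_genome(n_ervs = 10, genome_len = 100000, ages = 10,
                         seed = 6)
  pk <- simulate_peaks("b", c("d1", "d2"), sim$pbs_truth, 100000, seed = 6)
  pbs <- sim$pbs_truth
  names(pbs)[names(pbs) == "seqname"] <- "chrom"
  pbs$chrom <- pk$peaks$b$chrom[1]
  b <- count_overlaps_report(pk$peaks$b, pbs, "b")
  expect_gte(b$n_overlap, ceiling(0.8 * nrow(pbs)))
  # decoy expectation: n_peaks * P(random peak hits a PBS); each ~300 bp
  # peak can hit an 18 bp locus over ~317 positions per locus
  for (d in c("d1", "d2")) {
    r <- count_overlaps_report(pk$peaks[[d]], pbs, d)
    n <- r$n_peaks
    p_hit <- min(1, nrow(pbs) * (300 + 17) / 100000)
    expect_lte(abs(r$n_overlap - n * p_hit),
               3 * sqrt(n * p_hit * (1 - p_hit)) + 1)
  }
  # empty decoy set is valid
  pk0 <- simulate_peaks("b", character(), sim$pbs_truth, 100000, seed = 6)
  expect_named(pk0$peaks, "b")
})

test_that("LTR mutation calibration recovers the planted age on average", {
  recovered <- vapply(1:20, function(s) {
    sim <- simulate_genome(n_ervs = 1, genome_len = 4000, ages = 10,
                           seed = s, ltr_len = 1000, internal_len = 200)
    date_ltr_pairs(sim$ltr_pairs)$age
  }, 0)
  expect_lte(abs(mean(recovered) - 10), 1.5)
})

test_that("a simulated dataset writes to plain-text files that read back", {
  sim <- simulate_screen_inputs(n_kzfps = 4, n_ervs = 3, genome_len = 30000,
                                seed = 12)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "ervs.bed", "pbs_truth.bed", "kzfps.fa",
    "orthologs.tsv", "divergence_times.tsv", "truth.json")))))
  genome <- read_fasta(file.path(dir, "genome.fa"), "dna")
  expect_identical(unname(genome), unname(sim$genome$genome))
  prot <- read_fasta(file.path(dir, "kzfps.fa"), "protein")
  expect_identical(prot, sim$panel$proteins)
  orth <- read_ortholog_table(file.path(dir, "orthologs.tsv"))
  expect_setequal(names(orth), names(sim$orthologs$table))
  peaks <- read_bed(file.path(dir, "peaks",
                              paste0(sim$truth$binder, ".bed")))
  expect_equal(nrow(peaks), nrow(sim$peaks$peaks[[sim$truth$binder]]))
})
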