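screen_cfg <- function(sim, peaks = sim$peaks$peaks, ...) {
  screen_config(genome = sim$genome$genome,
                proteins = sim$panel$proteins,
                peaks = peaks,
                ltr_ends = sim$genome$ltr_ends,
                ltr_pairs = sim$genome$ltr_pairs,
                orthologs = sim$orthologs$table,
                divergence_times = sim$orthologs$times, ...)
}

test_that("arm A ranks the planted binder first on the default panel", {
  sim <- simulate_screen_inputs(seed = 1)
  rep <- run_screen(screen_cfg(sim))
  expect_false(rep$no_targets)
  expect_equal(nrow(rep$pbs), 10L)
  expect_equal(rep$arm_a$kzfp[1], sim$truth$binder)
  expect_true(all(names(sim$panel$proteins) %in% names(rep$arm_assignment)))
  expect_true(all(rep$arm_assignment == "A"))
})

test_that("arm B recovers the binder (and only it) when its peaks are withheld", {
  sim <- simulate_screen_inputs(seed = 2)
  binder <- sim$truth$binder
  withheld <- sim$peaks$peaks[setdiff(names(sim$peaks$peaks), binder)]
  rep <- run_screen(screen_cfg(sim, peaks = withheld))
  expect_equal(rep$arm_assignment[[binder]], "B")
  expect_equal(rep$arm_b$gene, binder)
  expect_gte(rep$arm_b$motif_match, 0.7)
  # binder age co-occurs with the ERV invasion peak
  expect_lte(rep$invasion$peak_window[1] - 10, rep$arm_b$age)
  expect_gte(rep$invasion$peak_window[2] + 10, rep$arm_b$age)
})

test_that("a decoy-only panel produces an empty candidate list without error", {
  sim <- simulate_screen_inputs(seed = 3)
  binder <- sim$truth$binder
  sim$panel$proteins <- sim$panel$proteins[names(sim$panel$proteins) != binder]
  withheld <- sim$peaks$peaks[setdiff(names(sim$peaks$peaks), binder)]
  rep <- run_screen(screen_cfg(sim, peaks = withheld))
  expect_true(is.null(rep$arm_b) || nrow(rep$arm_b) == 0L)
})

test_that("the report is identical across repeated runs", {
  sim <- simulate_screen_inputs(seed = 4)
  r1 <- run_screen(screen_cfg(sim))
  r2 <- run_screen(screen_cfg(sim))
  expect_identical(r1, r2)
})

test_that("raising thresholds never grows the candidate or PBS sets", {
  sim <- simulate_screen_inputs(seed = 5)
  binder <- sim$truth$binder
  withheld <- sim$peaks$peaks[setdiff(names(sim$peaks$peaks), binder)]
  base <- run_screen(screen_cfg(sim, peaks = withheld))
  for (args in list(list(pbs_min_score = 105),
                    list(motif_match_min = 0.9),
                    list(strong_peak = 900))) {
    cfg <- do.call(screen_cfg, c(list(sim, peaks = withheld), args))
    rep <- run_screen(cfg)
    expect_lte(nrow(rep$pbs), nrow(base$pbs))
    if (!is.null(rep$arm_b) && !is.null(base$arm_b))
      expect_true(all(rep$arm_b$gene %in% base$arm_b$gene))
  }
})

test_that("an unreachable PBS score threshold yields an explicit no-targets report", {
  sim <- simulate_screen_inputs(seed = 6)
  rep <- run_screen(screen_cfg(sim, pbs_min_score = 1000))
  expect_true(rep$no_targets)
  expect_equal(nrow(rep$pbs), 0L)
})

test_that("reference binders are reported with fingerprint similarity flags", {
  sim <- simulate_screen_inputs(seed = 7)
  binder <- sim$truth$binder
  withheld <- sim$peaks$peaks[setdiff(names(sim$peaks$peaks), binder)]
  refs <- setNames(sim$panel$proteins[binder], "REFBINDER")
  rep <- run_screen(screen_cfg(sim, peaks = withheld,
                               reference_binders = refs))
  expect_equal(rep$arm_b$gene, binder)
  # the candidate IS the reference here, so similarity is maximal
  expect_equal(rep$arm_b$fingerprint_similarity, 100)
  expect_false(rep$arm_b$dissimilar_to_refs)
})

test_that("screen reports serialize to files", {
  sim <- simulate_screen_inputs(n_kzfps = 5, n_ervs = 3, genome_len = 30000,
                                seed = 8)
  rep <- run_screen(screen_cfg(sim))
  dir <- withr::local_tempdir()
  write_screen_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "armA_ranking.tsv")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$arm_a_top, rep$arm_a$kzfp[1])
})

test_that("screen accepts file paths as inputs", {
  sim <- simulate_screen_inputs(n_kzfps = 5, n_ervs = 3, genome_len = 30000,
                                seed = 9)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  peak_paths <- as.list(file.path(dir, "peaks",
                                  paste0(names(sim$peaks$peaks), ".bed")))
  names(peak_paths) <- names(sim$peaks$peaks)
  cfg <- screen_config(genome = file.path(dir, "genome.fa"),
                       proteins = file.path(dir, "kzfps.fa"),
                       peaks = peak_paths,
                       ltr_ends = sim$genome$ltr_ends,
                       ltr_pairs = sim$genome$ltr_pairs,
                       orthologs = file.path(dir, "orthologs.tsv"),
                       divergence_times = file.path(dir,
                                                    "divergence_times.tsv"))
  rep <- run_screen(cfg)
  expect_equal(rep$arm_a$kzfp[1], sim$truth$binder)
})
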