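zif268_f1 <- "PYACPVESCDRRFSRSDELTRHIRIHTG"

test_that("the canonical Zif268 finger-1 peptide yields one finger with fingerprint RDER", {
  zfa <- find_c2h2(zif268_f1)
  expect_equal(nrow(zfa$fingers), 1L)
  expect_equal(zfa$fingers$fingerprint, "RDER")
  expect_match(zfa$fingers$motif, "^C.{2,4}C.{12}H.{3,5}H$")
})

test_that("proteins without the C2H2 pattern give an empty array", {
  expect_equal(nrow(find_c2h2(strrep("A", 60))$fingers), 0L)
  expect_equal(nrow(find_c2h2("MKVLQQW")$fingers), 0L)
})

test_that("an all-alanine spacer yields the AAAA fingerprint", {
  motif <- paste0("CAAC", strrep("A", 12), "HAAAH")
  expect_equal(extract_fingerprint(motif), "AAAA")
})

test_that("finger spans never overlap and fingerprints come from the spacer", {
  set.seed(13)
  aa_pool <- c("A", "R", "N", "D", "E", "G", "I", "L", "K", "F", "S", "T", "V")
  for (i in 1:200) {
    fp <- paste(sample(aa_pool, 4, replace = TRUE), collapse = "")
    motif <- synth_finger(fp)
    expect_equal(extract_fingerprint(motif), fp)
    # each extracted residue must be inside the 12-residue spacer
    spacer <- substr(motif, 5, 16)
    for (r in strsplit(fp, "")[[1]]) expect_true(grepl(r, spacer, fixed = TRUE))
  }
  # multi-finger protein: spans ascend without overlap
  prot <- paste0("MKV", synth_finger("RDER"), "TGEKP", synth_finger("NDET"),
                 "TGEKP", synth_finger("TDRN"), "STQ")
  zfa <- find_c2h2(prot)
  expect_equal(nrow(zfa$fingers), 3L)
  expect_true(all(diff(zfa$fingers$start) > 0))
  expect_true(all(zfa$fingers$start[-1] > zfa$fingers$end[-3]))
  expect_equal(zfa$fingers$fingerprint, c("RDER", "NDET", "TDRN"))
})

test_that("fingerprint similarity is 100 for identical arrays and 0 for disjoint residues", {
  expect_equal(fingerprint_similarity(c("RDER", "NDET"), c("RDER", "NDET")), 100)
  expect_equal(fingerprint_similarity(c("RRRR"), c("EEEE", "TTTT")), 0)
  expect_error(fingerprint_similarity(character(), "RDER"), "non-empty")
})

test_that("fingerprint similarity equals the exhaustive monotone-alignment oracle", {
  pool <- c("RDER", "RDET", "NDER")
  arrays <- list()
  for (l in 1:3) {
    grid <- do.call(expand.grid, rep(list(pool), l))
    arrays <- c(arrays, lapply(seq_len(nrow(grid)), function(i)
      as.character(unlist(grid[i, ]))))
  }
  for (a in arrays) for (b in arrays) {
    expect_equal(fingerprint_similarity(a, b),
                 brute_fingerprint_similarity(a, b),
                 info = paste(paste(a, collapse = ","), "vs",
                              paste(b, collapse = ",")))
  }
})

test_that("fingerprint similarity is symmetric and extra fingers dilute it", {
  set.seed(17)
  pool <- apply(matrix(sample(c("R", "D", "E", "T", "N"), 200, TRUE), 50), 1,
                paste, collapse = "")
  for (i in 1:25) {
    a <- sample(pool, sample(1:5, 1))
    b <- sample(pool, sample(1:5, 1))
    expect_equal(fingerprint_similarity(a, b), fingerprint_similarity(b, a))
    expect_lte(fingerprint_similarity(a, c(b, "AAAA")),
               fingerprint_similarity(a, b) * max(length(b), length(a)) /
                 max(length(b) + 1, length(a)) + 1e-9)
  }
})

test_that("motif prediction reads the recognition code in reverse finger order", {
  code <- default_recognition_code()
  single <- find_c2h2(synth_finger("RDER"))
  expect_equal(predict_motif(single, code)$consensus, "GCG")
  # C-terminal finger binds the 5'-most triplet
  two <- find_c2h2(paste0(synth_finger("RDER"), "TGEKP", synth_finger("RDHT")))
  pm <- predict_motif(two, code)
  expect_equal(pm$consensus, "TGGGCG")
  expect_equal(pm$revcomp, reverse_complement("TGGGCG"))
  expect_equal(nchar(pm$consensus), 3L * nrow(two$fingers))
})

test_that("unknown fingerprints map to NNN with a warning", {
  zfa <- find_c2h2(synth_finger("WWWW"))
  expect_warning(pm <- predict_motif(zfa), "NNN")
  expect_equal(pm$consensus, "NNN")
  expect_true(all(pm$unknown))
})

test_that("the simulator's planted binder round-trips through motif prediction", {
  for (seed in c(1, 7)) {
    panel <- simulate_kzfp_panel(n = 6, seed = seed)
    binder <- panel$truth$binder
    zfa <- find_c2h2(panel$proteins[[binder]], binder)
    pm <- predict_motif(zfa)
    expect_equal(pm$consensus, panel$truth$pbs)
    expect_equal(motif_vs_pbs(pm, panel$truth$pbs)$fraction, 1.0)
  }
})

test_that("motif/PBS comparison finds the best ungapped offset on either strand", {
  pro <- default_pbs_catalog()$Pro
  first9 <- substr(pro$consensus, 1, 9)
  got <- motif_vs_pbs(first9, pro)
  expect_equal(got$fraction, 1.0)
  expect_equal(got$offset, 0L)
  expect_equal(got$strand, "+")
  # reverse-complement motif matches on the minus strand
  got_rc <- motif_vs_pbs(reverse_complement(first9), pro)
  expect_equal(got_rc$fraction, 1.0)
  expect_equal(got_rc$strand, "-")
  # all-N motif is degenerate
  degen <- motif_vs_pbs("NNNNNN", pro)
  expect_equal(degen$fraction, 0)
  expect_true(degen$degenerate)
})

test_that("motif/PBS match fraction equals an exhaustive offset/strand scan", {
  pro <- default_pbs_catalog()$Pro$consensus
  set.seed(47)
  for (i in 1:40) {
    m <- random_dna_str(sample(c(3, 6, 9, 12, 21), 1))
    got <- motif_vs_pbs(m, pro)$fraction
    best <- 0
    for (ms in c(m, reverse_complement(m))) {
      lm <- nchar(ms); lp <- nchar(pro)
      for (off in -(max(lm - lp, 0)):(max(lp - lm, 0))) {
        x <- strsplit(ms, "")[[1]]
        y <- strsplit(pro, "")[[1]]
        idx <- seq_len(min(lm, lp - max(off, 0), lm + off, lp))
        xs <- x[idx + max(-off, 0)]
        ys <- y[idx + max(off, 0)]
        best <- max(best, sum(xs == ys) / length(idx))
      }
    }
    expect_equal(got, best, info = m)
  }
})

test_that("recognition code tables load from TSV and reject malformed triplets", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(fingerprint = c("RDER", "RDHT"),
                         triplet = c("GCG", "TGG")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  code <- load_recognition_code(path)
  expect_equal(predict_motif(find_c2h2(synth_finger("RDER")), code)$consensus,
               "GCG")
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(fingerprint = "RDER", triplet = "GC"),
              bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_recognition_code(bad), "3 nt")
})
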