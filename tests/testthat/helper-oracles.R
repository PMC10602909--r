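# Independent brute-force oracles. These deliberately avoid the package's
# dynamic-programming code paths: alignments are enumerated as explicit move
# sequences and scored directly.

# all monotone move sequences from (0,0) to (na,nb); moves: "M" diagonal,
# "U" consume a only (gap in b), "L" consume b only (gap in a)
enumerate_moves <- function(na, nb) {
  if (na == 0L && nb == 0L) return(list(character()))
  out <- list()
  if (na > 0L && nb > 0L)
    out <- c(out, lapply(enumerate_moves(na - 1L, nb - 1L), function(p) c("M", p)))
  if (na > 0L)
    out <- c(out, lapply(enumerate_moves(na - 1L, nb), function(p) c("U", p)))
  if (nb > 0L)
    out <- c(out, lapply(enumerate_moves(na, nb - 1L), function(p) c("L", p)))
  out
}

# score one alignment (move sequence) with affine gaps: a gap run of length
# L costs open + L * ext; with ends_free, runs touching either end are free
score_moves <- function(moves, a, b, mat, open, ext, ends_free) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  i <- 0L; j <- 0L
  runs <- rle(moves)
  total <- 0
  pos <- cumsum(c(1L, runs$lengths))
  for (k in seq_along(runs$values)) {
    v <- runs$values[k]; len <- runs$lengths[k]
    if (v == "M") {
      for (q in seq_len(len)) total <- total + mat[ca[i + q], cb[j + q]]
      i <- i + len; j <- j + len
    } else {
      terminal <- k == 1L || k == length(runs$values)
      if (!(ends_free && terminal)) total <- total - (open + len * ext)
      if (v == "U") i <- i + len else j <- j + len
    }
  }
  total
}

# optimal score by exhaustive enumeration
brute_align_score <- function(a, b, mat, open, ext, ends_free = TRUE) {
  paths <- enumerate_moves(nchar(a), nchar(b))
  max(vapply(paths, score_moves, 0, a = a, b = b, mat = mat,
             open = open, ext = ext, ends_free = ends_free))
}

# exhaustive fingerprint-array similarity: max over all monotone pairings
# of fingers (no reordering), scored as positionally identical residues
brute_fingerprint_similarity <- function(fa, fb) {
  score <- function(x, y) sum(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
  best <- 0
  rec <- function(i, j, acc) {
    if (i > length(fa) || j > length(fb)) {
      best <<- max(best, acc)
      return(invisible())
    }
    rec(i + 1L, j + 1L, acc + score(fa[i], fb[j]))
    rec(i + 1L, j, acc)
    rec(i, j + 1L, acc)
  }
  rec(1L, 1L, 0)
  100 * best / (4 * max(length(fa), length(fb)))
}

# quadratic all-pairs interval overlap count (0-based half-open)
brute_overlap_counts <- function(peaks, pbs, min_overlap = 1L) {
  hit <- logical(nrow(peaks))
  pbs_hit <- logical(nrow(pbs))
  for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(pbs))) {
    if (peaks$chrom[i] != pbs$chrom[j]) next
    inter <- min(peaks$end[i], pbs$end[j]) - max(peaks$start[i], pbs$start[j])
    if (inter >= min_overlap) {
      hit[i] <- TRUE
      pbs_hit[j] <- TRUE
    }
  }
  list(n_overlap = sum(hit), n_pbs_hit = sum(pbs_hit))
}

random_dna_str <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# a synthetic C2H2 finger with the given fingerprint (helix -1, 2, 3, 6)
synth_finger <- function(fp) {
  f <- strsplit(fp, "")[[1]]
  paste0("C", "AE", "C", "GKAFS", f[1], "S", f[2], f[3], "LT", f[4],
         "H", "LRA", "H")
}
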