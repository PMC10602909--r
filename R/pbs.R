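#' Derive a PBS motif from a tRNA 3' end
#'
#' The retroviral primer-binding site is the 18-nt genomic sequence
#' complementary to the 3'-terminal 18 nt of the priming host tRNA, so the
#' PBS consensus is the reverse complement of that 18-mer.
#'
#' @param trna tRNA sequence (DNA alphabet, length >= 18; cDNA of the tRNA).
#' @param trna_id tRNA identity label, e.g. `"Pro"`, `"Lys"`. Defaults to the
#'   name of `trna` if present.
#' @return Object of class `"pbs_motif"`: list with `trna_id`, `consensus`
#'   (18-nt string), `source_trna`.
#' @examples
#' derive_pbs_from_trna("GGCTCGTTGGTCTAGGGGTATGATTCTCGCTTATCCCGGACGAGCCCCCA", "Pro")
#' @export
derive_pbs_from_trna <- function(trna, trna_id = NULL) {
  if (is.null(trna_id))
    trna_id <- if (!is.null(names(trna))) names(trna)[1L] else "unknown"
  trna <- check_sequence(unname(trna)[1L], "dna")
  if (nchar(trna) < 18L) stop("tRNA must be at least 18 nt")
  tail18 <- substr(trna, nchar(trna) - 17L, nchar(trna))
  structure(list(trna_id = trna_id,
                 consensus = reverse_complement(tail18),
                 source_trna = trna),
            class = "pbs_motif")
}

#' @export
print.pbs_motif <- function(x, ...) {
  cat(sprintf("PBS-%s: %s\n", x$trna_id, x$consensus))
  invisible(x)
}

#' Build a PBS catalog from tRNA sequences
#'
#' @param trnas named character vector of tRNA sequences (names are the
#'   tRNA identities).
#' @return List of [derive_pbs_from_trna()] motifs, named by type.
#' @export
pbs_catalog <- function(trnas) {
  if (is.null(names(trnas))) stop("tRNA sequences must be named by identity")
  out <- lapply(names(trnas), function(id)
    derive_pbs_from_trna(trnas[[id]], id))
  names(out) <- names(trnas)
  out
}

#' Default PBS catalog
#'
#' Built from the bundled tRNA 3'-end fixture
#' (`inst/extdata/trna_3prime_synthetic.fa`): the Pro and Lys 3' ends follow
#' the widely used consensus sequences (PBS-Pro starts with the conserved
#' TGGGGGCTC nine-mer); the Leu, Phe and Trp entries are synthetic decoy
#' types constructed to differ from PBS-Pro within the first nine
#' nucleotides.
#'
#' @return Named list of `pbs_motif` objects.
#' @export
default_pbs_catalog <- function() {
  path <- system.file("extdata", "trna_3prime_synthetic.fa",
                      package = "kzfpscreen")
  pbs_catalog(read_fasta(path, "dna"))
}

hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  # N counts as a mismatch against everything, including N
  sum(ca != cb | ca == "N" | cb == "N")
}

#' Classify an 18-mer against a PBS catalog
#'
#' Assigns the catalog type with the fewest Hamming mismatches (N counts as
#' mismatch); ties are reported as ambiguous with all tied types.
#'
#' @param seq18 18-nt DNA string.
#' @param catalog list of `pbs_motif` (e.g. [default_pbs_catalog()]).
#' @return List with `type` (NA when ambiguous), `mismatches`, `ambiguous`
#'   flag and `tied_types`.
#' @export
classify_pbs <- function(seq18, catalog = default_pbs_catalog()) {
  seq18 <- check_sequence(seq18, "dna")
  if (nchar(seq18) != 18L) stop("PBS classification requires an 18-nt input")
  if (!length(catalog)) stop("catalog must be non-empty")
  d <- vapply(catalog, function(m) hamming(seq18, m$consensus), 0)
  tied <- names(catalog)[d == min(d)]
  list(type = if (length(tied) == 1L) tied else NA_character_,
       mismatches = unname(min(d)),
       ambiguous = length(tied) > 1L,
       tied_types = tied)
}

#' Pairwise distinctiveness of PBS types over a window
#'
#' Reports inter-type Hamming distances restricted to a consensus window
#' (default the first nine nucleotides, the region that separates PBS-Pro
#' from the other types).
#'
#' @param catalog list of `pbs_motif`.
#' @param window integer positions within the 18-mer (default 1:9).
#' @return Symmetric integer matrix of Hamming distances.
#' @export
pbs_distinctiveness <- function(catalog = default_pbs_catalog(),
                                window = 1:9) {
  wins <- vapply(catalog, function(m)
    paste(strsplit(m$consensus, "")[[1]][window], collapse = ""), "")
  n <- length(wins)
  m <- matrix(0L, n, n, dimnames = list(names(catalog), names(catalog)))
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- hamming(wins[i], wins[j])
  m
}

pbs_hit_score <- function(mismatches) as.integer(round(100 * (18 - mismatches) / 18))

#' Scan a sequence for PBS occurrences
#'
#' Every 18-mer window (both strands when `both_strands`) within
#' `max_mismatch` Hamming mismatches of any catalog consensus is reported;
#' when several types match a window the minimal-mismatch type is kept
#' (alphabetical tie-break). Windows containing more than six Ns are
#' skipped.
#'
#' The confidence score is `round(100 * (18 - mismatches) / 18)` plus a
#' positional bonus (default +10) when the hit starts within `bonus_dist`
#' bp downstream of an annotated 5'-LTR end (`ltr_ends`), so that an exact
#' hit in the expected proviral position scores above 100 and survives the
#' conventional `score > 100` high-confidence filter.
#'
#' @param target DNA sequence to scan (character scalar, optionally named).
#' @param catalog list of `pbs_motif`.
#' @param max_mismatch maximum mismatches (default 3; the first nine
#'   nucleotides of a PBS are the conserved part, the 3' half drifts).
#' @param both_strands scan the minus strand too (default TRUE).
#' @param ltr_ends optional integer vector of 0-based 5'-LTR end
#'   coordinates used for the positional bonus.
#' @param bonus,bonus_dist positional bonus score and window (defaults 10
#'   and 20 bp).
#' @param seqname sequence name used in the output (default the name of
#'   `target` or `"seq"`).
#' @return data.frame with 0-based half-open `start`, `end`, plus
#'   `seqname`, `type`, `score`, `strand`, `mismatches`, sorted by position
#'   then strand.
#' @export
scan_pbs <- function(target, catalog = default_pbs_catalog(),
                     max_mismatch = 3L, both_strands = TRUE,
                     ltr_ends = NULL, bonus = 10L, bonus_dist = 20L,
                     seqname = NULL) {
  if (is.null(seqname))
    seqname <- if (!is.null(names(target))) names(target)[1L] else "seq"
  target <- check_sequence(unname(target)[1L], "dna")
  if (max_mismatch < 0L || max_mismatch > 18L)
    stop("max_mismatch must be in [0, 18]")
  if (nchar(target) < 18L)
    return(empty_pbs_hits())
  subj <- Biostrings::DNAString(target)
  rows <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (type in names(catalog)) {
    cons <- catalog[[type]]$consensus
    for (strand in strands) {
      pat <- if (strand == "+") cons else reverse_complement(cons)
      mp <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch,
                                     with.indels = FALSE, fixed = TRUE)
      if (!length(mp)) next
      st <- Biostrings::start(mp)
      mm <- vapply(seq_along(mp), function(i)
        hamming(as.character(mp[[i]]), pat), 0)
      keep <- mm <= max_mismatch &
        vapply(seq_along(mp), function(i) {
          w <- as.character(mp[[i]])
          sum(strsplit(w, "")[[1]] == "N") <= 6L
        }, TRUE)
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        seqname = seqname, start = st[keep] - 1L, end = st[keep] + 17L,
        type = type, score = pbs_hit_score(mm[keep]), strand = strand,
        mismatches = as.integer(mm[keep]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_pbs_hits())
  hits <- do.call(rbind, rows)
  # best type per (start, strand); alphabetical tie-break on type
  hits <- hits[order(hits$start, hits$strand, hits$mismatches, hits$type), ]
  hits <- hits[!duplicated(hits[c("start", "strand")]), ]
  if (!is.null(ltr_ends) && length(ltr_ends)) {
    near <- vapply(hits$start, function(s)
      any(s - ltr_ends >= 0 & s - ltr_ends <= bonus_dist), TRUE)
    hits$score <- hits$score + ifelse(near, as.integer(bonus), 0L)
  }
  hits <- hits[order(hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

empty_pbs_hits <- function() {
  data.frame(seqname = character(), start = integer(), end = integer(),
             type = character(), score = integer(), strand = character(),
             mismatches = integer(), stringsAsFactors = FALSE)
}

#' Write PBS hits as 6-column BED
#'
#' @param hits data.frame from [scan_pbs()].
#' @param path output file.
#' @export
write_pbs_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$seqname, start = hits$start, end = hits$end,
                    name = hits$type, score = hits$score,
                    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
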