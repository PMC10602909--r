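#' Detect C2H2 zinc fingers in a protein
#'
#' Scans left to right for non-overlapping matches of the classical C2H2
#' pattern `C-x(2,4)-C-x(12)-H-x(3,5)-H` (earliest start, shortest variable
#' stretches). Only the inter-cysteine (2-4) and inter-histidine (3-5)
#' stretches vary; the spacer between the second cysteine and the first
#' histidine is fixed at 12 residues, which is what makes the fingerprint
#' offsets well defined. Matches whose spacer deviates from 12 cannot occur
#' under this pattern; fingers are annotated with their 4-residue
#' fingerprint (recognition-helix positions -1, 2, 3, 6).
#'
#' @param protein protein sequence (character scalar, optionally named).
#' @param id protein identifier (defaults to the name of `protein`).
#' @return Object of class `"zf_array"`: list with `protein_id`, `fingers`
#'   (data.frame: `index`, `start`, `end` 1-based inclusive, `motif`,
#'   `fingerprint`).
#' @examples
#' find_c2h2("PYACPVESCDRRFSRSDELTRHIRIHTG")
#' @export
find_c2h2 <- function(protein, id = NULL) {
  if (is.null(id))
    id <- if (!is.null(names(protein))) names(protein)[1L] else "protein"
  protein <- check_sequence(unname(protein)[1L], "protein")
  # lazy quantifiers give the shortest stretch at the earliest start;
  # gregexpr returns leftmost non-overlapping matches
  m <- gregexpr("C.{2,4}?C.{12}H.{3,5}?H", protein, perl = TRUE)[[1]]
  if (m[1L] == -1L) {
    fingers <- data.frame(index = integer(), start = integer(),
                          end = integer(), motif = character(),
                          fingerprint = character(),
                          stringsAsFactors = FALSE)
  } else {
    start <- as.integer(m)
    len <- attr(m, "match.length")
    motif <- substring(protein, start, start + len - 1L)
    fingers <- data.frame(
      index = seq_along(start), start = start, end = start + len - 1L,
      motif = motif,
      fingerprint = vapply(motif, extract_fingerprint, "", USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  }
  structure(list(protein_id = id, fingers = fingers), class = "zf_array")
}

#' @export
print.zf_array <- function(x, ...) {
  cat(sprintf("C2H2 array for %s: %d finger(s)\n", x$protein_id,
              nrow(x$fingers)))
  if (nrow(x$fingers)) print(x$fingers, row.names = FALSE)
  invisible(x)
}

#' Extract the 4-residue fingerprint of a C2H2 finger
#'
#' The DNA-contacting residues sit at recognition-helix positions -1, 2, 3
#' and 6. With the helix numbered so that the first zinc-chelating
#' histidine is helix position 7, these are the residues at offsets -7, -5,
#' -4 and -1 from the first histidine (for the canonical Zif268 finger 1
#' helix RSDELTR this yields R, D, E, R). They are reported in helix order
#' (-1, 2, 3, 6).
#'
#' @param motif a C2H2 finger match as returned in `find_c2h2()$fingers`.
#' @return 4-character fingerprint string.
#' @export
extract_fingerprint <- function(motif) {
  motif <- check_sequence(motif, "protein")
  m <- regexec("^C(.{2,4}?)C(.{12})H(.{3,5}?)H$", motif, perl = TRUE)[[1]]
  if (m[1L] == -1L)
    stop("not a C2H2 finger with a 12-residue C->H spacer")
  # group 2 is the fixed 12-residue spacer preceding the first His; the
  # helix residues -1/2/3/6 sit at spacer offsets 6, 8, 9, 12
  spacer <- strsplit(substring(motif, m[3L], m[3L] + 11L), "")[[1]]
  paste(spacer[c(6L, 8L, 9L, 12L)], collapse = "")
}

#' Fingerprint-array similarity between two C2H2 arrays
#'
#' Aligns the two ordered fingerprint lists with a dynamic program whose
#' unit is one finger: aligning finger i of `a` with finger j of `b` scores
#' the number of positionally identical fingerprint residues (0-4), gaps
#' score 0 and fingers are never re-ordered. The similarity is
#' `100 * best_score / (4 * max(n_a, n_b))`, so unmatched extra fingers
#' dilute similarity.
#'
#' @param a,b `zf_array` objects (or character vectors of 4-residue
#'   fingerprints).
#' @return Percentage in \[0, 100\].
#' @export
fingerprint_similarity <- function(a, b) {
  fa <- fingerprints_of(a)
  fb <- fingerprints_of(b)
  if (!length(fa) || !length(fb)) stop("both arrays must be non-empty")
  na <- length(fa); nb <- length(fb)
  score <- function(x, y)
    sum(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
  d <- matrix(0, na + 1L, nb + 1L)
  for (i in seq_len(na)) for (j in seq_len(nb))
    d[i + 1L, j + 1L] <- max(d[i, j] + score(fa[i], fb[j]),
                             d[i, j + 1L], d[i + 1L, j])
  100 * d[na + 1L, nb + 1L] / (4 * max(na, nb))
}

fingerprints_of <- function(x) {
  if (inherits(x, "zf_array")) x$fingers$fingerprint else as.character(x)
}

#' Default recognition code
#'
#' A lookup from 4-residue fingerprints (helix order -1, 2, 3, 6) to the
#' preferred DNA triplet read 5' to 3' (helix position 6 contacts the
#' 5'-most base, 3 the middle, -1 the 3'-most; position 2 contacts the
#' complementary strand and is held fixed here). The table is generated
#' from simplified canonical base contacts (Arg-G, Asn-A, Glu-C, Thr-T)
#' covering all 64 triplets, plus the classical Zif268 entries (RDER-GCG,
#' RDHT-TGG) as aliases. This is a deliberately small documented code, not
#' a reconstruction of any published server table; a user table can be
#' loaded with [load_recognition_code()].
#'
#' @return data.frame with columns `fingerprint`, `triplet`.
#' @export
default_recognition_code <- function() {
  base2res <- c(G = "R", A = "N", C = "E", T = "T")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  fp <- paste0(base2res[grid$b3], "D", base2res[grid$b2], base2res[grid$b1])
  code <- data.frame(fingerprint = fp,
                     triplet = paste0(grid$b1, grid$b2, grid$b3),
                     stringsAsFactors = FALSE)
  extra <- data.frame(fingerprint = c("RDHT"), triplet = c("TGG"),
                      stringsAsFactors = FALSE)
  rbind(code, extra[!extra$fingerprint %in% code$fingerprint, ])
}

#' Load a recognition code from TSV
#'
#' @param path TSV with columns `fingerprint` and `triplet`.
#' @return data.frame usable by [predict_motif()].
#' @export
load_recognition_code <- function(path) {
  code <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  if (!all(c("fingerprint", "triplet") %in% names(code)))
    stop("recognition code TSV needs 'fingerprint' and 'triplet' columns")
  if (any(nchar(code$triplet) != 3L) ||
      any(!grepl("^[ACGT]{3}$", code$triplet)))
    stop("triplets must be 3 nt over ACGT")
  code
}

# fingerprint for a triplet under the default generated code (inverse map)
invert_recognition_code <- function(triplet, code = default_recognition_code()) {
  i <- match(triplet, code$triplet)
  if (anyNA(i))
    stop("recognition code is not invertible for triplet(s): ",
         paste(triplet[is.na(i)], collapse = ", "))
  code$fingerprint[i]
}

#' Predict the DNA-binding motif of a C2H2 array
#'
#' Looks each finger's fingerprint up in the recognition code and emits one
#' triplet per finger in reverse finger order (the C-terminal finger binds
#' the 5'-most triplet). Unknown fingerprints yield `NNN` and are flagged.
#' Both the emitted consensus and its reverse complement are retained,
#' since a ChIP motif may match either strand of the prediction.
#'
#' @param zfa `zf_array` from [find_c2h2()].
#' @param code recognition code data.frame (default
#'   [default_recognition_code()]).
#' @param fingers optional integer subset of finger indices to use.
#' @return Object of class `"predicted_motif"`: list with `consensus`,
#'   `revcomp`, `fingers_used`, `unknown` (logical per finger used, in
#'   emission order).
#' @export
predict_motif <- function(zfa, code = default_recognition_code(),
                          fingers = NULL) {
  stopifnot(inherits(zfa, "zf_array"))
  fp <- zfa$fingers$fingerprint
  if (is.null(fingers)) fingers <- seq_along(fp)
  if (!length(fp)) stop("zinc-finger array is empty")
  if (any(fingers < 1L | fingers > length(fp)))
    stop("finger subset out of bounds")
  use <- fp[fingers]
  trip <- code$triplet[match(use, code$fingerprint)]
  unknown <- is.na(trip)
  if (any(unknown)) {
    trip[unknown] <- "NNN"
    warning(sprintf("%d finger(s) with fingerprints absent from the code mapped to NNN",
                    sum(unknown)))
  }
  consensus <- paste(rev(trip), collapse = "")
  structure(list(consensus = consensus,
                 revcomp = if (grepl("^[ACGTN]+$", consensus))
                   reverse_complement(consensus) else consensus,
                 fingers_used = fingers,
                 unknown = rev(unknown)),
            class = "predicted_motif")
}

#' @export
print.predicted_motif <- function(x, ...) {
  cat(sprintf("Predicted motif (%d fingers): %s (revcomp %s)\n",
              length(x$fingers_used), x$consensus, x$revcomp))
  invisible(x)
}

#' Compare a predicted motif against a PBS consensus
#'
#' Slides the motif consensus ungapped along the 18-nt PBS on both strands
#' and reports the best match fraction; N positions are excluded from both
#' the numerator and the denominator. Offsets cover every full overlap of
#' the shorter sequence within the longer.
#'
#' @param motif `predicted_motif` (or a plain DNA string).
#' @param pbs `pbs_motif` (or a plain DNA string).
#' @return List with `fraction`, `offset` (0-based offset of the motif
#'   start on the PBS; negative when the motif overhangs), `strand`, and
#'   `degenerate` flag (all-N motif, fraction reported as 0).
#' @export
motif_vs_pbs <- function(motif, pbs) {
  mseq <- if (inherits(motif, "predicted_motif")) motif$consensus else
    check_sequence(motif, "dna")
  pseq <- if (inherits(pbs, "pbs_motif")) pbs$consensus else
    check_sequence(pbs, "dna")
  best <- list(fraction = 0, offset = NA_integer_, strand = NA_character_,
               degenerate = FALSE)
  if (!grepl("[ACGT]", mseq)) {
    best$degenerate <- TRUE
    return(best)
  }
  for (strand in c("+", "-")) {
    m <- if (strand == "+") mseq else reverse_complement(mseq)
    lm <- nchar(m); lp <- nchar(pseq)
    offsets <- if (lm <= lp) 0:(lp - lm) else -(lm - lp):0
    for (off in offsets) {
      if (off >= 0) {
        pw <- substr(pseq, off + 1L, off + min(lm, lp - off))
        mw <- substr(m, 1L, nchar(pw))
      } else {
        mw <- substr(m, -off + 1L, -off + lp)
        pw <- pseq
      }
      ca <- strsplit(mw, "")[[1]]
      cb <- strsplit(pw, "")[[1]]
      ok <- ca != "N" & cb != "N"
      if (!any(ok)) next
      frac <- sum(ca[ok] == cb[ok]) / sum(ok)
      if (frac > best$fraction ||
          (frac == best$fraction && is.na(best$offset))) {
        best$fraction <- frac
        best$offset <- off
        best$strand <- strand
      }
    }
  }
  best
}

#' Write fingerprints to TSV
#'
#' @param zfa `zf_array` or list of them.
#' @param path output TSV (protein_id, finger_index, start, end,
#'   fingerprint).
#' @export
write_fingerprints <- function(zfa, path) {
  arrays <- if (inherits(zfa, "zf_array")) list(zfa) else zfa
  rows <- do.call(rbind, lapply(arrays, function(z)
    if (nrow(z$fingers))
      data.frame(protein_id = z$protein_id,
                 finger_index = z$fingers$index,
                 start = z$fingers$start, end = z$fingers$end,
                 fingerprint = z$fingers$fingerprint,
                 stringsAsFactors = FALSE)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
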