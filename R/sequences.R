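#' kzfpscreen: screening KRAB zinc-finger proteins that target retroviral
#' primer-binding sites
#'
#' The package implements, stage by stage, a computational screen for KRAB
#' zinc-finger proteins (KZFPs) that recognise the 18-nt primer-binding site
#' (PBS) of endogenous retroviruses (ERVs): PBS derivation and genome
#' scanning, C2H2 fingerprint extraction and recognition-code motif
#' prediction, LTR-divergence dating, ortholog-based gene ages with a
#' co-occurrence screen, ChIP peak/PBS overlap ranking, and a two-arm
#' orchestration layer. A seeded simulator provides ground-truth inputs for
#' every stage.
#'
#' @keywords internal
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.table write.table data head
"_PACKAGE"

DNA_LETTERS <- c("A", "C", "G", "T", "N")
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Validate a sequence against an alphabet
#'
#' Sequences are plain uppercase character scalars; `alphabet` is `"dna"`
#' (ACGTN) or `"protein"` (20 amino acids plus X).
#'
#' @param x character scalar.
#' @param alphabet `"dna"` or `"protein"`.
#' @return The uppercased sequence, invisibly usable downstream.
#' @export
check_sequence <- function(x, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence must be a single character string")
  x <- toupper(x)
  if (nchar(x) == 0L) stop("sequence must be non-empty")
  letters <- if (alphabet == "dna") DNA_LETTERS else AA_LETTERS
  bad <- setdiff(unique(strsplit(x, "")[[1]]), letters)
  if (length(bad))
    stop(sprintf("invalid %s residue(s): %s", alphabet,
                 paste(bad, collapse = ", ")))
  x
}

#' Reverse complement of a DNA sequence
#'
#' @param x DNA string (ACGTN). N maps to N.
#' @return The reverse complement as a character string.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(x) {
  x <- check_sequence(x, "dna")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a FASTA file
#'
#' Thin wrapper over Biostrings returning a named character vector so the
#' rest of the package can stay alphabet-agnostic.
#'
#' @param path FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- if (alphabet == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  out <- toupper(as.character(set))
  # keep only the first whitespace-delimited token of each header
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  out
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width (default 60).
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Built-in BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix shipped with Biostrings (scores for X are
#' all non-positive), used for all protein alignments.
#'
#' @return Integer matrix with residue dimnames.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' DNA substitution matrix
#'
#' Simple match/mismatch matrix over ACGTN; N scores 0 against everything
#' (neutral handling of ambiguity).
#'
#' @param match match score (default +5).
#' @param mismatch mismatch score (default -4).
#' @return Numeric 5x5 matrix.
#' @export
dna_substitution_matrix <- function(match = 5, mismatch = -4) {
  m <- matrix(mismatch, 5, 5, dimnames = list(DNA_LETTERS, DNA_LETTERS))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by BLAST/EMBOSS (`#` comments, a
#' header row of residue letters, one labelled row per residue).
#'
#' @param path matrix file.
#' @return Numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))])
  cols <- strsplit(lines[1L], "\\s+")[[1]]
  rows <- strsplit(lines[-1L], "\\s+")
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(vapply(rows, `[`, "", 1L), cols))
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[i]][-1L]))
    if (length(vals) != length(cols) || anyNA(vals))
      stop(sprintf("malformed matrix row %d", i))
    m[i, ] <- vals
  }
  if (!isTRUE(all.equal(unname(m[cols, cols]), unname(t(m[cols, cols])))))
    stop("substitution matrix is not symmetric")
  m
}
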