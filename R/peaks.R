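#' Read a BED file of peaks
#'
#' Accepts BED3-BED6; coordinates are kept 0-based half-open. Malformed
#' lines (too few fields, non-integer or inverted coordinates) are rejected
#' with their line numbers.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing columns filled with `"."`/`0`).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line(s) with fewer than 3 fields: ",
         paste(lineno[nf < 3L], collapse = ", "))
  get <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i) f[i] else default, "")
  start <- suppressWarnings(as.integer(get(2L, NA)))
  end <- suppressWarnings(as.integer(get(3L, NA)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("non-integer coordinates on BED line(s): ",
         paste(lineno[bad], collapse = ", "))
  bad <- start >= end
  if (any(bad))
    stop("start >= end on BED line(s): ", paste(lineno[bad], collapse = ", "))
  score <- suppressWarnings(as.numeric(get(5L, "0")))
  score[is.na(score)] <- 0
  data.frame(chrom = get(1L, "."), start = start, end = end,
             name = get(4L, "."), score = score,
             strand = get(6L, "."), stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Write peaks to BED
#'
#' @param peaks data.frame as returned by [read_bed()].
#' @param path output file.
#' @export
write_bed <- function(peaks, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  write.table(peaks[intersect(cols, names(peaks))], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter peaks by score
#'
#' Strictly-greater filter used for "strong peak" selection; the
#' conventional thresholds are 500 for GFP ChIP and 300 for HA ChIP peak
#' scores.
#'
#' @param peaks peak data.frame.
#' @param min_score threshold; peaks with `score > min_score` are kept.
#' @return Filtered data.frame, input order preserved.
#' @export
filter_peaks <- function(peaks, min_score) {
  if (min_score < 0) stop("min_score must be >= 0")
  out <- peaks[peaks$score > min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

peaks_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Count peak overlaps with PBS intervals
#'
#' A peak overlaps a PBS interval when their intersection spans at least
#' `min_overlap_bp` bases (half-open coordinates, strand ignored). Each
#' peak counts once toward the overlap count even when it spans several
#' PBS intervals; the number of PBS intervals hit is reported separately.
#'
#' @param peaks peak data.frame (one KZFP).
#' @param pbs PBS intervals: data.frame with `chrom`/`seqname`, `start`,
#'   `end` (0-based half-open).
#' @param kzfp KZFP identifier for the report row.
#' @param min_overlap_bp minimum intersection width (default 1).
#' @return One-row data.frame: `kzfp`, `n_peaks`, `n_overlap`,
#'   `mean_score_at_overlap`, `n_pbs_hit`.
#' @export
count_overlaps_report <- function(peaks, pbs, kzfp = "kzfp",
                                  min_overlap_bp = 1L) {
  if (!"chrom" %in% names(pbs) && "seqname" %in% names(pbs))
    names(pbs)[names(pbs) == "seqname"] <- "chrom"
  if (nrow(peaks) == 0L || nrow(pbs) == 0L)
    return(data.frame(kzfp = kzfp, n_peaks = nrow(peaks), n_overlap = 0L,
                      mean_score_at_overlap = NA_real_, n_pbs_hit = 0L,
                      stringsAsFactors = FALSE))
  if (!any(pbs$chrom %in% peaks$chrom))
    warning("no shared chromosome names between peaks and PBS intervals")
  gp <- peaks_to_granges(peaks)
  gb <- peaks_to_granges(pbs)
  # findOverlaps repeats the disjoint-seqlevel situation as its own warning
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gp, gb,
                                minoverlap = as.integer(min_overlap_bp)))
  hit_peaks <- unique(S4Vectors::queryHits(ov))
  data.frame(kzfp = kzfp, n_peaks = nrow(peaks),
             n_overlap = length(hit_peaks),
             mean_score_at_overlap = if (length(hit_peaks))
               mean(peaks$score[hit_peaks]) else NA_real_,
             n_pbs_hit = length(unique(S4Vectors::subjectHits(ov))),
             stringsAsFactors = FALSE)
}

#' Rank KZFPs by PBS overlap
#'
#' @param reports data.frame of rows from [count_overlaps_report()].
#' @param top_n optionally keep the top N rows.
#' @return data.frame ordered by descending overlap count, ties broken by
#'   descending mean peak score at overlaps then KZFP name; a `rank`
#'   column is added.
#' @export
rank_binders <- function(reports, top_n = NULL) {
  if (!nrow(reports)) stop("need at least one report row")
  ms <- reports$mean_score_at_overlap
  ms[is.na(ms)] <- -Inf
  ord <- order(-reports$n_overlap, -ms, reports$kzfp)
  out <- reports[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(top_n)) out <- head(out, top_n)
  rownames(out) <- NULL
  out
}
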