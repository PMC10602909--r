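#' LTR divergence of a provirus
#'
#' The 5' and 3' LTRs of a provirus are identical at insertion and diverge
#' neutrally afterwards, so their pairwise divergence is a molecular clock.
#' The two LTRs are globally aligned (DNA +5/-4 matrix, end gaps free) and
#' the divergence is the raw p-distance over columns where both rows are
#' non-gap and non-N. Gap columns are excluded from numerator and
#' denominator; indel-heavy alignments (gap fraction above `max_gap_frac`)
#' are flagged low-confidence. A Jukes-Cantor corrected distance
#' (`-3/4 log(1 - 4p/3)`) is available behind `jc = TRUE`; at small
#' divergence it coincides with the raw value.
#'
#' @param ltr5,ltr3 LTR sequences (DNA strings).
#' @param min_len minimum LTR length accepted (default 50).
#' @param jc apply Jukes-Cantor correction (default FALSE: the clock
#'   calibration used downstream is stated as a linear rule).
#' @param max_gap_frac gap-column fraction above which the pair is flagged
#'   low-confidence (default 0.2).
#' @param gap_open,gap_extend alignment gap penalties.
#' @return List with `divergence`, `sites` (comparable columns),
#'   `mismatches`, `gap_fraction`, `low_confidence`.
#' @export
ltr_divergence <- function(ltr5, ltr3, min_len = 50L, jc = FALSE,
                           max_gap_frac = 0.2, gap_open = 10,
                           gap_extend = 0.5) {
  ltr5 <- check_sequence(ltr5, "dna")
  ltr3 <- check_sequence(ltr3, "dna")
  if (nchar(ltr5) < min_len || nchar(ltr3) < min_len)
    stop(sprintf("both LTRs must be at least %d nt", min_len))
  aln <- global_align(ltr5, ltr3, alphabet = "dna",
                      gap_open = gap_open, gap_extend = gap_extend,
                      end_gaps_free = TRUE)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  gap <- ca == "-" | cb == "-"
  usable <- !gap & ca != "N" & cb != "N"
  n <- sum(usable)
  if (n == 0L) stop("no comparable (non-gap, non-N) columns; divergence undefined")
  mism <- sum(ca[usable] != cb[usable])
  p <- mism / n
  if (jc) {
    if (p >= 0.75) stop("p-distance too large for Jukes-Cantor correction")
    p <- -0.75 * log(1 - 4 * p / 3)
  }
  list(divergence = p, sites = n, mismatches = mism,
       gap_fraction = mean(gap),
       low_confidence = mean(gap) > max_gap_frac)
}

#' Convert LTR divergence to insertion age
#'
#' Linear molecular-clock calibration: a divergence of 0.4% corresponds to
#' 1 million years, i.e. `age = 100 * divergence / rate`.
#'
#' @param divergence p-distance in \[0, 1\].
#' @param rate clock rate in percent divergence per Myr (default 0.4).
#' @return Age in Myr.
#' @examples
#' insertion_age(0.004)  # 1 Myr
#' @export
insertion_age <- function(divergence, rate = 0.4) {
  if (any(divergence < 0) || any(divergence > 1))
    stop("divergence must be in [0, 1]")
  if (rate <= 0) stop("rate must be positive")
  100 * divergence / rate
}

#' Invasion-time profile of an ERV subfamily
#'
#' Bins insertion ages into a histogram and reports the peak replication
#' window: the maximal contiguous run of bins, containing the modal bin,
#' whose counts are all at least 50% of the modal count.
#'
#' @param ages numeric vector of insertion ages (Myr).
#' @param bin_width histogram bin width in Myr (default 5).
#' @param peak_frac fraction of the modal count a bin must reach to extend
#'   the peak window (default 0.5).
#' @return Object of class `"invasion_profile"`: list with `ages`,
#'   `bin_width`, `breaks`, `counts`, `peak_window` (c(start, end) in Myr).
#' @export
invasion_profile <- function(ages, bin_width = 5, peak_frac = 0.5) {
  if (!length(ages)) stop("ages must be non-empty")
  if (any(ages < 0)) stop("ages must be >= 0")
  breaks <- seq(0, (floor(max(ages) / bin_width) + 1) * bin_width,
                by = bin_width)
  counts <- as.integer(table(cut(ages, breaks, right = FALSE,
                                 include.lowest = FALSE)))
  modal <- which.max(counts)
  ok <- counts >= peak_frac * counts[modal]
  lo <- modal
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- modal
  while (hi < length(counts) && ok[hi + 1L]) hi <- hi + 1L
  structure(list(ages = ages, bin_width = bin_width, breaks = breaks,
                 counts = counts,
                 peak_window = c(breaks[lo], breaks[hi + 1L])),
            class = "invasion_profile")
}

#' @export
print.invasion_profile <- function(x, ...) {
  cat(sprintf("Invasion profile: %d insertions, bin width %g Myr, peak window [%g, %g) Myr\n",
              length(x$ages), x$bin_width, x$peak_window[1], x$peak_window[2]))
  invisible(x)
}

#' Date a set of LTR pairs
#'
#' @param pairs named list of `list(ltr5 =, ltr3 =)` DNA strings, or a
#'   named character vector with ids suffixed `_5p`/`_3p`.
#' @param rate clock rate (percent per Myr).
#' @param ... passed to [ltr_divergence()].
#' @return data.frame with `erv_id`, `divergence`, `age`,
#'   `low_confidence`.
#' @export
date_ltr_pairs <- function(pairs, rate = 0.4, ...) {
  if (is.character(pairs)) pairs <- collect_ltr_pairs(pairs)
  rows <- lapply(names(pairs), function(id) {
    d <- ltr_divergence(pairs[[id]]$ltr5, pairs[[id]]$ltr3, ...)
    data.frame(erv_id = id, divergence = d$divergence,
               age = insertion_age(d$divergence, rate),
               low_confidence = d$low_confidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# pair up a FASTA-style named vector with ids suffixed _5p/_3p
collect_ltr_pairs <- function(seqs) {
  ids5 <- sub("_5p$", "", grep("_5p$", names(seqs), value = TRUE))
  ids3 <- sub("_3p$", "", grep("_3p$", names(seqs), value = TRUE))
  ids <- intersect(ids5, ids3)
  if (!length(ids)) stop("no ids with both _5p and _3p entries")
  setNames(lapply(ids, function(id)
    list(ltr5 = unname(seqs[[paste0(id, "_5p")]]),
         ltr3 = unname(seqs[[paste0(id, "_3p")]]))), ids)
}
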