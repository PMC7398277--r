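# Motif placement statistics: peak-center offsets, KS comparison of offset
# distributions, 1-40 bp co-association windows, and peak partitions by motif
# content.

#' Extract named sequences for a set of intervals
#'
#' @param genome a `genome_sequence`.
#' @param intervals data.frame with chrom/start/end.
#' @param ids names for the sequences (default `loc<i>`).
#' @return named character vector.
#' @export
interval_sequences <- function(genome, intervals, ids = NULL) {
  validate_intervals(intervals)
  if (is.null(ids)) ids <- paste0("loc", seq_len(nrow(intervals)))
  out <- vapply(seq_len(nrow(intervals)), function(i)
    genome_string(genome, as.character(intervals$chrom[i]),
                  intervals$start[i], intervals$end[i]), character(1))
  stats::setNames(out, ids)
}

#' Peak windows for scanning
#'
#' One scanning window per peak (the peak interval itself), with the peak
#' center expressed as an offset inside the window: the summit when recorded,
#' else the midpoint.
#'
#' @param collection a `peak_collection`.
#' @return data.frame (`seq_id`, `chrom`, `start`, `end`, `center`).
#' @export
peak_windows <- function(collection) {
  p <- collection$peaks
  ids <- paste0(collection$factor_id, "_p", seq_len(nrow(p)))
  data.frame(seq_id = ids, chrom = p$chrom, start = p$start, end = p$end,
             center = ifelse(p$summit >= 0, p$summit,
                             floor((p$end - p$start) / 2)))
}

#' Motif offsets from peak centers
#'
#' Signed offset of each hit's motif center (`position + floor(width/2)`)
#' from the peak center, in bp; hits whose motif center falls outside the
#' window are excluded and counted.
#'
#' @param hits data.frame from [scan_pwm()] (`seq_id`, `position`, `width`).
#' @param windows data.frame from [peak_windows()] (or any frame with
#'   `seq_id`, `center` and optionally `start`/`end` for bounds checking).
#' @return list: `offsets` (signed bp), `median_abs`, `n_excluded`.
#' @export
offset_distribution <- function(hits, windows) {
  if (!all(hits$seq_id %in% windows$seq_id))
    stop("hits reference windows absent from `windows`")
  i <- match(hits$seq_id, windows$seq_id)
  mc <- hits$position + floor(hits$width / 2)
  excl <- rep(FALSE, nrow(hits))
  if (!is.null(windows$start) && !is.null(windows$end)) {
    w <- windows$end[i] - windows$start[i]
    excl <- mc < 0 | mc >= w
  }
  off <- mc[!excl] - windows$center[i][!excl]
  list(offsets = off,
       median_abs = if (length(off)) stats::median(abs(off)) else NA_real_,
       n_excluded = sum(excl))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum ECDF difference; the p-value follows the standard
#' two-sample KS null (exact for small untied samples, Kolmogorov asymptotic
#' otherwise).
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("ks_two_sample requires at least 2 observations per sample")
  v <- sort(unique(c(a, b)))
  D <- max(abs(stats::ecdf(a)(v) - stats::ecdf(b)(v)))
  p <- suppressWarnings(stats::ks.test(a, b)$p.value)
  list(D = D, p = p)
}

#' Motif co-association within a gap window
#'
#' For each peak containing at least one primary-motif hit, another motif
#' co-occurs when some pair of hits has an edge-to-edge gap inside
#' `gap_range` bp (overlapping or book-ended hits have gap 0 and do not count
#' for the default 1-40 bp window).
#'
#' @param primary_hits hits data.frame for the primary motif.
#' @param other_hits_by_motif named list of hits data.frames.
#' @param gap_range inclusive gap bounds in bp.
#' @return data.frame (`other_motif`, `frequency`, `n_cooccurring`,
#'   `n_primary_peaks`).
#' @export
motif_cooccurrence <- function(primary_hits, other_hits_by_motif,
                               gap_range = c(1, 40)) {
  if (gap_range[1] > gap_range[2]) stop("gap_range must be (lo, hi) with lo <= hi")
  prim_peaks <- unique(primary_hits$seq_id)
  n <- length(prim_peaks)
  out <- lapply(names(other_hits_by_motif), function(om) {
    oh <- other_hits_by_motif[[om]]
    co <- 0L
    for (pk in prim_peaks) {
      ph <- primary_hits[primary_hits$seq_id == pk, , drop = FALSE]
      o2 <- oh[oh$seq_id == pk, , drop = FALSE]
      if (!nrow(o2)) next
      found <- FALSE
      for (r in seq_len(nrow(ph))) {
        gap <- pmax(o2$position - (ph$position[r] + ph$width[r]),
                    ph$position[r] - (o2$position + o2$width))
        if (any(gap >= gap_range[1] & gap <= gap_range[2])) { found <- TRUE; break }
      }
      co <- co + found
    }
    data.frame(other_motif = om, frequency = if (n) co / n else NA_real_,
               n_cooccurring = co, n_primary_peaks = n)
  })
  do.call(rbind, out)
}

#' Partition peaks by primary/partner motif content
#'
#' Scans the peak sequences with both motifs and reports the mutually
#' exclusive fractions (both, primary_only, partner_only, neither), which sum
#' to 1. With no primary motif (factor without a known motif) a flagged
#' three-way partition is returned.
#'
#' @param sequences named character vector of peak sequences.
#' @param primary_pwm `pwm_motif` or NULL.
#' @param partner_pwm `pwm_motif`.
#' @param background,p_threshold scan parameters (see [scan_pwm()]).
#' @return list: `fractions` (named, sums to 1), `three_way` flag, `n_peaks`.
#' @export
peak_motif_partition <- function(sequences, primary_pwm, partner_pwm,
                                 background = NULL, p_threshold = 1e-4) {
  ids <- names(sequences)
  if (is.null(ids)) { ids <- paste0("p", seq_along(sequences)); names(sequences) <- ids }
  has_partner <- ids %in% unique(scan_pwm(partner_pwm, sequences, background,
                                          p_threshold)$seq_id)
  if (is.null(primary_pwm)) {
    f <- c(partner_only = mean(has_partner), neither = mean(!has_partner))
    return(list(fractions = f, three_way = TRUE, n_peaks = length(sequences)))
  }
  has_primary <- ids %in% unique(scan_pwm(primary_pwm, sequences, background,
                                          p_threshold)$seq_id)
  f <- c(both = mean(has_primary & has_partner),
         primary_only = mean(has_primary & !has_partner),
         partner_only = mean(!has_primary & has_partner),
         neither = mean(!has_primary & !has_partner))
  list(fractions = f, three_way = FALSE, n_peaks = length(sequences))
}
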