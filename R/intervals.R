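# Interval primitives. All coordinates are 0-based half-open [start, end),
# the BED convention; `chrom` is a plain string. Intervals travel as
# data.frames with columns chrom/start/end (extra columns pass through where
# documented).

#' Validate an interval data.frame
#'
#' Checks the basic interval invariants: required columns, non-empty
#' chromosome names, integer-valued coordinates and 0 <= start < end.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x` invisibly, with coordinates coerced to integer-valued numerics.
#' @export
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) stop(what, " must be a data.frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(what, " missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom))))
    stop(what, ": chrom must be non-empty")
  s <- x$start; e <- x$end
  if (any(is.na(s)) || any(is.na(e)) || any(s != floor(s)) || any(e != floor(e)))
    stop(what, ": start/end must be integer-valued")
  if (any(s < 0)) stop(what, ": start must be >= 0")
  if (any(s >= e)) stop(what, ": requires start < end for every record")
  invisible(x)
}

#' Sort intervals
#'
#' Deterministic sort by (chrom lexicographic, start, end, name when present),
#' using a locale-independent (C) ordering of chromosome names.
#'
#' @param x interval data.frame.
#' @return `x` reordered.
#' @export
sort_intervals <- function(x) {
  if (nrow(x) == 0) return(x)
  keys <- list(as.character(x$chrom), x$start, x$end)
  if (!is.null(x$name)) keys <- c(keys, list(as.character(x$name)))
  o <- do.call(order, c(keys, list(method = "radix")))
  x[o, , drop = FALSE]
}

is_sorted_intervals <- function(x) {
  if (nrow(x) < 2) return(TRUE)
  o <- order(as.character(x$chrom), x$start, x$end, method = "radix")
  all(o == seq_len(nrow(x)))
}

parse_size_rule <- function(size_rule) {
  if (is.null(size_rule) || identical(size_rule, "none"))
    return(list(mode = "none", width = NA_real_))
  if (!is.character(size_rule) || length(size_rule) != 1)
    stop("size_rule must be 'none', 'cap:W' or 'filter:W'")
  m <- regmatches(size_rule, regexec("^(cap|filter):([0-9]+)$", size_rule))[[1]]
  if (length(m) != 3) stop("unrecognised size_rule: ", size_rule)
  w <- as.numeric(m[3])
  if (w <= 0) stop("size_rule width must be > 0")
  list(mode = m[2], width = w)
}

# union merge of one chromosome's sorted intervals; merging requires >= 1 bp
# shared base, so book-ended intervals stay separate
merge_chrom_none <- function(s, e) {
  out_s <- numeric(0); out_e <- numeric(0)
  cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] < ce) ce <- max(ce, e[i]) else { out_s <- c(out_s, cs); out_e <- c(out_e, ce); cs <- s[i]; ce <- e[i] }
  }
  cbind(c(out_s, cs), c(out_e, ce))
}

# cap:W — left-to-right merge, but an interval that would push the current
# locus beyond width W closes it; the new locus starts where the old one ends
# so every covered base lands in exactly one locus, and any locus that still
# exceeds W (a single wide input) is chopped at W boundaries
merge_chrom_cap <- function(s, e, w) {
  out_s <- numeric(0); out_e <- numeric(0)
  emit <- function(cs, ce) {
    while (ce - cs > w) { out_s <<- c(out_s, cs); out_e <<- c(out_e, cs + w); cs <- cs + w }
    out_s <<- c(out_s, cs); out_e <<- c(out_e, ce)
  }
  cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] >= ce) { emit(cs, ce); cs <- s[i]; ce <- e[i]; next }
    if (max(ce, e[i]) - cs <= w) { ce <- max(ce, e[i]); next }
    # overflow implies e[i] > ce (the running locus is <= w wide), so the new
    # locus [ce, e[i]) is non-empty and keeps the base partition exact
    emit(cs, ce)
    cs <- ce
    ce <- e[i]
  }
  emit(cs, ce)
  cbind(out_s, out_e)
}

#' Merge genomic intervals with an optional size rule
#'
#' Union-merges intervals that share at least one base. `size_rule` bounds
#' merged locus width: `"filter:W"` drops merged loci wider than `W` bp
#' (the ~1\% of >2 kb merges excluded from downstream co-binding analysis);
#' `"cap:W"` starts a new locus whenever an incoming peak would extend the
#' current one beyond `W` bp, so loci never exceed the maximum merged size.
#'
#' @param intervals data.frame with chrom/start/end.
#' @param size_rule `"none"`, `"cap:W"` or `"filter:W"` (e.g. `"filter:2000"`).
#' @return sorted, non-overlapping interval data.frame.
#' @export
merge_intervals <- function(intervals, size_rule = "none") {
  validate_intervals(intervals)
  rule <- parse_size_rule(size_rule)
  if (nrow(intervals) == 0)
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  x <- sort_intervals(intervals[, c("chrom", "start", "end")])
  res <- lapply(split(x, factor(x$chrom, levels = unique(x$chrom))), function(d) {
    m <- if (rule$mode == "cap") merge_chrom_cap(d$start, d$end, rule$width)
         else merge_chrom_none(d$start, d$end)
    data.frame(chrom = d$chrom[1], start = m[, 1], end = m[, 2])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (rule$mode == "filter") out <- out[out$end - out$start <= rule$width, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition merged intervals into fixed-width windows
#'
#' Splits each merged interval into consecutive windows of `width` bp anchored
#' at the interval start; a final partial window is kept. The union of windows
#' equals the union of inputs base-for-base.
#'
#' @param merged_intervals sorted, non-overlapping intervals.
#' @param width window width in bp (default 2000, the 2-kb windows used for
#'   occupancy matrices).
#' @return interval data.frame of windows.
#' @export
window_partition <- function(merged_intervals, width = 2000) {
  validate_intervals(merged_intervals)
  if (width <= 0 || width != floor(width)) stop("width must be a positive integer")
  if (!is_sorted_intervals(merged_intervals)) stop("window_partition requires sorted input")
  if (nrow(merged_intervals) == 0) return(merged_intervals[, c("chrom", "start", "end")])
  n_win <- ceiling((merged_intervals$end - merged_intervals$start) / width)
  idx <- rep(seq_len(nrow(merged_intervals)), n_win)
  off <- (sequence(n_win) - 1) * width
  s <- merged_intervals$start[idx] + off
  e <- pmin(s + width, merged_intervals$end[idx])
  data.frame(chrom = as.character(merged_intervals$chrom[idx]), start = s, end = e)
}

#' Intersect two sorted interval sets
#'
#' Reports every pair of intervals sharing at least one base (half-open
#' convention: end-abutting intervals do not overlap), with the overlap length,
#' in BEDtools-style semantics.
#'
#' @param a,b sorted interval data.frames.
#' @return data.frame with `a_idx`, `b_idx` (row indices into the inputs),
#'   `chrom` and `overlap` (bp).
#' @export
intersect_intervals <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (!is_sorted_intervals(a) || !is_sorted_intervals(b))
    stop("intersect_intervals requires sorted inputs")
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(a_idx = integer(0), b_idx = integer(0),
                      chrom = character(0), overlap = numeric(0)))
  a$.ai <- seq_len(nrow(a)); b$.bi <- seq_len(nrow(b))
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- lapply(chroms, function(ch) {
    da <- a[a$chrom == ch, , drop = FALSE]; db <- b[b$chrom == ch, , drop = FALSE]
    ra <- IRanges::IRanges(start = da$start + 1, end = da$end)
    rb <- IRanges::IRanges(start = db$start + 1, end = db$end)
    h <- IRanges::findOverlaps(ra, rb, minoverlap = 1)
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    if (!length(qi)) return(NULL)
    ov <- pmin(da$end[qi], db$end[si]) - pmax(da$start[qi], db$start[si])
    data.frame(a_idx = da$.ai[qi], b_idx = db$.bi[si], chrom = ch, overlap = ov)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(a_idx = integer(0), b_idx = integer(0),
                                      chrom = character(0), overlap = numeric(0))
  rownames(out) <- NULL
  out[order(out$a_idx, out$b_idx), , drop = FALSE]
}

# index of the locus (sorted, non-overlapping, same chrom set) containing each
# point; NA when the point falls outside every locus
locate_points <- function(loci, chrom, pos) {
  res <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    li <- which(loci$chrom == ch)
    if (!length(li)) next
    pi <- which(chrom == ch)
    k <- findInterval(pos[pi], loci$start[li])
    ok <- k >= 1 & pos[pi] < loci$end[li][pmax(k, 1)]
    res[pi[ok]] <- li[k[ok]]
  }
  res
}
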