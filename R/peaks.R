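# Peak collections: one factor's called peaks in ENCODE narrowPeak layout
# (BED6+4; column 10 is the summit offset from peak start, -1 when unknown).

NARROWPEAK_COLS <- c("chrom", "start", "end", "name", "score", "strand",
                     "signal", "pvalue", "qvalue", "summit")

#' Construct a peak collection
#'
#' Validates narrowPeak invariants (0 <= start < end; summit offset -1 or
#' inside the peak) and stores peaks sorted by (chrom, start, end, name).
#'
#' @param factor_id assayed factor identifier.
#' @param peaks data.frame with at least chrom/start/end; missing narrowPeak
#'   columns are filled with defaults (summit -1, strand ".").
#' @param genome optional `genome_sequence`; records on chromosomes absent
#'   from it, or outside its bounds, are rejected with an error.
#' @return a `peak_collection`.
#' @export
peak_collection <- function(factor_id, peaks, genome = NULL) {
  stopifnot(is.character(factor_id), length(factor_id) == 1)
  if (nrow(peaks) > 0) validate_intervals(peaks, "peaks")
  defaults <- list(name = ".", score = 0, strand = ".", signal = 0,
                   pvalue = -1, qvalue = -1, summit = -1)
  for (col in names(defaults))
    if (is.null(peaks[[col]])) peaks[[col]] <- rep(defaults[[col]], length.out = nrow(peaks))
  peaks <- peaks[, NARROWPEAK_COLS, drop = FALSE]
  peaks$chrom <- as.character(peaks$chrom)
  if (nrow(peaks) > 0) {
    bad <- peaks$summit != -1 & (peaks$summit < 0 | peaks$start + peaks$summit >= peaks$end)
    if (any(bad)) stop("summit offset outside peak for ", sum(bad), " record(s)")
    if (!is.null(genome)) check_genome_interval(genome, peaks$chrom, peaks$start, peaks$end)
  }
  peaks <- sort_intervals(peaks)
  rownames(peaks) <- NULL
  structure(list(factor_id = factor_id, peaks = peaks), class = "peak_collection")
}

#' Read an ENCODE narrowPeak file
#'
#' @param path narrowPeak path (10 tab-separated columns; may be empty).
#' @param factor_id factor identifier to attach.
#' @param genome optional `genome_sequence` used to reject out-of-genome
#'   records.
#' @return a `peak_collection`, sorted.
#' @export
read_narrowpeak <- function(path, factor_id, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(peak_collection(factor_id, data.frame(chrom = character(0),
                                                 start = numeric(0), end = numeric(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10))
    stop("malformed narrowPeak record at line ", which(nf != 10)[1],
         ": expected 10 tab-separated columns, got ", nf[nf != 10][1])
  m <- do.call(rbind, fields)
  peaks <- data.frame(chrom = m[, 1],
                      start = as.numeric(m[, 2]), end = as.numeric(m[, 3]),
                      name = m[, 4], score = as.numeric(m[, 5]), strand = m[, 6],
                      signal = as.numeric(m[, 7]), pvalue = as.numeric(m[, 8]),
                      qvalue = as.numeric(m[, 9]), summit = as.numeric(m[, 10]))
  peak_collection(factor_id, peaks, genome = genome)
}

fmt_num <- function(x) {
  # deterministic, locale-free numeric formatting (no scientific notation)
  ifelse(x == floor(x), sprintf("%d", as.integer(x)),
         sub("0+$", "", sprintf("%.6f", x)))
}

#' Write a peak collection as narrowPeak
#'
#' Deterministic serialization: `read_narrowpeak(write_narrowpeak(x))` is the
#' identity field-for-field, and writing twice is byte-identical.
#'
#' @param collection a `peak_collection`.
#' @param path output path.
#' @export
write_narrowpeak <- function(collection, path) {
  stopifnot(inherits(collection, "peak_collection"))
  p <- collection$peaks
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(p) > 0) {
    out <- paste(p$chrom, fmt_num(p$start), fmt_num(p$end), p$name, fmt_num(p$score),
                 p$strand, fmt_num(p$signal), fmt_num(p$pvalue), fmt_num(p$qvalue),
                 fmt_num(p$summit), sep = "\t")
    writeLines(out, con)
  }
  invisible(path)
}

#' Peak anchor positions
#'
#' The analysis anchor of each peak: the summit when recorded, otherwise the
#' midpoint `floor((start + end) / 2)`.
#'
#' @param collection a `peak_collection`.
#' @return numeric vector of absolute positions (0-based).
#' @export
peak_centers <- function(collection) {
  p <- collection$peaks
  ifelse(p$summit >= 0, p$start + p$summit, floor((p$start + p$end) / 2))
}

#' @export
print.peak_collection <- function(x, ...) {
  cat("peak_collection:", x$factor_id, "-", nrow(x$peaks), "peak(s)\n")
  invisible(x)
}

#' Read a BED4 chromatin-state segmentation
#'
#' Overlapping or book-ended segments with the same state label are merged;
#' overlapping segments with different labels are an error; every label must
#' appear in `class_map`.
#'
#' @param path BED4 file (chrom, start, end, state_label).
#' @param class_map named character vector mapping state labels to element
#'   classes (`promoter`, `strong_enhancer`, `weak_enhancer`, `other`).
#' @return a `state_segmentation`.
#' @export
read_segmentation <- function(path, class_map) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "state"),
                         colClasses = c("character", "numeric", "numeric", "character"))
  state_segmentation(d, class_map)
}

#' Construct a chromatin-state segmentation
#'
#' @param segments data.frame with chrom/start/end/state.
#' @param class_map named character vector state -> element class.
#' @return a `state_segmentation` with sorted, non-overlapping segments.
#' @export
state_segmentation <- function(segments, class_map) {
  validate_intervals(segments, "segments")
  if (is.null(segments$state)) stop("segments require a state column")
  known_classes <- c("promoter", "strong_enhancer", "weak_enhancer", "other")
  if (!all(class_map %in% known_classes))
    stop("class_map values must be one of: ", paste(known_classes, collapse = ", "))
  miss <- setdiff(unique(segments$state), names(class_map))
  if (length(miss))
    stop("state label(s) missing from class_map: ", paste(miss, collapse = ", "))
  segments <- sort_intervals(segments)
  # merge same-label overlapping/abutting runs; reject cross-label overlap
  out <- lapply(split(segments, factor(segments$chrom, levels = unique(segments$chrom))),
    function(d) {
      keep_s <- numeric(0); keep_e <- numeric(0); keep_l <- character(0)
      cs <- d$start[1]; ce <- d$end[1]; cl <- d$state[1]
      for (i in seq_len(nrow(d))[-1]) {
        if (d$start[i] < ce && d$state[i] != cl)
          stop("overlapping segments with different labels ('", cl, "' vs '",
               d$state[i], "') on ", d$chrom[1])
        if (d$start[i] <= ce && d$state[i] == cl) { ce <- max(ce, d$end[i]); next }
        keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce); keep_l <- c(keep_l, cl)
        cs <- d$start[i]; ce <- d$end[i]; cl <- d$state[i]
      }
      data.frame(chrom = d$chrom[1], start = c(keep_s, cs), end = c(keep_e, ce),
                 state = c(keep_l, cl))
    })
  segments <- do.call(rbind, out)
  rownames(segments) <- NULL
  structure(list(segments = segments, class_map = class_map),
            class = "state_segmentation")
}

#' Write a segmentation as BED4
#' @param segmentation a `state_segmentation`.
#' @param path output path.
#' @export
write_segmentation <- function(segmentation, path) {
  s <- segmentation$segments
  writeLines(paste(s$chrom, fmt_num(s$start), fmt_num(s$end), s$state, sep = "\t"), path)
  invisible(path)
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat("state_segmentation:", nrow(x$segments), "segment(s),",
      length(unique(x$segments$state)), "state label(s)\n")
  invisible(x)
}
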