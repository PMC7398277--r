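# Genome sequence container. Sequences are held as integer code vectors
# (A=1, C=2, G=3, T=4, N=0) with a per-base logical repeat flag taken from
# soft-masking (lowercase in FASTA). Cumulative GC and repeat counts make
# interval composition queries O(1), which the matched-null sampler leans on.

BASE_CHARS <- c("A", "C", "G", "T")

new_genome_sequence <- function(codes, masks) {
  stopifnot(is.list(codes), is.list(masks), identical(names(codes), names(masks)))
  lens <- vapply(codes, length, integer(1))
  cum_gc <- lapply(codes, function(v) cumsum(as.integer(v == 2L | v == 3L)))
  cum_rep <- lapply(masks, function(v) cumsum(as.integer(v)))
  structure(list(chroms = names(codes), lengths = lens, code = codes,
                 mask = masks, cum_gc = cum_gc, cum_rep = cum_rep),
            class = "genome_sequence")
}

#' Read a soft-masked FASTA genome
#'
#' Lowercase bases are flagged as repeat-masked and upper-cased for all
#' sequence queries; `N` is allowed (code 0). Duplicate sequence names are an
#' error.
#'
#' @param path FASTA file.
#' @return a `genome_sequence` object.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate sequence name in FASTA: ",
                              nm[duplicated(nm)][1])
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt("N")] <- 0L; lut[utf8ToInt("n")] <- 0L
  lower <- utf8ToInt("a"):utf8ToInt("z")
  codes <- list(); masks <- list()
  for (i in seq_along(ss)) {
    raw <- utf8ToInt(as.character(ss[[i]]))
    code <- lut[raw]
    if (anyNA(code)) stop("invalid base character in sequence ", nm[i])
    codes[[nm[i]]] <- code
    masks[[nm[i]]] <- raw %in% lower
  }
  new_genome_sequence(codes, masks)
}

#' Write a genome to soft-masked FASTA
#'
#' @param genome a `genome_sequence`.
#' @param path output path.
#' @param line_width bases per line.
#' @export
write_fasta <- function(genome, path, line_width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in genome$chroms) {
    s <- genome_string(genome, ch, 0, genome$lengths[[ch]], soft_mask = TRUE)
    writeLines(paste0(">", ch), con)
    n <- nchar(s)
    starts <- seq(1, n, by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1, n)), con)
  }
  invisible(path)
}

check_genome_interval <- function(genome, chrom, start, end) {
  bad <- !(chrom %in% genome$chroms)
  if (any(bad)) stop("chromosome absent from genome: ", unique(chrom[bad])[1])
  len <- genome$lengths[chrom]
  if (any(start < 0) || any(end > len)) stop("interval outside chromosome bounds")
  invisible(NULL)
}

#' Extract an uppercase subsequence
#'
#' @param genome a `genome_sequence`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @param soft_mask lowercase repeat-masked bases in the output.
#' @return a character scalar.
#' @export
genome_string <- function(genome, chrom, start, end, soft_mask = FALSE) {
  check_genome_interval(genome, chrom, start, end)
  code <- genome$code[[chrom]][(start + 1):end]
  chars <- c("N", BASE_CHARS)[code + 1L]
  if (soft_mask) {
    m <- genome$mask[[chrom]][(start + 1):end]
    chars[m] <- tolower(chars[m])
  }
  paste(chars, collapse = "")
}

#' Integer base codes of an interval
#' @inheritParams genome_string
#' @return integer vector (A=1, C=2, G=3, T=4, N=0).
#' @export
genome_codes <- function(genome, chrom, start, end) {
  check_genome_interval(genome, chrom, start, end)
  genome$code[[chrom]][(start + 1):end]
}

cum_range <- function(cum, start, end) {
  # sum over 0-based half-open [start, end) of the per-base indicator
  cum[end] - ifelse(start > 0, cum[start], 0L)
}

#' GC fraction of intervals
#' @param genome a `genome_sequence`.
#' @param intervals data.frame with chrom/start/end.
#' @return numeric vector of GC fractions (N counts in the denominator).
#' @export
interval_gc <- function(genome, intervals) {
  validate_intervals(intervals)
  vapply(seq_len(nrow(intervals)), function(i) {
    ch <- as.character(intervals$chrom[i])
    check_genome_interval(genome, ch, intervals$start[i], intervals$end[i])
    cum_range(genome$cum_gc[[ch]], intervals$start[i], intervals$end[i]) /
      (intervals$end[i] - intervals$start[i])
  }, numeric(1))
}

#' Repeat-masked fraction of intervals
#' @inheritParams interval_gc
#' @return numeric vector of soft-masked base fractions.
#' @export
interval_repeat_fraction <- function(genome, intervals) {
  validate_intervals(intervals)
  vapply(seq_len(nrow(intervals)), function(i) {
    ch <- as.character(intervals$chrom[i])
    check_genome_interval(genome, ch, intervals$start[i], intervals$end[i])
    cum_range(genome$cum_rep[[ch]], intervals$start[i], intervals$end[i]) /
      (intervals$end[i] - intervals$start[i])
  }, numeric(1))
}

#' Read a chrom.sizes file (2-column TSV)
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "integer"))
  stats::setNames(d$size, d$chrom)
}

#' Write a chrom.sizes file
#' @param genome a `genome_sequence`.
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(data.frame(genome$chroms, unname(genome$lengths)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence:", length(x$chroms), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp\n")
  invisible(x)
}
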