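# Position weight matrices and the MEME minimal motif format.

#' Construct a position weight matrix motif
#'
#' @param id unique motif identifier.
#' @param matrix numeric matrix, L columns x 4 rows (A, C, G, T order), each
#'   column a probability vector. Columns whose sum deviates by more than 0.01
#'   from 1 are an error; smaller deviations are renormalized.
#' @param factor_annotation factor the motif is annotated to ("" if none).
#' @param source free-text provenance.
#' @return a `pwm_motif`.
#' @export
pwm_motif <- function(id, matrix, factor_annotation = "", source = "") {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  m <- as.matrix(matrix)
  if (nrow(m) != 4) stop("PWM matrix must have 4 rows (A,C,G,T)")
  if (ncol(m) < 1) stop("PWM must have at least one column")
  if (any(m < 0)) stop("PWM probabilities must be non-negative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 0.01))
    stop("PWM column sum deviates from 1 by more than 0.01 in motif ", id)
  m <- sweep(m, 2, cs, "/")
  rownames(m) <- c("A", "C", "G", "T")
  structure(list(id = id, factor_annotation = factor_annotation,
                 matrix = m, source = source), class = "pwm_motif")
}

#' Motif length (columns)
#' @param pwm a `pwm_motif`.
#' @export
pwm_length <- function(pwm) ncol(pwm$matrix)

#' Reverse complement of a PWM
#'
#' Column order reversed and A/T, C/G probabilities swapped within each
#' column; an involution.
#'
#' @param pwm a `pwm_motif`.
#' @return a `pwm_motif` (same id, `source` notes the orientation flip).
#' @export
reverse_complement <- function(pwm) {
  m <- pwm$matrix[c(4, 3, 2, 1), rev(seq_len(ncol(pwm$matrix))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  structure(list(id = pwm$id, factor_annotation = pwm$factor_annotation,
                 matrix = m, source = pwm$source), class = "pwm_motif")
}

#' GC content of a motif
#'
#' Mean probability of G or C across columns.
#'
#' @param pwm a `pwm_motif`.
#' @return fraction in [0, 1].
#' @export
motif_gc_content <- function(pwm) {
  mean(pwm$matrix["G", ] + pwm$matrix["C", ])
}

#' Information content of a motif (bits)
#'
#' Sum over columns of 2 - H(column), the usual small-sample-uncorrected IC.
#'
#' @param pwm a `pwm_motif`.
#' @return total IC in bits.
#' @export
motif_ic <- function(pwm) {
  p <- pwm$matrix
  h <- apply(p, 2, function(col) { col <- col[col > 0]; -sum(col * log2(col)) })
  sum(2 - h)
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat("pwm_motif:", x$id, "- length", ncol(x$matrix),
      sprintf("(IC %.1f bits)", motif_ic(x)),
      if (nzchar(x$factor_annotation)) paste0("[", x$factor_annotation, "]") else "", "\n")
  invisible(x)
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections over the
#' ACGT alphabet. Column probabilities are renormalized to sum to 1 (within
#' 1e-6); sums off by more than 0.01 and duplicate motif ids are errors.
#'
#' @param path MEME minimal file.
#' @return named list of `pwm_motif` objects.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  idx <- grep("^MOTIF\\b", lines)
  if (!length(idx)) return(stats::setNames(list(), character(0)))
  motifs <- list()
  bounds <- c(idx, length(lines) + 1)
  for (k in seq_along(idx)) {
    header <- strsplit(trimws(lines[idx[k]]), "\\s+")[[1]]
    id <- header[2]
    if (is.na(id)) stop("MOTIF line without identifier at line ", idx[k])
    alt <- if (length(header) >= 3) header[3] else ""
    block <- lines[idx[k]:(bounds[k + 1] - 1)]
    li <- grep("letter-probability matrix", block)
    if (!length(li)) stop("motif ", id, " has no letter-probability matrix")
    rows <- character(0)
    for (j in (li[1] + 1):length(block)) {
      ln <- trimws(block[j])
      if (!nzchar(ln)) { if (length(rows)) break else next }
      if (!grepl("^[-0-9.eE+ \t]+$", ln)) break
      rows <- c(rows, ln)
    }
    if (!length(rows)) stop("empty probability matrix for motif ", id)
    vals <- lapply(strsplit(rows, "\\s+"), as.numeric)
    if (any(lengths(vals) != 4)) stop("motif ", id, ": expected 4 probabilities per row")
    m <- t(do.call(rbind, vals))  # rows of file are positions -> columns of PWM
    if (id %in% names(motifs)) stop("duplicate motif id: ", id)
    motifs[[id]] <- pwm_motif(id, m, factor_annotation = alt, source = path)
  }
  motifs
}

#' Write motifs in MEME minimal format
#'
#' Round-trips with [read_meme_motifs()] preserving probabilities to 1e-6.
#'
#' @param motifs list of `pwm_motif` objects.
#' @param path output path.
#' @param background background letter frequencies (length 4).
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1], background[2],
                       background[3], background[4]), ""), con)
  for (m in motifs) {
    hdr <- if (nzchar(m$factor_annotation)) paste("MOTIF", m$id, m$factor_annotation)
           else paste("MOTIF", m$id)
    writeLines(hdr, con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m$matrix)), con)
    writeLines(apply(m$matrix, 2, function(col) sprintf("%.6f %.6f %.6f %.6f",
                                                        col[1], col[2], col[3], col[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a motif-to-factor annotation table
#' @param path 2-column TSV (motif_id, factor_id), no header.
#' @return data.frame with columns motif_id, factor_id.
#' @export
read_motif_annotation <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("motif_id", "factor_id"),
                    colClasses = c("character", "character"))
}
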