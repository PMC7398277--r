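# HOT (high-occupancy target) regions: detection above a strict occupancy
# threshold, state composition, subsampling motif-recovery curves, the
# PWM-percentile anchor/degenerate profile, and expression by co-occupancy.

#' Detect HOT regions in an occupancy matrix
#'
#' A locus is HOT when strictly more than the resolved threshold of distinct
#' factors occupy it: the "more than 70 CAPs within a 2-kb region" rule, with
#' the fractional form resolved as `ceiling(fraction * n_factors)` against
#' the factors actually assayed.
#'
#' @param occupancy an `occupancy_matrix` built with a size rule bounding loci
#'   at 2 kb.
#' @param threshold absolute factor count (strict lower bound), or NULL to
#'   use `fraction`.
#' @param fraction fraction of assayed factors (e.g. 1/3).
#' @return a `hot_call_set`: list(loci [with n_factors], factor_sets,
#'   locus_idx, threshold, provenance).
#' @export
detect_hot <- function(occupancy, threshold = 70, fraction = NULL) {
  n_fac <- length(occupancy$factors)
  resolved <- if (!is.null(fraction)) ceiling(fraction * n_fac) else threshold
  if (resolved >= n_fac)
    warning("threshold (", resolved, ") is not below the number of assayed factors")
  counts <- rowSums(occupancy$values)
  idx <- which(counts > resolved)
  loci <- occupancy$loci[idx, , drop = FALSE]
  loci$n_factors <- counts[idx]
  rownames(loci) <- NULL
  factor_sets <- lapply(idx, function(i)
    occupancy$factors[occupancy$values[i, ] == 1L])
  structure(list(loci = loci, factor_sets = factor_sets, locus_idx = idx,
                 threshold = resolved,
                 provenance = occupancy$provenance), class = "hot_call_set")
}

#' @export
print.hot_call_set <- function(x, ...) {
  cat("hot_call_set:", nrow(x$loci), "HOT loci ( >", x$threshold, "factors )\n")
  invisible(x)
}

#' Write HOT calls as BED6 (name = factor count)
#' @param hot a `hot_call_set`.
#' @param path output path.
#' @export
write_hot_bed <- function(hot, path) {
  l <- hot$loci
  writeLines(paste(l$chrom, fmt_num(l$start), fmt_num(l$end),
                   l$n_factors, 0, ".", sep = "\t"), path)
  invisible(path)
}

#' Chromatin-state class composition of HOT regions
#'
#' Majority-state annotation of each HOT locus, tabulated by element class;
#' fractions sum to 1 (unannotated loci count as "other").
#'
#' @param hot a `hot_call_set`.
#' @param segmentation a `state_segmentation`.
#' @return named fractions over promoter/strong_enhancer/weak_enhancer/other.
#' @export
hot_state_composition <- function(hot, segmentation) {
  ann <- annotate_loci(hot$loci[, c("chrom", "start", "end")], segmentation)
  cls <- ifelse(ann$state == "unannotated", "other",
                unname(segmentation$class_map[ann$state]))
  lv <- c("promoter", "strong_enhancer", "weak_enhancer", "other")
  vapply(lv, function(x) mean(cls == x), numeric(1))
}

#' Subsampling motif-recovery curves for HOT regions
#'
#' For each subsample size k, repeatedly draws k factors without replacement
#' and asks (i) how often each HOT locus is identified as bound by strictly
#' more than `identify_fraction` of the subsample and (ii) among identified
#' loci, the fraction containing >= 1, >= 2 and >= 3 planted motifs of the
#' subsampled factors. Median/min/max over iterations are reported per k.
#'
#' @param occupancy the full `occupancy_matrix`.
#' @param hot a `hot_call_set` derived from it.
#' @param motif_presence logical HOT-loci x factors matrix: does the factor's
#'   motif occur at the locus (factors without motifs all-FALSE).
#' @param k_grid subsample sizes; defaults to 12..162 in steps of 10 (clipped
#'   to the factor count, which is always included so recovery reaches 1).
#' @param iterations iterations per k.
#' @param identify_fraction strict identification fraction (default 1/3).
#' @param seed RNG seed.
#' @return data.frame (k, metric, median, min, max); metrics are
#'   `identification`, `ge1`, `ge2`, `ge3`.
#' @export
subsample_recovery <- function(occupancy, hot, motif_presence, k_grid = NULL,
                               iterations = 100, identify_fraction = 1/3,
                               seed = 1) {
  n_fac <- length(occupancy$factors)
  if (is.null(k_grid)) k_grid <- seq(12, 162, by = 10)
  if (any(k_grid > n_fac))
    warning("grid points above the factor count were skipped")
  k_grid <- sort(unique(c(k_grid[k_grid <= n_fac], n_fac)))
  occ_hot <- occupancy$values[hot$locus_idx, , drop = FALSE]
  mp <- motif_presence
  stopifnot(nrow(mp) == nrow(occ_hot), ncol(mp) == n_fac)
  with_seed(seed, {
    out <- lapply(k_grid, function(k) {
      met <- matrix(NA_real_, iterations, 4,
                    dimnames = list(NULL, c("identification", "ge1", "ge2", "ge3")))
      for (it in seq_len(iterations)) {
        fs <- sample.int(n_fac, k)
        cnt <- rowSums(occ_hot[, fs, drop = FALSE])
        ident <- cnt > identify_fraction * k
        met[it, 1] <- mean(ident)
        if (any(ident)) {
          mm <- rowSums(mp[ident, fs, drop = FALSE])
          met[it, 2:4] <- c(mean(mm >= 1), mean(mm >= 2), mean(mm >= 3))
        }
      }
      do.call(rbind, lapply(colnames(met), function(m) {
        v <- met[, m]
        data.frame(k = k, metric = m,
                   median = stats::median(v, na.rm = TRUE),
                   min = suppressWarnings(min(v, na.rm = TRUE)),
                   max = suppressWarnings(max(v, na.rm = TRUE)))
      }))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

# best PWM log-odds score (bits) per sequence over both strands
best_pwm_scores <- function(pwm, code_list, background, bin_bits = 0.01) {
  tp <- pwm_score_table(pwm, background, bin_bits)
  tm <- pwm_score_table(reverse_complement(pwm), background, bin_bits)
  vapply(code_list, function(v) {
    if (length(v) < pwm_length(pwm)) return(-Inf)
    s1 <- score_positions(tp$int_scores, v)
    s2 <- score_positions(tm$int_scores, v)
    m <- suppressWarnings(max(c(s1, s2), na.rm = TRUE))
    if (is.finite(m)) m * bin_bits else -Inf
  }, numeric(1))
}

#' Strong/weak motif profile of HOT loci (PWM-percentile analog)
#'
#' Scans every factor's PWM over the HOT loci plus a GC/repeat-matched
#' background locus panel, percentile-ranks each factor's best per-locus
#' scores across all scanned loci, and counts, per HOT locus, the occupying
#' factors whose percentile reaches `strong_percentile` (strong) or lies in
#' `[weak_percentile, strong_percentile)` (weak). This is a declared
#' PWM-percentile analog of sequence-model scoring of HOT sites, not a
#' reproduction of it; percentiles make the profile invariant to monotone
#' transforms of the raw scores.
#'
#' @param hot a `hot_call_set`.
#' @param pwms_by_factor named list of `pwm_motif` (factors without a PWM are
#'   excluded and listed).
#' @param genome a `genome_sequence`.
#' @param strong_percentile,weak_percentile percentile cut points (0-100).
#' @param background_fold background panel size as a multiple of the HOT set.
#' @param seed RNG seed for the background panel.
#' @param occupants_only count only factors occupying the locus.
#' @return list: `per_locus` (n_strong, n_weak, strongest_factor, tie),
#'   `percentiles` (HOT loci x factors), `excluded_factors`.
#' @export
anchor_profile <- function(hot, pwms_by_factor, genome, strong_percentile = 95,
                           weak_percentile = 25, background_fold = 10,
                           seed = 1, occupants_only = TRUE) {
  hl <- hot$loci[, c("chrom", "start", "end")]
  if (!nrow(hl)) stop("no HOT loci to profile")
  bg_iv <- generate_matched_null(hl, genome, gc_tol = 0.05, repeat_tol = 0.1,
                                 fold = background_fold, seed = seed)
  all_iv <- rbind(hl, bg_iv[, c("chrom", "start", "end")])
  code_list <- lapply(seq_len(nrow(all_iv)), function(i)
    genome_codes(genome, as.character(all_iv$chrom[i]), all_iv$start[i],
                 all_iv$end[i]))
  background <- estimate_background(code_list)
  has_pwm <- !vapply(pwms_by_factor, is.null, logical(1))
  excluded <- names(pwms_by_factor)[!has_pwm]
  fids <- names(pwms_by_factor)[has_pwm]
  n_hot <- nrow(hl)
  pct <- matrix(NA_real_, n_hot, length(fids), dimnames = list(NULL, fids))
  for (f in fids) {
    sc <- best_pwm_scores(pwms_by_factor[[f]], code_list, background)
    r <- rank(sc, ties.method = "average") / length(sc) * 100
    pct[, f] <- r[seq_len(n_hot)]
  }
  per_locus <- do.call(rbind, lapply(seq_len(n_hot), function(i) {
    use <- fids
    if (occupants_only) use <- intersect(fids, hot$factor_sets[[i]])
    p <- pct[i, use]
    n_strong <- sum(p >= strong_percentile)
    n_weak <- sum(p >= weak_percentile & p < strong_percentile)
    if (length(p)) {
      top <- which(p == max(p))
      strongest <- sort(use[top])[1]
      tie <- length(top) > 1
    } else { strongest <- NA_character_; tie <- FALSE }
    data.frame(n_strong = n_strong, n_weak = n_weak,
               strongest_factor = strongest, tie = tie)
  }))
  list(per_locus = per_locus, percentiles = pct, excluded_factors = excluded)
}

#' Expression near co-occupied versus singly occupied sites
#'
#' Partitions factor-A and factor-B summit sites (+/- 50 bp windows) into
#' both / A-only / B-only groups, adds GC-matched random control sites,
#' assigns each site its nearest TSS (unbounded distance) and compares the
#' expression of the associated genes between groups with two-sided rank-sum
#' tests.
#'
#' @param peaks_a,peaks_b `peak_collection` objects.
#' @param gene_table data.frame with chrom/tss/tpm.
#' @param genome a `genome_sequence` (for the matched controls).
#' @param seed RNG seed.
#' @param flank_bp summit window half-width.
#' @return list: `medians`, `tests` (group1, group2, p), `groups` (tpm
#'   vectors), `skipped` (empty groups).
#' @export
expression_by_cooccupancy <- function(peaks_a, peaks_b, gene_table, genome,
                                      seed = 1, flank_bp = 50) {
  ca <- peak_centers(peaks_a); cb <- peak_centers(peaks_b)
  cha <- peaks_a$peaks$chrom; chb <- peaks_b$peaks$chrom
  near_other <- function(c1, ch1, c2, ch2) {
    out <- rep(FALSE, length(c1))
    for (ch in unique(ch1)) {
      x2 <- sort(c2[ch2 == ch])
      if (!length(x2)) next
      i1 <- which(ch1 == ch)
      k <- findInterval(c1[i1], x2)
      lo <- k >= 1 & c1[i1] - x2[pmax(k, 1)] <= 2 * flank_bp
      hi <- k < length(x2) & x2[pmin(k + 1, length(x2))] - c1[i1] <= 2 * flank_bp
      out[i1] <- lo | hi
    }
    out
  }
  a_near <- near_other(ca, cha, cb, chb)
  b_near <- near_other(cb, chb, ca, cha)
  sites <- list(
    both = data.frame(chrom = cha[a_near], pos = ca[a_near]),
    a_only = data.frame(chrom = cha[!a_near], pos = ca[!a_near]),
    b_only = data.frame(chrom = chb[!b_near], pos = cb[!b_near]))
  all_pos <- rbind(sites$both, sites$a_only, sites$b_only)
  ctrl_iv <- generate_matched_null(
    data.frame(chrom = all_pos$chrom, start = pmax(0, all_pos$pos - flank_bp),
               end = all_pos$pos + flank_bp + 1),
    genome, gc_tol = 0.05, repeat_tol = 0.1, fold = 1, seed = seed)
  sites$control <- data.frame(chrom = ctrl_iv$chrom,
                              pos = floor((ctrl_iv$start + ctrl_iv$end) / 2))
  nearest_tpm <- function(s) {
    if (!nrow(s)) return(numeric(0))
    vapply(seq_len(nrow(s)), function(i) {
      g <- gene_table[gene_table$chrom == s$chrom[i], , drop = FALSE]
      if (!nrow(g)) return(NA_real_)
      g$tpm[which.min(abs(g$tss - s$pos[i]))]
    }, numeric(1))
  }
  groups <- lapply(sites, nearest_tpm)
  skipped <- names(groups)[vapply(groups, length, integer(1)) == 0]
  medians <- vapply(groups, function(v)
    if (length(v)) stats::median(v, na.rm = TRUE) else NA_real_, numeric(1))
  pairs <- utils::combn(names(groups), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    if (g1 %in% skipped || g2 %in% skipped) return(NULL)
    v1 <- groups[[g1]]; v2 <- groups[[g2]]
    # degenerate all-tied comparison carries no evidence of a group effect
    p <- if (length(unique(c(v1, v2))) == 1) 1
         else suppressWarnings(stats::wilcox.test(v1, v2)$p.value)
    data.frame(group1 = g1, group2 = g2, p = p)
  }))
  list(medians = medians, tests = tests, groups = groups, skipped = skipped)
}
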