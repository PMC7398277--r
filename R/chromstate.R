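# Chromatin-state annotation and enrichment: majority-vote locus labelling,
# GC/repeat-matched null sequences, Fisher/BH enrichment statistics,
# regulatory-element construction, CpG promoter classes, conservation by
# occupancy, and promoter-vs-enhancer prediction curves.

#' Annotate loci with the majority chromatin state
#'
#' Each locus gets the state covering most of its bases; ties are broken by
#' the first state in segment order and flagged. Loci on chromosomes absent
#' from the segmentation are labelled "unannotated".
#'
#' @param loci interval data.frame.
#' @param segmentation a `state_segmentation`.
#' @return data.frame (`state`, `tie`) aligned with `loci` rows.
#' @export
annotate_loci <- function(loci, segmentation) {
  validate_intervals(loci)
  seg <- segmentation$segments
  out <- data.frame(state = rep("unannotated", nrow(loci)),
                    tie = rep(FALSE, nrow(loci)))
  if (!nrow(loci)) return(out)
  lx <- loci[, c("chrom", "start", "end")]
  lx$.i <- seq_len(nrow(lx))
  o <- order(as.character(lx$chrom), lx$start, lx$end, method = "radix")
  lx <- lx[o, , drop = FALSE]
  ov <- intersect_intervals(lx, seg)
  if (!nrow(ov)) return(out)
  ov$orig <- lx$.i[ov$a_idx]
  ov$state <- seg$state[ov$b_idx]
  for (li in unique(ov$orig)) {
    d <- ov[ov$orig == li, , drop = FALSE]
    tot <- tapply(d$overlap, d$state, sum)
    best <- max(tot)
    winners <- names(tot)[tot == best]
    if (length(winners) > 1) {
      # first state in segment order among the tied
      first_seg <- vapply(winners, function(s) min(d$b_idx[d$state == s]), numeric(1))
      out$state[li] <- winners[which.min(first_seg)]
      out$tie[li] <- TRUE
    } else out$state[li] <- winners
  }
  out
}

# state of single positions (0-based); "unannotated" outside every segment
state_at_points <- function(segmentation, chrom, pos) {
  seg <- segmentation$segments
  idx <- locate_points(seg, chrom, pos)
  ifelse(is.na(idx), "unannotated", seg$state[pmax(idx, 1)])
}

#' Sample GC- and repeat-matched null intervals
#'
#' For every input interval, places `fold` random intervals of identical
#' length whose GC content is within `gc_tol` and repeat fraction within
#' `repeat_tol` of the source, and which do not overlap any input interval.
#' If placement fails within the try budget the tolerances are doubled once;
#' failure beyond that is an error reporting the achieved fold.
#'
#' @param intervals source intervals (chrom/start/end).
#' @param genome a `genome_sequence`.
#' @param gc_tol,repeat_tol matching tolerances.
#' @param fold nulls per input interval.
#' @param seed RNG seed (global RNG state restored).
#' @param batch candidate placements evaluated per attempt (candidates are
#'   screened in vectorised batches; the relaxed second phase uses a much
#'   larger batch so GC-extreme source intervals can still be matched).
#' @return data.frame (chrom, start, end, source_idx).
#' @export
generate_matched_null <- function(intervals, genome, gc_tol = 0.02,
                                  repeat_tol = 0.05, fold = 2, seed = 1,
                                  batch = 2000) {
  validate_intervals(intervals)
  src_gc <- interval_gc(genome, intervals)
  src_rep <- interval_repeat_fraction(genome, intervals)
  merged_in <- merge_intervals(intervals[, c("chrom", "start", "end")], "none")
  forbid <- split(merged_in, merged_in$chrom)
  lens <- genome$lengths
  chrom_w <- lens / sum(lens)
  # vectorised candidate screen: first start passing all filters, or NA
  try_batch <- function(L, gc0, rep0, gtol, rtol, n_cand) {
    ch <- sample(genome$chroms, n_cand, replace = TRUE, prob = chrom_w)
    s <- floor(stats::runif(n_cand) * (lens[ch] - L))
    ok <- lens[ch] > L
    for (cc in unique(ch)) {
      sel <- which(ch == cc & ok)
      if (!length(sel)) next
      fb <- forbid[[cc]]
      if (!is.null(fb) && nrow(fb)) {
        j <- findInterval(s[sel] + L, fb$start)
        bad <- j >= 1 & fb$end[pmax(j, 1)] > s[sel]
        ok[sel][bad] <- FALSE
      }
      gc <- (genome$cum_gc[[cc]][s[sel] + L] -
               ifelse(s[sel] > 0, genome$cum_gc[[cc]][pmax(s[sel], 1)], 0)) / L
      rp <- (genome$cum_rep[[cc]][s[sel] + L] -
               ifelse(s[sel] > 0, genome$cum_rep[[cc]][pmax(s[sel], 1)], 0)) / L
      ok[sel][abs(gc - gc0) > gtol | abs(rp - rep0) > rtol] <- FALSE
    }
    w <- which(ok)
    if (!length(w)) return(NULL)
    list(chrom = ch[w[1]], start = s[w[1]])
  }
  with_seed(seed, {
    res <- vector("list", nrow(intervals) * fold)
    k <- 0
    for (i in seq_len(nrow(intervals))) {
      L <- intervals$end[i] - intervals$start[i]
      for (f in seq_len(fold)) {
        hit <- try_batch(L, src_gc[i], src_rep[i], gc_tol, repeat_tol, batch)
        if (is.null(hit))   # tolerances doubled once, with a deeper search
          hit <- try_batch(L, src_gc[i], src_rep[i], 2 * gc_tol, 2 * repeat_tol,
                           25 * batch)
        if (is.null(hit))
          stop("matched-null placement exhausted the genome: achieved fold ",
               signif(k / nrow(intervals), 3), " of requested ", fold)
        k <- k + 1
        res[[k]] <- data.frame(chrom = hit$chrom, start = hit$start,
                               end = hit$start + L, source_idx = i)
      }
    }
    out <- do.call(rbind, res[seq_len(k)])
    rownames(out) <- NULL
    out
  })
}

#' One-sided Fisher's exact test (enrichment)
#'
#' Upper hypergeometric tail probability for the 2x2 table
#' `rbind(c(a, b), c(c, d))`: `P(X >= a)` with `X ~ Hypergeom(N = a+b+c+d,
#' K = a+c, n = a+b)`. All-zero margins give p = 1 by convention.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return p-value.
#' @export
fisher_exact_onesided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers")
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  if (N == 0 || K == 0 || n == 0) return(1)
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; monotone in the raw p-values and never
#' smaller than them.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Chromatin-state enrichment of a factor's peaks
#'
#' Assigns each peak a state by its center, compares the observed state
#' composition with that of GC/repeat-matched null intervals, and tests each
#' state with a one-sided Fisher test, BH-corrected across states.
#'
#' @param collection a `peak_collection`.
#' @param segmentation a `state_segmentation`.
#' @param genome a `genome_sequence`.
#' @param alpha significance level on BH-adjusted p-values (default 0.001).
#' @param fold matched nulls per peak.
#' @param seed RNG seed for null placement.
#' @param null_intervals optional pre-computed null intervals (bypasses
#'   [generate_matched_null()]).
#' @param epsilon pseudo-fraction in the log2 enrichment.
#' @return data.frame: factor_id, state, observed_fraction, null_fraction,
#'   log2_enrichment, fisher_p, bh_adjusted_p, significant.
#' @export
state_enrichment <- function(collection, segmentation, genome, alpha = 0.001,
                             fold = 2, seed = 1, null_intervals = NULL,
                             epsilon = 1e-6) {
  p <- collection$peaks
  if (!nrow(p)) stop("state enrichment undefined for an empty collection")
  if (is.null(null_intervals))
    null_intervals <- generate_matched_null(p[, c("chrom", "start", "end")],
                                            genome, fold = fold, seed = seed)
  obs_state <- state_at_points(segmentation, p$chrom, peak_centers(collection))
  null_state <- state_at_points(segmentation, null_intervals$chrom,
                                floor((null_intervals$start + null_intervals$end) / 2))
  states <- sort(unique(c(obs_state, null_state, names(segmentation$class_map))))
  n_obs <- length(obs_state); n_null <- length(null_state)
  obs_n <- vapply(states, function(s) sum(obs_state == s), numeric(1))
  null_n <- vapply(states, function(s) sum(null_state == s), numeric(1))
  obs_f <- obs_n / n_obs
  null_f <- null_n / n_null
  fisher <- vapply(seq_along(states), function(i)
    fisher_exact_onesided(obs_n[i], n_obs - obs_n[i], null_n[i], n_null - null_n[i]),
    numeric(1))
  bh <- bh_adjust(fisher)
  data.frame(factor_id = collection$factor_id, state = states,
             observed_fraction = obs_f, null_fraction = null_f,
             log2_enrichment = log2((obs_f + epsilon) / (null_f + epsilon)),
             fisher_p = fisher, bh_adjusted_p = bh,
             significant = bh < alpha, row.names = NULL)
}

#' Cluster factors by their state-enrichment profiles
#'
#' Ward/Euclidean hierarchical clustering of per-factor log2-enrichment
#' vectors, cut at `k` (default 5, the number of main factor clusters on real
#' compendia).
#'
#' @param enrichments list of [state_enrichment()] data.frames, or a numeric
#'   factors x states matrix.
#' @param k number of clusters.
#' @return named integer vector of cluster labels with the `hclust` attached
#'   as attribute `hclust`.
#' @export
cluster_state_profiles <- function(enrichments, k = 5) {
  if (is.list(enrichments) && !is.matrix(enrichments) && !is.data.frame(enrichments)) {
    states <- sort(unique(unlist(lapply(enrichments, `[[`, "state"))))
    m <- t(vapply(enrichments, function(e) {
      v <- stats::setNames(rep(0, length(states)), states)
      v[e$state] <- e$log2_enrichment
      v
    }, numeric(length(states))))
    rownames(m) <- vapply(enrichments, function(e) e$factor_id[1], character(1))
  } else m <- as.matrix(enrichments)
  if (k > nrow(m)) stop("k exceeds the number of factors")
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  attr(cl, "hclust") <- hc
  cl
}

#' Promoter and enhancer binding fractions of a factor
#'
#' Fractions of peaks whose center falls in promoter-class versus
#' enhancer-class (strong or weak) states; fractions over all classes plus
#' "other"/"unannotated" sum to 1.
#'
#' @param collection a `peak_collection`.
#' @param segmentation a `state_segmentation`.
#' @return list: `f_promoter`, `f_enhancer`, `by_class` (named fractions).
#' @export
promoter_enhancer_fractions <- function(collection, segmentation) {
  if (!nrow(collection$peaks))
    stop("fractions undefined for an empty collection")
  st <- state_at_points(segmentation, collection$peaks$chrom,
                        peak_centers(collection))
  cls <- ifelse(st == "unannotated", "unannotated",
                unname(segmentation$class_map[st]))
  lv <- c("promoter", "strong_enhancer", "weak_enhancer", "other", "unannotated")
  by_class <- vapply(lv, function(x) mean(cls == x), numeric(1))
  list(f_promoter = by_class[["promoter"]],
       f_enhancer = by_class[["strong_enhancer"]] + by_class[["weak_enhancer"]],
       by_class = by_class)
}

#' Build regulatory elements from a segmentation
#'
#' Keeps promoter/strong-enhancer/weak-enhancer states, mapping each segment
#' to its element class, and merges adjacent same-class segments separated by
#' at most `merge_gap` bp (an intervening different-class segment blocks the
#' merge, so elements never overlap).
#'
#' @param segmentation a `state_segmentation`.
#' @param merge_gap maximum gap (bp) bridged between same-class segments.
#' @return data.frame (chrom, start, end, element_class).
#' @export
build_elements <- function(segmentation, merge_gap = 100) {
  seg <- segmentation$segments
  cls <- unname(segmentation$class_map[seg$state])
  reg <- seg[cls != "other", , drop = FALSE]
  reg$element_class <- cls[cls != "other"]
  if (!nrow(reg))
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      element_class = character(0)))
  out <- lapply(split(reg, factor(reg$chrom, levels = unique(reg$chrom))), function(d) {
    cs <- d$start[1]; ce <- d$end[1]; cc <- d$element_class[1]
    acc <- list()
    for (i in seq_len(nrow(d))[-1]) {
      if (d$element_class[i] == cc && d$start[i] - ce <= merge_gap) {
        ce <- max(ce, d$end[i]); next
      }
      acc[[length(acc) + 1]] <- data.frame(chrom = d$chrom[1], start = cs,
                                           end = ce, element_class = cc)
      cs <- d$start[i]; ce <- d$end[i]; cc <- d$element_class[i]
    }
    acc[[length(acc) + 1]] <- data.frame(chrom = d$chrom[1], start = cs,
                                         end = ce, element_class = cc)
    do.call(rbind, acc)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Distinct-CAP counts per regulatory element
#'
#' Counts distinct factors with at least 1 bp of peak overlap per element,
#' with summary statistics.
#'
#' @param elements data.frame from [build_elements()].
#' @param peak_collections list of `peak_collection` objects.
#' @return list: `counts` (elements with an `n_caps` column), `summary`
#'   (mean_all, mean_occupied, fraction_zero, mean_by_class).
#' @export
element_cap_counts <- function(elements, peak_collections) {
  n_caps <- integer(nrow(elements))
  if (nrow(elements)) {
    el <- elements[, c("chrom", "start", "end")]
    el$.i <- seq_len(nrow(el))
    el <- el[order(as.character(el$chrom), el$start, el$end, method = "radix"), ]
    hit <- matrix(FALSE, nrow(elements), length(peak_collections))
    for (f in seq_along(peak_collections)) {
      p <- peak_collections[[f]]$peaks
      if (!nrow(p)) next
      ov <- intersect_intervals(el, p[, c("chrom", "start", "end")])
      if (nrow(ov)) hit[unique(el$.i[ov$a_idx]), f] <- TRUE
    }
    n_caps <- rowSums(hit)
  }
  counts <- cbind(elements, n_caps = n_caps)
  summary <- list(mean_all = mean(n_caps),
                  mean_occupied = if (any(n_caps > 0)) mean(n_caps[n_caps > 0]) else NA_real_,
                  fraction_zero = mean(n_caps == 0),
                  mean_by_class = tapply(n_caps, elements$element_class, mean))
  list(counts = counts, summary = summary)
}

#' CpG promoter class
#'
#' Classifies each TSS by scanning 500-bp subwindows of the +/- `window_bp`
#' region: `high` if some subwindow reaches GC >= 0.55 and CpG
#' observed/expected >= 0.6, `low` if no subwindow reaches o/e >= 0.4,
#' `intermediate` otherwise; o/e = (#CpG x L) / (#C x #G). Windows running
#' off a chromosome end are truncated and flagged.
#'
#' @param genome a `genome_sequence`.
#' @param tss data.frame with `chrom` and `tss` columns.
#' @param window_bp half-width of the promoter window.
#' @param subwindow_bp scanning subwindow length.
#' @return data.frame (`class`, `truncated`).
#' @export
classify_promoter_cpg <- function(genome, tss, window_bp = 1000,
                                  subwindow_bp = 500) {
  res <- data.frame(class = character(nrow(tss)), truncated = logical(nrow(tss)))
  for (i in seq_len(nrow(tss))) {
    ch <- as.character(tss$chrom[i])
    s <- tss$tss[i] - window_bp; e <- tss$tss[i] + window_bp
    trunc <- s < 0 || e > genome$lengths[[ch]]
    s <- max(0, s); e <- min(genome$lengths[[ch]], e)
    v <- genome_codes(genome, ch, s, e)
    n <- length(v)
    if (n < subwindow_bp) { res$class[i] <- "low"; res$truncated[i] <- TRUE; next }
    cum_c <- cumsum(v == 2L); cum_g <- cumsum(v == 3L)
    cg <- c(v[-n] == 2L & v[-1] == 3L, FALSE)
    cum_cg <- cumsum(cg)
    st <- seq_len(n - subwindow_bp + 1)
    en <- st + subwindow_bp - 1
    rng <- function(cum) cum[en] - c(0, cum)[st]
    nC <- rng(cum_c); nG <- rng(cum_g)
    # CpG dinucleotides starting inside [st, en - 1]
    nCG <- cum_cg[en - 1] - c(0, cum_cg)[st]
    gc <- (nC + nG) / subwindow_bp
    oe <- ifelse(nC * nG > 0, nCG * subwindow_bp / (nC * nG), 0)
    res$class[i] <- if (any(gc >= 0.55 & oe >= 0.6)) "high"
                    else if (all(oe < 0.4)) "low" else "intermediate"
    res$truncated[i] <- trunc
  }
  res
}

#' Constrained-element overlap by occupancy bin
#'
#' Per CAP-count bin: overlapping constrained bases over total bases (also
#' expressed per 100 bp), plus a two-sample KS comparison of per-locus overlap
#' fractions between highly bound (>= `hi_threshold` CAPs) and not highly
#' bound (1 to `hi_threshold` - 1) loci.
#'
#' @param loci interval data.frame.
#' @param cap_counts CAP count per locus.
#' @param constrained constrained-element intervals (BED3-style data.frame).
#' @param bin_edges increasing CAP-count bin edges (left-closed).
#' @param hi_threshold CAP count defining the highly bound group.
#' @return list: `per_bin` data.frame (bin, n_loci, overlap_fraction,
#'   per_100bp), `ks` (D, p; NULL when a group is empty), `per_locus_fraction`.
#' @export
conservation_by_occupancy <- function(loci, cap_counts, constrained,
                                      bin_edges = c(1, 5, 10, 15, 20, Inf),
                                      hi_threshold = 20) {
  stopifnot(nrow(loci) == length(cap_counts))
  cons <- merge_intervals(constrained, "none")
  lx <- loci[, c("chrom", "start", "end")]
  lx$.i <- seq_len(nrow(lx))
  lx <- lx[order(as.character(lx$chrom), lx$start, lx$end, method = "radix"), ]
  ov_bases <- numeric(nrow(loci))
  if (nrow(cons)) {
    ov <- intersect_intervals(lx, cons)
    if (nrow(ov)) {
      agg <- tapply(ov$overlap, lx$.i[ov$a_idx], sum)
      ov_bases[as.integer(names(agg))] <- agg
    }
  }
  widths <- loci$end - loci$start
  frac <- ov_bases / widths
  bins <- cut(cap_counts, breaks = bin_edges, right = FALSE)
  per_bin <- do.call(rbind, lapply(levels(bins), function(b) {
    sel <- !is.na(bins) & bins == b
    if (!any(sel)) { warning("empty occupancy bin ", b, " excluded"); return(NULL) }
    f <- sum(ov_bases[sel]) / sum(widths[sel])
    data.frame(bin = b, n_loci = sum(sel), overlap_fraction = f,
               per_100bp = f * 100)
  }))
  hi <- frac[cap_counts >= hi_threshold]
  lo <- frac[cap_counts >= 1 & cap_counts < hi_threshold]
  ks <- if (length(hi) >= 2 && length(lo) >= 2) ks_two_sample(hi, lo) else NULL
  list(per_bin = per_bin, ks = ks, per_locus_fraction = frac)
}

#' Promoter/enhancer prediction accuracy versus feature count
#'
#' For each feature-count grid point, repeatedly samples `n_loci` loci and
#' that many features uniformly at random, trains a random forest, and
#' records the out-of-bag accuracy; reports median/min/max per grid point.
#' The protocol applies unchanged to peak-presence and motif-presence
#' matrices.
#'
#' @param x binary loci x feature matrix.
#' @param labels factor/character vector of locus labels (two classes).
#' @param n_features_grid feature counts to evaluate (points above the
#'   feature count are clipped with a warning).
#' @param n_loci loci sampled per iteration.
#' @param iterations iterations per grid point.
#' @param seed RNG seed.
#' @param ntree trees per forest.
#' @return data.frame (n_features, median, min, max).
#' @export
predict_state_from_binding <- function(x, labels, n_features_grid = c(5, 15, 30, 60),
                                       n_loci = 1000, iterations = 100, seed = 1,
                                       ntree = 100) {
  x <- as.matrix(x)
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes")
  grid <- n_features_grid
  if (any(grid > ncol(x))) {
    warning("grid points above the feature count were clipped")
    grid <- pmin(grid, ncol(x))
  }
  grid <- sort(unique(grid))
  with_seed(seed, {
    out <- lapply(grid, function(g) {
      acc <- vapply(seq_len(iterations), function(it) {
        for (try in 1:20) {
          li <- sample.int(nrow(x), min(n_loci, nrow(x)))
          if (length(unique(y[li])) == 2) break
        }
        fi <- sample.int(ncol(x), g)
        xi <- x[li, fi, drop = FALSE]
        colnames(xi) <- paste0("f", seq_len(ncol(xi)))
        rf <- randomForest::randomForest(xi, droplevels(y[li]), ntree = ntree)
        1 - rf$err.rate[ntree, "OOB"]
      }, numeric(1))
      data.frame(n_features = g, median = stats::median(acc),
                 min = min(acc), max = max(acc))
    })
    do.call(rbind, out)
  })
}
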