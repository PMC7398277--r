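# Occupancy matrices and co-binding analyses: loci from merged peaks or 2-kb
# windows, binary loci x factor membership by peak summit, PCA of loci,
# TSS-proximal fractions, pairwise summit-window overlap, co-binding networks
# and co-occupancy profiles over CAP-count bins.

#' Build a binary occupancy matrix from many peak sets
#'
#' Loci are either the size-ruled union merge of all peaks (`mode = "merge"`)
#' or non-overlapping 2-kb windows tiled over the unbounded merge
#' (`mode = "windows"`). A factor occupies a locus iff one of its peak
#' summits (midpoint fallback) lies inside it; loci with fewer than
#' `min_factors` distinct factors are dropped.
#'
#' @param peak_collections list of `peak_collection` objects.
#' @param mode `"merge"` or `"windows"`.
#' @param size_rule size rule for `mode = "merge"` (see [merge_intervals()]).
#' @param min_factors minimum distinct factors per retained locus.
#' @param window_bp window width for `mode = "windows"`.
#' @return an `occupancy_matrix`: list(loci, factors, values, provenance).
#' @export
build_loci <- function(peak_collections, mode = c("merge", "windows"),
                       size_rule = "filter:2000", min_factors = 2,
                       window_bp = 2000) {
  mode <- match.arg(mode)
  stopifnot(length(peak_collections) >= 1)
  factors <- vapply(peak_collections, `[[`, character(1), "factor_id")
  if (anyDuplicated(factors)) stop("duplicate factor ids in peak collections")
  all_iv <- do.call(rbind, lapply(peak_collections, function(pc)
    pc$peaks[, c("chrom", "start", "end")]))
  if (is.null(all_iv) || nrow(all_iv) == 0) {
    warning("no peaks in any collection: empty occupancy matrix")
    loci <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    return(structure(list(loci = loci, factors = factors,
                          values = matrix(0L, 0, length(factors),
                                          dimnames = list(NULL, factors)),
                          provenance = list(mode = mode, size_rule = size_rule,
                                            min_factors = min_factors)),
                     class = "occupancy_matrix"))
  }
  loci <- if (mode == "merge") merge_intervals(all_iv, size_rule)
          else window_partition(merge_intervals(all_iv, "none"), window_bp)
  values <- matrix(0L, nrow(loci), length(factors),
                   dimnames = list(NULL, factors))
  for (f in seq_along(peak_collections)) {
    pc <- peak_collections[[f]]
    if (!nrow(pc$peaks)) next
    li <- locate_points(loci, pc$peaks$chrom, peak_centers(pc))
    values[unique(li[!is.na(li)]), f] <- 1L
  }
  keep <- rowSums(values) >= min_factors
  loci <- loci[keep, , drop = FALSE]
  rownames(loci) <- NULL
  values <- values[keep, , drop = FALSE]
  structure(list(loci = loci, factors = unname(factors), values = values,
                 provenance = list(mode = mode, size_rule = size_rule,
                                   min_factors = min_factors)),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat("occupancy_matrix:", nrow(x$loci), "loci x", length(x$factors),
      "factors (", x$provenance$mode, ",", x$provenance$size_rule, ")\n")
  invisible(x)
}

#' Fraction of a factor's peaks near expressed TSSs
#'
#' Fraction of peak centers within a closed +/- `window_bp` of any TSS of a
#' gene expressed at `tpm >= min_tpm`.
#'
#' @param collection a `peak_collection`.
#' @param gene_table data.frame with columns `chrom`, `tss`, `tpm`.
#' @param window_bp proximity window (bp, closed at both ends).
#' @param min_tpm expression threshold defining an expressed gene.
#' @return fraction in [0, 1].
#' @export
tss_proximal_fraction <- function(collection, gene_table, window_bp = 3000,
                                  min_tpm = 1.0) {
  if (!nrow(collection$peaks))
    stop("TSS-proximal fraction undefined for an empty peak collection")
  g <- gene_table[gene_table$tpm >= min_tpm, , drop = FALSE]
  centers <- peak_centers(collection)
  chrom <- collection$peaks$chrom
  near <- rep(FALSE, length(centers))
  for (ch in unique(chrom)) {
    tss <- sort(g$tss[g$chrom == ch])
    if (!length(tss)) next
    ci <- which(chrom == ch)
    k <- findInterval(centers[ci], tss)
    lo_ok <- k >= 1 & centers[ci] - tss[pmax(k, 1)] <= window_bp
    hi_ok <- k < length(tss) & tss[pmin(k + 1, length(tss))] - centers[ci] <= window_bp
    near[ci] <- lo_ok | hi_ok
  }
  mean(near)
}

#' PCA of a binary loci x feature matrix
#'
#' Mean-centered principal component analysis (no scaling), deterministic up
#' to component sign.
#'
#' @param x an `occupancy_matrix` or a plain numeric matrix (loci x features).
#' @param n_components number of components to keep.
#' @return a `pca_result`: scores (loci x k), loadings (features x k),
#'   variance_fraction (per component, of the total variance).
#' @export
pca_loci <- function(x, n_components = 2) {
  m <- if (inherits(x, "occupancy_matrix")) x$values else as.matrix(x)
  storage.mode(m) <- "double"
  nonconst <- sum(apply(m, 2, function(v) stats::var(v) > 0))
  if (n_components > nonconst)
    stop("n_components (", n_components, ") exceeds the number of non-constant columns")
  pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > pr$sdev[1] * 1e-9)
  if (n_components > rank) stop("n_components exceeds matrix rank (", rank, ")")
  total_var <- sum(pr$sdev^2)
  k <- seq_len(n_components)
  structure(list(scores = pr$x[, k, drop = FALSE],
                 loadings = pr$rotation[, k, drop = FALSE],
                 variance_fraction = pr$sdev[k]^2 / total_var,
                 center = pr$center, total_variance = total_var),
            class = "pca_result")
}

#' Variance-weighted principal-component distance between factors
#'
#' Cumulative PC distance between factor loading rows, each component
#' weighted by its variance fraction:
#' `D[i,j] = sqrt(sum_c w_c (L[i,c] - L[j,c])^2)`.
#'
#' @param pca a `pca_result`.
#' @return symmetric factor x factor distance matrix.
#' @export
factor_pc_distance <- function(pca) {
  w <- pca$variance_fraction
  L <- sweep(pca$loadings, 2, sqrt(w), "*")
  as.matrix(stats::dist(L))
}

#' Pairwise summit-window overlap matrix
#'
#' `M[a, b]` is the fraction of factor a's peaks whose closed summit window
#' `[s - flank, s + flank]` overlaps at least one of factor b's summit
#' windows (summits within `2 * flank` bp). Asymmetric; diagonal 1. Factors
#' with no peaks get NA rows/columns, listed in the `undefined` attribute.
#'
#' @param collections list of `peak_collection` objects.
#' @param flank_bp window half-width around the summit.
#' @return numeric matrix with factor ids as dimnames.
#' @export
pairwise_overlap_matrix <- function(collections, flank_bp = 50) {
  stopifnot(length(collections) >= 2)
  ids <- vapply(collections, `[[`, character(1), "factor_id")
  centers <- lapply(collections, function(pc) {
    split(peak_centers(pc), pc$peaks$chrom)
  })
  n <- length(ids)
  M <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  empty <- vapply(collections, function(pc) nrow(pc$peaks) == 0, logical(1))
  for (a in seq_len(n)) {
    if (empty[a]) next
    for (b in seq_len(n)) {
      if (empty[b]) next
      if (a == b) { M[a, b] <- 1; next }
      hitn <- 0L; tot <- 0L
      for (ch in names(centers[[a]])) {
        xa <- centers[[a]][[ch]]
        tot <- tot + length(xa)
        xb <- centers[[b]][[ch]]
        if (is.null(xb) || !length(xb)) next
        xb <- sort(xb)
        k <- findInterval(xa, xb)
        lo <- k >= 1 & xa - xb[pmax(k, 1)] <= 2 * flank_bp
        hi <- k < length(xb) & xb[pmin(k + 1, length(xb))] - xa <= 2 * flank_bp
        hitn <- hitn + sum(lo | hi)
      }
      M[a, b] <- hitn / tot
    }
  }
  attr(M, "undefined") <- ids[empty]
  M
}

#' Co-binding network from an overlap matrix
#'
#' Directed edge a -> b whenever `M[a, b] >= threshold` (a != b); node size is
#' its number of connections.
#'
#' @param overlap_matrix output of [pairwise_overlap_matrix()].
#' @param threshold minimum overlap fraction for an edge (default the 75\%
#'   co-binding threshold).
#' @return a `cobind_network`: list(nodes, edges, degree, threshold).
#' @export
cobind_network <- function(overlap_matrix, threshold = 0.75) {
  ids <- rownames(overlap_matrix)
  idx <- which(overlap_matrix >= threshold & !is.na(overlap_matrix) &
                 row(overlap_matrix) != col(overlap_matrix), arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = overlap_matrix[idx])
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  degree <- stats::setNames(integer(length(ids)), ids)
  tab <- table(c(edges$from, edges$to))
  degree[names(tab)] <- as.integer(tab)
  structure(list(nodes = ids, edges = edges, degree = degree,
                 threshold = threshold), class = "cobind_network")
}

#' @export
print.cobind_network <- function(x, ...) {
  cat("cobind_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges at threshold", x$threshold, "\n")
  invisible(x)
}

#' Write a co-binding network as edge-list TSV (and optionally GraphML)
#' @param network a `cobind_network`.
#' @param path TSV path (columns from, to, weight).
#' @param graphml_path optional GraphML path (requires igraph).
#' @export
write_network <- function(network, path, graphml_path = NULL) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("GraphML export requires the igraph package")
    g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                       vertices = data.frame(name = network$nodes))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Rank correlation of per-locus counts between factors
#'
#' Pairwise Spearman (default) or Pearson correlation of loci x factor count
#' columns; constant columns yield NA entries and are listed in the
#' `undefined` attribute; the diagonal is 1.
#'
#' @param counts non-negative numeric matrix, loci x factors.
#' @param method `"spearman"` or `"pearson"`.
#' @return symmetric correlation matrix.
#' @export
count_correlation <- function(counts, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  M <- suppressWarnings(stats::cor(counts, method = method))
  const <- apply(counts, 2, function(v) stats::var(v) == 0)
  diag(M) <- 1
  attr(M, "undefined") <- colnames(counts)[const]
  M
}

#' Per-factor co-occupancy profile over CAP-count bins
#'
#' For each factor, the distribution of its occupied loci across CAP-count
#' bins (rows sum to 1), its enrichment relative to the marginal bin
#' distribution of all loci, and Ward/Euclidean clustering of the enrichment
#' profiles.
#'
#' @param occupancy an `occupancy_matrix`.
#' @param bin_edges increasing locus CAP-count bin edges partitioning
#'   `[1, n_factors]` (left-closed); default a fixed logarithmic-style grid.
#' @param k number of clusters to cut (default 3).
#' @return list: `profile` (per-factor bin distribution), `enrichment`
#'   (profile / marginal), `marginal`, `clusters`, `hclust`, `excluded`.
#' @export
cooccupancy_profile <- function(occupancy, bin_edges = NULL, k = 3) {
  nfac <- length(occupancy$factors)
  counts <- rowSums(occupancy$values)
  if (is.null(bin_edges))
    bin_edges <- unique(pmin(c(1, 2, 3, 5, 10, 20, 40, 70, nfac + 1), nfac + 1))
  if (bin_edges[1] != 1 || bin_edges[length(bin_edges)] < nfac + 1)
    stop("bin_edges must partition [1, n_factors]")
  bins <- cut(counts, breaks = bin_edges, right = FALSE,
              labels = paste0("[", utils::head(bin_edges, -1), ",",
                              utils::tail(bin_edges, -1), ")"))
  marginal <- as.numeric(table(bins)) / length(bins)
  prof <- t(vapply(seq_len(nfac), function(f) {
    sel <- occupancy$values[, f] == 1L
    if (!any(sel)) return(rep(NA_real_, nlevels(bins)))
    as.numeric(table(bins[sel])) / sum(sel)
  }, numeric(nlevels(bins))))
  dimnames(prof) <- list(occupancy$factors, levels(bins))
  excluded <- occupancy$factors[is.na(prof[, 1])]
  if (length(excluded))
    warning("factor(s) with no occupied loci excluded: ",
            paste(excluded, collapse = ", "))
  keep <- !is.na(prof[, 1])
  enr <- sweep(prof[keep, , drop = FALSE], 2, pmax(marginal, 1e-12), "/")
  hc <- NULL
  clusters <- NULL
  if (sum(keep) >= 2) {
    hc <- stats::hclust(stats::dist(enr), method = "ward.D2")
    clusters <- stats::cutree(hc, k = min(k, sum(keep)))
  }
  list(profile = prof[keep, , drop = FALSE], enrichment = enr,
       marginal = stats::setNames(marginal, levels(bins)),
       clusters = clusters, hclust = hc, excluded = excluded)
}
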