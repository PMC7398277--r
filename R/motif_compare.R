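# Motif-motif similarity and concordance classification.
#
# The similarity statistic sums per-column Pearson correlations of
# probability 4-vectors over the best ungapped alignment (both target
# orientations, >= min_overlap aligned columns) and normalises by the shorter
# motif length, so a full-length match of the shorter motif scores 1 while a
# short chance alignment cannot (a plain mean over aligned columns lets a
# 4-column fluke tie a full-length match and has no discriminating power
# against column shuffles). Significance comes from a column-shuffle null of
# the target, realigned per shuffle, with +1 smoothing; E-values multiply the
# empirical p by the database cardinality.

with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# z-normalised columns: cor of two 4-vectors is the dot product of their
# z-columns; all-equal columns (sd 0) become zero vectors, correlation 0
pwm_colz <- function(m) {
  z <- sweep(m, 2, colMeans(m))
  nrm <- sqrt(colSums(z^2))
  nrm[nrm == 0] <- 1
  sweep(z, 2, nrm, "/")
}

alignment_offsets <- function(Lq, Lt, min_overlap) {
  offs <- (-(Lt - min_overlap)):(Lq - min_overlap)
  lapply(offs, function(o) {
    j <- max(1, 1 - o):min(Lt, Lq - o)
    list(offset = o, qi = j + o, tj = j)
  })
}

# best alignment score over offsets for one correlation matrix; `den` is the
# shorter motif length
best_over_offsets <- function(C, aligns, den) {
  best <- -Inf; boff <- NA_integer_
  for (a in aligns) {
    s <- sum(C[cbind(a$qi, a$tj)]) / den
    if (s > best + 1e-12) { best <- s; boff <- a$offset }
  }
  list(score = best, offset = boff)
}

# best score per column-permutation of the target, using precomputed C and
# C_comp (query vs complemented target columns); shuffled target column j is
# target column perm[j], and the revcomp of the shuffle uses complemented
# columns in reverse order
null_best_scores <- function(C, C_comp, Lt, aligns, perms, den) {
  ns <- nrow(perms)
  best <- rep(-Inf, ns)
  for (a in aligns) {
    idx_same <- perms[, a$tj, drop = FALSE]
    rowsel <- rep(a$qi, each = ns)
    s_same <- rowSums(matrix(C[cbind(rowsel, as.vector(idx_same))], nrow = ns)) / den
    idx_rc <- perms[, Lt + 1 - a$tj, drop = FALSE]
    s_rc <- rowSums(matrix(C_comp[cbind(rowsel, as.vector(idx_rc))], nrow = ns)) / den
    best <- pmax(best, s_same, s_rc)
  }
  best
}

similarity_core <- function(query, target, min_overlap) {
  Lq <- pwm_length(query); Lt <- pwm_length(target)
  if (min_overlap > min(Lq, Lt))
    stop("min_overlap exceeds the shorter motif length")
  Zq <- pwm_colz(query$matrix)
  Zt <- pwm_colz(target$matrix)
  Zt_comp <- pwm_colz(target$matrix[c(4, 3, 2, 1), , drop = FALSE])
  C <- crossprod(Zq, Zt)          # C[i, j] = cor(query col i, target col j)
  C_comp <- crossprod(Zq, Zt_comp)
  aligns <- alignment_offsets(Lq, Lt, min_overlap)
  den <- min(Lq, Lt)
  b_same <- best_over_offsets(C, aligns, den)
  # revcomp target column j = complement of target column Lt + 1 - j
  C_rc <- C_comp[, rev(seq_len(Lt)), drop = FALSE]
  b_rc <- best_over_offsets(C_rc, aligns, den)
  if (b_rc$score > b_same$score + 1e-12)
    best <- list(score = b_rc$score, offset = b_rc$offset, orientation = "revcomp")
  else
    best <- list(score = b_same$score, offset = b_same$offset, orientation = "same")
  list(best = best, C = C, C_comp = C_comp, Lt = Lt, aligns = aligns, den = den)
}

#' Motif-motif similarity with an empirical shuffle null
#'
#' Scores every ungapped offset (>= `min_overlap` aligned columns) in both
#' target orientations by the mean per-column Pearson correlation, and
#' calibrates the best score against `n_shuffles` column permutations of the
#' target, each realigned to its own best offset/orientation.
#'
#' @param query,target `pwm_motif` objects.
#' @param min_overlap minimum aligned columns.
#' @param n_shuffles column permutations for the null.
#' @param seed RNG seed for the shuffle null (global RNG state is restored).
#' @param db_size multiplier turning the empirical p into an E-value.
#' @return data.frame row: query_id, target_id, best_offset, orientation,
#'   score, p_value, e_value.
#' @export
motif_similarity <- function(query, target, min_overlap = 4, n_shuffles = 1000,
                             seed = 1, db_size = 1) {
  core <- similarity_core(query, target, min_overlap)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_shuffles), function(i) sample.int(core$Lt),
             integer(core$Lt)))
  })
  nb <- null_best_scores(core$C, core$C_comp, core$Lt, core$aligns, perms,
                         core$den)
  p <- (1 + sum(nb >= core$best$score - 1e-12)) / (n_shuffles + 1)
  data.frame(query_id = query$id, target_id = target$id,
             best_offset = core$best$offset, orientation = core$best$orientation,
             score = core$best$score, p_value = p, e_value = p * db_size)
}

#' All-vs-all motif similarity scores
#'
#' Best-alignment similarity scores for every (a, b) pair, with Ward/Euclidean
#' hierarchical clustering of rows and columns attached.
#'
#' @param motifs_a,motifs_b lists of `pwm_motif` objects.
#' @param min_overlap minimum aligned columns.
#' @return list with `scores` (matrix), `row_hclust`, `col_hclust` (NULL when
#'   fewer than 3 motifs on that side).
#' @export
similarity_matrix <- function(motifs_a, motifs_b = motifs_a, min_overlap = 4) {
  ids_a <- vapply(motifs_a, `[[`, character(1), "id")
  ids_b <- vapply(motifs_b, `[[`, character(1), "id")
  scores <- matrix(NA_real_, length(motifs_a), length(motifs_b),
                   dimnames = list(ids_a, ids_b))
  for (i in seq_along(motifs_a))
    for (j in seq_along(motifs_b))
      scores[i, j] <- similarity_core(motifs_a[[i]], motifs_b[[j]], min_overlap)$best$score
  rh <- if (nrow(scores) > 2) stats::hclust(stats::dist(scores), method = "ward.D2")
  ch <- if (ncol(scores) > 2) stats::hclust(stats::dist(t(scores)), method = "ward.D2")
  list(scores = scores, row_hclust = rh, col_hclust = ch)
}

#' Classify a derived motif as concordant, discordant or novel
#'
#' The query is compared to every database motif by similarity score and the
#' most similar motif is the best match (score ties broken by E-value); the
#' shuffle null is evaluated for the top-scoring candidates to obtain
#' E-values. `novel` when no candidate's E-value falls below `e_threshold`;
#' otherwise the best match's factor annotation decides `concordant` (matches
#' the assayed factor) versus `discordant`. Manual overrides (motif_id ->
#' forced call) are applied last.
#'
#' @param query a `pwm_motif` (the motif derived from the factor's peaks).
#' @param assayed_factor factor the peaks were assayed for.
#' @param motif_db list of `pwm_motif` objects with `factor_annotation` set.
#' @param e_threshold similarity E-value call threshold.
#' @param overrides named character vector motif_id -> forced call.
#' @param min_overlap,n_shuffles,seed see [motif_similarity()].
#' @param top_m number of top-scoring candidates given the full shuffle null.
#' @param db_size E-value multiplier; defaults to the database cardinality.
#' @return one-row data.frame: motif_id, assayed_factor, call, best_match_id,
#'   best_match_factor, score, e_value, override_applied.
#' @export
classify_concordance <- function(query, assayed_factor, motif_db,
                                 e_threshold = 0.05, overrides = NULL,
                                 min_overlap = 4, n_shuffles = 5000, seed = 1,
                                 top_m = 3, db_size = length(motif_db)) {
  res <- data.frame(motif_id = query$id, assayed_factor = assayed_factor,
                    call = "novel", best_match_id = NA_character_,
                    best_match_factor = NA_character_, score = NA_real_,
                    e_value = NA_real_, override_applied = FALSE)
  if (!length(motif_db)) {
    warning("empty motif database: calling '", query$id, "' novel")
  } else {
    scores <- vapply(motif_db, function(t)
      similarity_core(query, t, min_overlap)$best$score, numeric(1))
    cand <- order(scores, decreasing = TRUE)[seq_len(min(top_m, length(scores)))]
    hits <- do.call(rbind, lapply(cand, function(i)
      motif_similarity(query, motif_db[[i]], min_overlap = min_overlap,
                       n_shuffles = n_shuffles, seed = seed, db_size = db_size)))
    o <- order(-hits$score, hits$e_value)
    best <- hits[o[1], ]
    res$best_match_id <- best$target_id
    res$best_match_factor <- motif_db[[cand[o[1]]]]$factor_annotation
    res$score <- best$score
    res$e_value <- best$e_value
    if (best$e_value < e_threshold)
      res$call <- if (identical(res$best_match_factor, assayed_factor))
        "concordant" else "discordant"
  }
  if (!is.null(overrides) && query$id %in% names(overrides)) {
    forced <- unname(overrides[[query$id]])
    if (!forced %in% c("concordant", "discordant", "novel"))
      stop("invalid override call: ", forced)
    res$call <- forced
    res$override_applied <- TRUE
  }
  res
}

#' Read a concordance override table
#' @param path 2-column TSV (motif_id, forced_call), no header.
#' @return named character vector.
#' @export
read_overrides <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("motif_id", "call"),
                         colClasses = c("character", "character"))
  stats::setNames(d$call, d$motif_id)
}
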