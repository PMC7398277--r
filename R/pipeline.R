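# End-to-end pipeline over a synthetic regulome: generation, occupancy,
# chromatin-state, motif and HOT analyses, with deterministic TSV outputs.

#' Motif-presence matrix for HOT loci
#'
#' Scans each factor's PWM over the HOT locus sequences and marks loci where
#' the motif occurs at `p_threshold`; factors without a PWM get all-FALSE
#' columns so the matrix aligns with the occupancy factor set.
#'
#' @param hot a `hot_call_set`.
#' @param factors factor ids defining the column order.
#' @param pwms_by_factor named list of `pwm_motif` (subset of `factors`).
#' @param genome a `genome_sequence`.
#' @param p_threshold scan p-value threshold.
#' @return logical HOT-loci x factors matrix.
#' @export
hot_motif_presence <- function(hot, factors, pwms_by_factor, genome,
                               p_threshold = 1e-4) {
  hl <- hot$loci[, c("chrom", "start", "end")]
  ids <- paste0("h", seq_len(nrow(hl)))
  seqs <- interval_sequences(genome, hl, ids)
  mp <- matrix(FALSE, nrow(hl), length(factors),
               dimnames = list(NULL, factors))
  for (f in intersect(factors, names(pwms_by_factor))) {
    if (is.null(pwms_by_factor[[f]])) next
    hits <- scan_pwm(pwms_by_factor[[f]], seqs, p_threshold = p_threshold)
    mp[match(unique(hits$seq_id), ids), f] <- TRUE
  }
  mp
}

#' Motif offsets of anchor and tethered factors
#'
#' For anchors, scans the factor's own motif over its peaks; for tethered
#' factors, scans the anchor's motif (the motif their peaks actually
#' contain). Returns per-factor signed offsets from peak centers.
#'
#' @param regulome a `synthetic_regulome`.
#' @param p_threshold scan p-value threshold.
#' @return list: `per_factor` (named list of signed offset vectors),
#'   `summary` data.frame (factor_id, role, n_hits, median_abs).
#' @export
factor_motif_offsets <- function(regulome, p_threshold = 1e-4) {
  fac <- regulome$truth$factor_table
  anchor_of <- stats::setNames(regulome$truth$tether_graph$anchor,
                               regulome$truth$tether_graph$tether)
  per <- list()
  rows <- list()
  for (i in seq_len(nrow(fac))) {
    f <- fac$factor_id[i]
    role <- fac$role[i]
    if (!role %in% c("anchor", "tethered")) next
    pwm <- if (role == "anchor") regulome$motif_db[[f]]
           else regulome$motif_db[[anchor_of[[f]]]]
    pc <- regulome$collections[[f]]
    if (!nrow(pc$peaks)) next
    w <- peak_windows(pc)
    seqs <- interval_sequences(regulome$genome,
                               w[, c("chrom", "start", "end")], w$seq_id)
    hits <- scan_pwm(pwm, seqs, p_threshold = p_threshold)
    od <- offset_distribution(hits, w)
    per[[f]] <- od$offsets
    rows[[f]] <- data.frame(factor_id = f, role = role,
                            n_hits = length(od$offsets),
                            median_abs = od$median_abs)
  }
  list(per_factor = per, summary = do.call(rbind, rows))
}

write_tsv <- function(d, path, rn = FALSE) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = rn,
                     col.names = TRUE)
}

#' Run the full analysis pipeline on a synthetic regulome
#'
#' Generates the regulome for `config`, writes the raw datasets and the
#' analysis outputs (occupancy, TSS fractions, PCA, co-binding network,
#' state enrichment and clusters, element CAP counts, HOT calls and
#' composition, subsampling recovery, motif offsets and concordance,
#' co-occupancy profile, conservation by occupancy) as TSV/BED files.
#' Byte-identical across runs with the same config.
#'
#' @param config a `synth_config`.
#' @param outdir output directory.
#' @param hot_fraction HOT threshold as a fraction of assayed factors.
#' @param subsample_iterations iterations for the subsampling curves.
#' @param concordance also classify every derived motif (the slowest step).
#' @return list of analysis results, invisibly.
#' @export
run_pipeline <- function(config, outdir, hot_fraction = 1/3,
                         subsample_iterations = 50, concordance = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reg <- generate_regulome(config)
  synthesize_datasets(config, file.path(outdir, "data"), regulome = reg)
  res <- list(regulome = reg)

  occ <- build_loci(reg$collections, mode = "merge", size_rule = "filter:2000",
                    min_factors = 2)
  res$occupancy <- occ
  write_tsv(cbind(occ$loci, n_factors = rowSums(occ$values)),
            file.path(outdir, "occupancy_loci.tsv"))

  tssf <- vapply(reg$collections, function(pc)
    if (nrow(pc$peaks)) tss_proximal_fraction(pc, reg$gene_table) else NA_real_,
    numeric(1))
  res$tss_fractions <- tssf
  write_tsv(data.frame(factor_id = names(tssf), fraction = unname(tssf)),
            file.path(outdir, "tss_fractions.tsv"))

  pca <- pca_loci(occ, n_components = 5)
  res$pca <- pca
  write_tsv(data.frame(component = seq_along(pca$variance_fraction),
                       variance_fraction = pca$variance_fraction),
            file.path(outdir, "pca_variance.tsv"))
  res$pc_distance <- factor_pc_distance(pca)

  ov <- pairwise_overlap_matrix(reg$collections)
  net <- cobind_network(ov, threshold = 0.75)
  res$network <- net
  write_network(net, file.path(outdir, "network_edges.tsv"))

  enr <- lapply(seq_along(reg$collections), function(i)
    state_enrichment(reg$collections[[i]], reg$segmentation, reg$genome,
                     seed = stage_seed(config$seed, 20) + i))
  res$enrichment <- enr
  write_tsv(do.call(rbind, enr), file.path(outdir, "state_enrichment.tsv"))
  cl <- cluster_state_profiles(enr, k = min(5, length(enr)))
  res$state_clusters <- cl
  write_tsv(data.frame(factor_id = names(cl), cluster = as.integer(cl)),
            file.path(outdir, "state_clusters.tsv"))

  elements <- build_elements(reg$segmentation)
  capc <- element_cap_counts(elements, reg$collections)
  res$cap_counts <- capc
  write_tsv(capc$counts, file.path(outdir, "element_cap_counts.tsv"))

  hot <- detect_hot(occ, fraction = hot_fraction)
  res$hot <- hot
  write_hot_bed(hot, file.path(outdir, "hot.bed"))
  comp <- hot_state_composition(hot, reg$segmentation)
  res$hot_composition <- comp
  write_tsv(data.frame(class = names(comp), fraction = unname(comp)),
            file.path(outdir, "hot_composition.tsv"))

  if (nrow(hot$loci)) {
    mp <- hot_motif_presence(hot, occ$factors, reg$motif_db, reg$genome)
    sub <- subsample_recovery(occ, hot, mp, iterations = subsample_iterations,
                              seed = stage_seed(config$seed, 21))
    res$subsample <- sub
    write_tsv(sub, file.path(outdir, "subsample_recovery.tsv"))
    prof <- anchor_profile(hot, reg$motif_db, reg$genome,
                           seed = stage_seed(config$seed, 22))
    res$anchor_profile <- prof
    write_tsv(prof$per_locus, file.path(outdir, "anchor_profile.tsv"))
  }

  offs <- factor_motif_offsets(reg)
  res$offsets <- offs
  if (!is.null(offs$summary))
    write_tsv(offs$summary, file.path(outdir, "motif_offsets.tsv"))

  if (concordance) {
    db <- reg$motif_db
    calls <- do.call(rbind, lapply(names(reg$derived_motifs), function(f)
      classify_concordance(reg$derived_motifs[[f]], f, db,
                           seed = stage_seed(config$seed, 23))))
    res$concordance <- calls
    write_tsv(calls, file.path(outdir, "concordance.tsv"))
  }

  prof2 <- cooccupancy_profile(occ)
  res$cooccupancy <- prof2
  write_tsv(as.data.frame(prof2$enrichment), file.path(outdir, "cooccupancy_profile.tsv"),
            rn = TRUE)

  cons <- conservation_by_occupancy(occ$loci, rowSums(occ$values),
                                    reg$constrained)
  res$conservation <- cons
  write_tsv(cons$per_bin, file.path(outdir, "conservation.tsv"))

  invisible(res)
}
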