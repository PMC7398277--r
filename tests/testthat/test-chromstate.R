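seg_fixture <- function() {
  state_segmentation(
    data.frame(chrom = "chr1", start = c(0, 1000, 2000, 3000),
               end = c(1000, 2000, 3000, 10000),
               state = c("P", "ES", "EW", "Q")),
    c(P = "promoter", ES = "strong_enhancer", EW = "weak_enhancer", Q = "other"))
}

test_that("locus annotation is a majority vote with ordered tie-breaks", {
  seg <- seg_fixture()
  ann <- annotate_loci(data.frame(chrom = "chr1", start = 100, end = 900), seg)
  expect_equal(ann$state, "P")
  maj <- annotate_loci(data.frame(chrom = "chr1", start = 400, end = 1400), seg)
  expect_equal(maj$state, "P")          # 600 vs 400 bases
  expect_false(maj$tie)
  tie <- annotate_loci(data.frame(chrom = "chr1", start = 500, end = 1500), seg)
  expect_equal(tie$state, "P")          # tied, first state in segment order
  expect_true(tie$tie)
  off <- annotate_loci(data.frame(chrom = "chrX", start = 0, end = 10), seg)
  expect_equal(off$state, "unannotated")
  # random loci match a per-base majority oracle
  set.seed(81)
  loci <- data.frame(chrom = "chr1", start = sample(0:8000, 30))
  loci$end <- loci$start + sample(50:1500, 30, TRUE)
  got <- annotate_loci(loci, seg)
  segs <- seg$segments
  for (i in seq_len(nrow(loci))) {
    pos <- loci$start[i]:(loci$end[i] - 1)
    lab <- vapply(pos, function(p) {
      h <- which(segs$start <= p & segs$end > p)
      if (length(h)) segs$state[h] else "none"
    }, character(1))
    tab <- table(lab[lab != "none"])
    expect_true(got$state[i] %in% names(tab)[tab == max(tab)])
  }
})

test_that("matched nulls respect length, composition tolerances, and exclusion", {
  reg <- get_small_regulome()
  src <- reg$truth$elements[sample(seq_len(nrow(reg$truth$elements)), 40), ]
  src <- src[, c("chrom", "start", "end")]
  nulls <- generate_matched_null(src, reg$genome, gc_tol = 0.02,
                                 repeat_tol = 0.05, fold = 2, seed = 5)
  expect_equal(nrow(nulls), 80)
  expect_equal(nulls$end - nulls$start,
               (src$end - src$start)[nulls$source_idx])
  gc_src <- interval_gc(reg$genome, src)
  gc_null <- interval_gc(reg$genome, nulls[, c("chrom", "start", "end")])
  expect_true(all(abs(gc_null - gc_src[nulls$source_idx]) <= 0.04 + 1e-9))
  expect_lt(abs(mean(gc_null) - mean(gc_src[nulls$source_idx])), 0.01)
  expect_equal(nrow(intersect_intervals(sort_intervals(src),
                                        sort_intervals(nulls[, 1:3]))), 0)
})

test_that("one-sided Fisher equals the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact_onesided(0, 7, 0, 9), 1)
  expect_equal(fisher_exact_onesided(5, 5, 1, 9), enum_fisher(5, 5, 1, 9),
               tolerance = 1e-12)
  set.seed(82)
  for (i in 1:25) {
    cells <- sample(0:12, 4, TRUE)
    p <- do.call(fisher_exact_onesided, as.list(cells))
    expect_equal(p, do.call(enum_fisher, as.list(cells)), tolerance = 1e-10)
    # invariant under transposing the table (swap rows and columns together)
    expect_equal(p, fisher_exact_onesided(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_onesided(-1, 2, 3, 4), "non-negative")
})

test_that("BH adjustment is the step-up procedure with its invariances", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(83)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))          # monotone in raw p
  perm <- sample(20)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("state enrichment partitions peaks and self-null stays flat", {
  reg <- get_small_regulome()
  ft <- reg$truth$factor_table
  cand <- ft$factor_id[ft$state_class == "promoter" & ft$role == "anchor"]
  # the best-powered promoter factor (Fisher significance needs peak numbers)
  f <- cand[which.max(vapply(reg$collections[cand], function(pc)
    nrow(pc$peaks), numeric(1)))]
  enr <- state_enrichment(reg$collections[[f]], reg$segmentation, reg$genome,
                          seed = 6, fold = 5)
  expect_equal(sum(enr$observed_fraction), 1, tolerance = 1e-12)
  prom_states <- names(reg$segmentation$class_map)[reg$segmentation$class_map == "promoter"]
  prom <- enr[enr$state %in% prom_states, ]
  expect_true(any(prom$log2_enrichment > 0 & prom$significant))
  # null drawn from the factor's own peaks: enrichment vanishes
  own <- reg$collections[[f]]$peaks[, c("chrom", "start", "end")]
  self <- state_enrichment(reg$collections[[f]], reg$segmentation, reg$genome,
                           null_intervals = own)
  expect_true(all(abs(self$log2_enrichment) <= 0.2))
})

test_that("state-profile clustering keeps duplicates together and validates k", {
  m <- rbind(a = c(1, 0, 0), a2 = c(1, 0, 0), b = c(0, 2, 1), c = c(-1, 0, 2))
  cl <- cluster_state_profiles(m, k = 3)
  expect_equal(cl[["a"]], cl[["a2"]])
  expect_equal(unname(cluster_state_profiles(m, k = 1)), rep(1, 4),
               ignore_attr = TRUE)
  expect_error(cluster_state_profiles(m, k = 9), "exceeds")
})

test_that("promoter/enhancer fractions partition peak centers", {
  seg <- seg_fixture()
  prom <- make_collection("A", "chr1", c(100, 500), c(300, 700), -1)
  pe <- promoter_enhancer_fractions(prom, seg)
  expect_equal(pe$f_promoter, 1)
  expect_equal(pe$f_enhancer, 0)
  mix <- make_collection("B", "chr1", c(100, 1100, 2100, 3100),
                         c(300, 1300, 2300, 3300), -1)
  pem <- promoter_enhancer_fractions(mix, seg)
  expect_equal(sum(pem$by_class), 1)
  expect_equal(pem$f_enhancer, 0.5)
})

test_that("regulatory elements merge same-class neighbours within 100 bp", {
  cm <- c(P = "promoter", E = "strong_enhancer", Q = "other")
  seg <- state_segmentation(
    data.frame(chrom = "chr1", start = c(0, 180, 400, 700),
               end = c(100, 300, 480, 900), state = c("P", "P", "E", "P")),
    cm)
  el <- build_elements(seg)
  expect_equal(nrow(el), 3)
  expect_equal(el$end[1] - el$start[1], 300)     # merged across the 80-bp gap
  # different classes 80 bp apart stay apart
  seg2 <- state_segmentation(
    data.frame(chrom = "chr1", start = c(0, 180), end = c(100, 300),
               state = c("P", "E")), cm)
  expect_equal(nrow(build_elements(seg2)), 2)
  # idempotence and a brute-force gap-scan oracle on random segmentations
  set.seed(84)
  for (rep in 1:5) {
    starts <- sort(sample(seq(0, 5000, 60), 25))
    segs <- data.frame(chrom = "chr1", start = starts,
                       end = starts + sample(20:50, 25, TRUE),
                       state = sample(c("P", "E"), 25, TRUE))
    sg <- state_segmentation(segs, cm)
    el1 <- build_elements(sg)
    oracle <- 1
    for (i in 2:nrow(sg$segments)) {
      same <- cm[sg$segments$state[i]] == cm[sg$segments$state[i - 1]]
      gap <- sg$segments$start[i] - sg$segments$end[i - 1]
      if (!(same && gap <= 100)) oracle <- oracle + 1
    }
    expect_equal(nrow(el1), oracle)
    el_seg <- state_segmentation(cbind(el1[, 1:3],
                                       state = c(promoter = "P",
                                                 strong_enhancer = "E")[el1$element_class]),
                                 cm)
    expect_equal(nrow(build_elements(el_seg)), nrow(el1))
  }
})

test_that("element CAP counts equal brute-force overlap enumeration", {
  elements <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                         end = c(500, 1500, 2500),
                         element_class = c("promoter", "promoter", "strong_enhancer"))
  cols <- list(make_collection("A", "chr1", c(100, 1100), c(200, 1200)),
               make_collection("B", "chr1", 480, 520),
               make_collection("C", "chr1", 600, 900))
  cc <- element_cap_counts(elements, cols)
  expect_equal(cc$counts$n_caps, c(2, 1, 0))
  expect_equal(cc$summary$fraction_zero, 1 / 3)
  set.seed(85)
  el2 <- data.frame(chrom = "chr1", start = seq(0, 4500, 500))
  el2$end <- el2$start + 300
  el2$element_class <- "promoter"
  cols2 <- lapply(LETTERS[1:5], function(f) {
    s <- sample(0:4700, 12)
    make_collection(f, "chr1", s, s + sample(30:150, 12, TRUE))
  })
  cc2 <- element_cap_counts(el2, cols2)
  for (i in seq_len(nrow(el2))) {
    n <- sum(vapply(cols2, function(pc)
      any(pc$peaks$start < el2$end[i] & pc$peaks$end > el2$start[i]),
      logical(1)))
    expect_equal(cc2$counts$n_caps[i], n)
  }
})

test_that("CpG promoter classes follow the subwindow GC and o/e rules", {
  g <- genome_from_strings(list(
    cpg = strrep("CG", 1500),
    flat = strrep("AT", 1500),
    chr1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE,
                        prob = c(0.295, 0.205, 0.205, 0.295)), collapse = "")))
  hi <- classify_promoter_cpg(g, data.frame(chrom = "cpg", tss = 1500))
  expect_equal(hi$class, "high")
  lo <- classify_promoter_cpg(g, data.frame(chrom = "flat", tss = 1500))
  expect_equal(lo$class, "low")
  tr <- classify_promoter_cpg(g, data.frame(chrom = "cpg", tss = 100))
  expect_true(tr$truncated)
  # background promoter: class matches a brute-force subwindow scan
  res <- classify_promoter_cpg(g, data.frame(chrom = "chr1", tss = 1500))
  v <- strsplit(genome_string(g, "chr1", 500, 2500), "")[[1]]
  oes <- gcs <- numeric(1501)
  for (s in 1:1501) {
    w <- v[s:(s + 499)]
    nC <- sum(w == "C"); nG <- sum(w == "G")
    ncg <- sum(w[-500] == "C" & w[-1] == "G")
    gcs[s] <- (nC + nG) / 500
    oes[s] <- if (nC * nG > 0) ncg * 500 / (nC * nG) else 0
  }
  want <- if (any(gcs >= 0.55 & oes >= 0.6)) "high"
          else if (all(oes < 0.4)) "low" else "intermediate"
  expect_equal(res$class, want)
})

test_that("conservation by occupancy tracks per-base overlap and group contrast", {
  loci <- data.frame(chrom = "chr1", start = c(0, 1000, 2000, 3000),
                     end = c(500, 1500, 2500, 3500))
  counts <- c(2, 8, 21, 25)
  cons_bed <- data.frame(chrom = "chr1", start = c(100, 2100, 3000),
                         end = c(150, 2400, 3500))
  out <- conservation_by_occupancy(loci, counts, cons_bed,
                                   bin_edges = c(1, 5, 20, Inf))
  pb <- out$per_bin
  expect_equal(pb$overlap_fraction[pb$bin == "[1,5)"], 50 / 500)
  expect_equal(pb$overlap_fraction[pb$bin == "[5,20)"], 0)
  expect_equal(pb$overlap_fraction[pb$bin == "[20,Inf)"], 800 / 1000)
  expect_equal(pb$per_100bp, pb$overlap_fraction * 100)
  expect_equal(out$per_locus_fraction, c(0.1, 0, 0.6, 1))
  empty <- conservation_by_occupancy(loci, counts, cons_bed[0, ],
                                     bin_edges = c(1, 5, 20, Inf))
  expect_true(all(empty$per_bin$overlap_fraction == 0))
})

test_that("prediction accuracy sits at baseline without signal", {
  set.seed(86)
  x <- matrix(rbinom(3000, 1, 0.3), 300, 10)
  y <- rep(c("promoter", "enhancer"), 150)
  pr <- suppressWarnings(
    predict_state_from_binding(x, y, n_features_grid = c(5, 10), n_loci = 200,
                               iterations = 15, seed = 2, ntree = 60))
  expect_true(all(abs(pr$median - 0.5) <= 0.05))
  expect_warning(predict_state_from_binding(x, y, n_features_grid = 50,
                                            n_loci = 200, iterations = 2,
                                            seed = 2, ntree = 30), "clipped")
})
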