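toy_occupancy <- function(counts, n_fac = 100) {
  vals <- matrix(0L, length(counts), n_fac,
                 dimnames = list(NULL, sprintf("F%03d", seq_len(n_fac))))
  for (i in seq_along(counts)) vals[i, seq_len(counts[i])] <- 1L
  structure(list(loci = data.frame(chrom = "chr1",
                                   start = seq_along(counts) * 3000,
                                   end = seq_along(counts) * 3000 + 2000),
                 factors = colnames(vals), values = vals,
                 provenance = list(size_rule = "filter:2000")),
            class = "occupancy_matrix")
}

test_that("HOT detection is a strict count threshold with fractional resolution", {
  occ <- toy_occupancy(c(70, 71, 40, 100))
  hot <- detect_hot(occ, threshold = 70)
  expect_equal(hot$loci$n_factors, c(71, 100))       # 70 is not "more than 70"
  expect_equal(length(hot$factor_sets[[1]]), 71)
  # fraction resolves as ceiling(fraction x assayed), still strict
  hf <- detect_hot(occ, fraction = 1/3)              # ceil(100/3) = 34
  expect_equal(hf$threshold, 34)
  expect_equal(hf$loci$n_factors, c(70, 71, 40, 100))
  empty <- build_loci(list(make_collection("A", "chr1", 0, 100, 50)),
                      min_factors = 2)
  expect_warning(none <- detect_hot(empty, threshold = 1), "not below")
  expect_equal(nrow(none$loci), 0)
  expect_warning(detect_hot(occ, threshold = 200), "not below")
})

test_that("HOT detection counts distinct factors regardless of order", {
  cols <- list(make_collection("A", "chr1", c(100, 110), c(400, 410), 150),
               make_collection("B", "chr1", 120, 420, 150),
               make_collection("C", "chr1", 90, 390, 160))
  occ1 <- build_loci(cols, min_factors = 1)
  occ2 <- build_loci(rev(cols), min_factors = 1)
  h1 <- detect_hot(occ1, threshold = 2)
  h2 <- detect_hot(occ2, threshold = 2)
  expect_equal(h1$loci$n_factors, h2$loci$n_factors)  # duplicate peak of A counts once
  expect_equal(h1$loci$n_factors, 3)
})

test_that("HOT state composition is a unit partition over element classes", {
  seg <- state_segmentation(
    data.frame(chrom = "chr1", start = c(0, 50000), end = c(50000, 400000),
               state = c("P", "Q")),
    c(P = "promoter", Q = "other"))
  occ <- toy_occupancy(c(50, 60))
  hot <- detect_hot(occ, threshold = 40)
  comp <- hot_state_composition(hot, seg)
  expect_equal(sum(comp), 1)
  expect_equal(unname(comp["promoter"]), 1)
})

test_that("subsampling recovery is exact at the full factor set", {
  reg <- get_small_regulome()
  occ <- build_loci(reg$collections)
  hot <- detect_hot(occ, fraction = 1/3)
  mp <- matrix(FALSE, nrow(hot$loci), length(occ$factors),
               dimnames = list(NULL, occ$factors))
  for (i in seq_len(nrow(hot$loci)))
    mp[i, hot$factor_sets[[i]][1:2]] <- TRUE       # plant 2 known motifs/locus
  expect_warning(sub <- subsample_recovery(occ, hot, mp, k_grid = c(12, 30, 500),
                                           iterations = 30, seed = 4),
                 "skipped")
  full <- sub[sub$k == length(occ$factors), ]
  expect_equal(full$median[full$metric == "identification"], 1)
  expect_equal(full$min[full$metric == "identification"], 1)
  # with exactly 2 planted motifs per locus, >=3 never happens at full k
  expect_equal(full$median[full$metric == "ge2"], 1)
  expect_equal(full$max[full$metric == "ge3"], 0)
})

test_that("anchor profiles rank occupants and keep within scanned-factor bounds", {
  reg <- get_small_regulome()
  occ <- build_loci(reg$collections)
  hot <- detect_hot(occ, fraction = 1/3)
  prof <- anchor_profile(hot, reg$motif_db[1:6], reg$genome,
                         background_fold = 4, seed = 8)
  expect_true(all(prof$per_locus$n_strong + prof$per_locus$n_weak <= 6))
  expect_true(all(prof$per_locus$strongest_factor %in%
                    c(names(reg$motif_db)[1:6], NA)))
  # single factor, single locus: that factor is strongest
  one <- hot
  one$loci <- one$loci[1, , drop = FALSE]
  one$factor_sets <- one$factor_sets[1]
  one$locus_idx <- one$locus_idx[1]
  p1 <- anchor_profile(one, reg$motif_db[1], reg$genome, background_fold = 4,
                       seed = 8, occupants_only = FALSE)
  expect_equal(p1$per_locus$strongest_factor, names(reg$motif_db)[1])
})

test_that("expression comparisons assign nearest TSSs and respect null controls", {
  reg <- get_small_regulome()
  # nearest-TSS assignment equals a linear scan (via the control group's genes)
  tg <- reg$truth$tether_graph
  a <- reg$collections[[tg$anchor[1]]]; b <- reg$collections[[tg$tether[1]]]
  ex <- expression_by_cooccupancy(a, b, reg$gene_table, reg$genome, seed = 3)
  expect_true(all(c("both", "a_only", "b_only", "control") %in% names(ex$groups)))
  # flat expression: no comparison is significant
  flat <- reg$gene_table
  flat$tpm <- 7
  exf <- expression_by_cooccupancy(a, b, flat, reg$genome, seed = 3)
  expect_true(all(exf$tests$p > 0.99))
  # brute-force nearest-TSS oracle for the "both" sites
  ca <- peak_centers(a); cb <- peak_centers(b)
  near <- vapply(seq_along(ca), function(i)
    any(b$peaks$chrom == a$peaks$chrom[i] & abs(cb - ca[i]) <= 100), logical(1))
  want <- vapply(which(near), function(i) {
    g <- reg$gene_table[reg$gene_table$chrom == a$peaks$chrom[i], ]
    g$tpm[which.min(abs(g$tss - ca[i]))]
  }, numeric(1))
  expect_equal(ex$groups$both, want)
})
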