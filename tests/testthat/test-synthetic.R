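test_that("the generator is fully deterministic in (config, seed)", {
  cfg <- small_config(seed = 9)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$code, g2$code)
  expect_identical(g1$mask, g2$mask)
  m1 <- generate_factor_models(cfg)
  m2 <- generate_factor_models(cfg)
  expect_identical(lapply(m1$pwms, `[[`, "matrix"),
                   lapply(m2$pwms, `[[`, "matrix"))
  # and a different seed changes the sequence
  expect_false(identical(generate_genome(small_config(seed = 10))$code, g1$code))
})

test_that("background composition and masking hit their configured levels", {
  cfg <- synth_config(seed = 5, n_chroms = 2, chrom_length_bp = 500000,
                      background_gc = 0.5, repeat_fraction = 0.2,
                      n_promoters = 120, n_strong_enhancers = 100,
                      n_weak_enhancers = 60, n_hot_loci = 4,
                      n_anchor_factors = 24, n_tethered_factors = 8,
                      n_chromatin_factors = 8,
                      hot_strong_anchor_range = c(1, 3),
                      hot_weak_factor_range = c(8, 16))
  g <- generate_genome(cfg)
  gc <- sum(vapply(g$code, function(v) sum(v == 2L | v == 3L), numeric(1))) /
    sum(g$lengths)
  expect_lt(abs(gc - 0.5), 0.01)
  masked <- sum(vapply(g$mask, sum, numeric(1))) / sum(g$lengths)
  expect_lt(abs(masked - 0.2), 0.02)
})

test_that("anchor PWMs reach the configured information content", {
  cfg <- small_config(anchor_motif_ic_bits = 12, anchor_motif_length = 8)
  models <- generate_factor_models(cfg)
  ics <- vapply(models$pwms, motif_ic, numeric(1))
  expect_true(all(abs(ics - 12) <= 0.5))
  expect_error(generate_factor_models(small_config(anchor_motif_ic_bits = 30,
                                                   anchor_motif_length = 8)),
               "unreachable")
  none <- generate_factor_models(small_config(n_tethered_factors = 0))
  expect_equal(nrow(none$tether_graph), 0)
})

test_that("full-strength planted motifs are recovered at p <= 1e-4", {
  reg <- get_small_regulome()
  fac <- reg$truth$factor_table
  ev <- reg$truth$events
  for (f in fac$factor_id[fac$role == "anchor"][1:5]) {
    pc <- reg$collections[[f]]
    w <- peak_windows(pc)
    seqs <- interval_sequences(reg$genome, w[, c("chrom", "start", "end")],
                               w$seq_id)
    hits <- scan_pwm(reg$motif_db[[f]], seqs, p_threshold = 1e-4)
    found <- w$seq_id %in% hits$seq_id
    # peak names record the generation-order event index
    evf <- ev[ev$factor_id == f, ]
    pk_name_order <- as.integer(sub(".*_", "", pc$peaks$name))
    strong <- evf$plant[pk_name_order] == "strong"
    expect_gte(mean(found[strong]), 0.99)
  }
})

test_that("tethered factors co-occur with their anchors at the configured rate", {
  reg <- get_small_regulome()
  tg <- reg$truth$tether_graph
  for (k in seq_len(min(4, nrow(tg)))) {
    a <- peak_centers(reg$collections[[tg$anchor[k]]])
    ach <- reg$collections[[tg$anchor[k]]]$peaks$chrom
    t <- peak_centers(reg$collections[[tg$tether[k]]])
    tch <- reg$collections[[tg$tether[k]]]$peaks$chrom
    near <- vapply(seq_along(t), function(i)
      any(ach == tch[i] & abs(a - t[i]) <= 100), logical(1))
    expect_gte(mean(near), 0.8)       # configured rate 0.9, binomial slack
  }
})

test_that("a regulome without HOT loci yields no HOT calls", {
  # element CAP counts capped below the detection threshold, as at full scale
  cfg <- small_config(seed = 12, n_hot_loci = 0, max_caps_per_element = 12)
  reg <- generate_regulome(cfg)
  occ <- build_loci(reg$collections)
  expect_warning(hot <- detect_hot(occ, fraction = 1/3), NA)
  expect_equal(nrow(hot$loci), 0)
})

test_that("the planted truth round-trips losslessly through JSON", {
  reg <- get_small_regulome()
  tmp <- tempfile(fileext = ".json")
  write_truth(reg$truth, tmp)
  back <- read_truth(tmp)
  expect_equal(back$factor_table, reg$truth$factor_table)
  expect_equal(back$elements, reg$truth$elements)
  expect_equal(back$tether_graph, reg$truth$tether_graph)
  expect_equal(back$gene_table, reg$truth$gene_table, tolerance = 1e-12)
  expect_equal(back$consensus, reg$truth$consensus)
  expect_equal(back$hot_truth, reg$truth$hot_truth)
})

test_that("emitted dataset files reload to the in-memory regulome", {
  cfg <- small_config(seed = 13, n_promoters = 60, n_strong_enhancers = 50,
                      n_weak_enhancers = 30, n_hot_loci = 4)
  out <- tempfile("simdir")
  reg <- generate_regulome(cfg)
  paths <- synthesize_datasets(cfg, out, regulome = reg)
  g <- read_fasta(paths$fasta)
  expect_identical(g$code, reg$genome$code)
  expect_identical(g$mask, reg$genome$mask)
  f1 <- names(reg$collections)[1]
  pc <- read_narrowpeak(file.path(paths$peaks, paste0(f1, ".narrowPeak")), f1,
                        genome = g)
  expect_equal(pc$peaks, reg$collections[[f1]]$peaks)
  seg <- read_segmentation(paths$segmentation, reg$segmentation$class_map)
  expect_equal(covered_bases(seg$segments[seg$segments$state != "Q", ]),
               covered_bases(reg$segmentation$segments[
                 reg$segmentation$segments$state != "Q", ]))
  mot <- read_meme_motifs(paths$motifs)
  expect_equal(names(mot), unname(vapply(reg$motif_db, `[[`, character(1), "id")))
  expect_lt(max(abs(mot[[1]]$matrix - reg$motif_db[[1]]$matrix)), 1e-6)
  ann <- read_motif_annotation(paths$annotation)
  expect_equal(ann$factor_id, reg$annotation$factor_id)
  unlink(out, recursive = TRUE)
})
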