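test_that("similarity recognises identity and reverse-complement identity", {
  set.seed(51)
  pwm <- random_pwm("q", 8)
  self <- motif_similarity(pwm, pwm, seed = 1)
  expect_equal(self$score, 1, tolerance = 1e-9)
  expect_equal(self$best_offset, 0)
  expect_equal(self$orientation, "same")
  rc <- reverse_complement(pwm); rc$id <- "q_rc"
  flip <- motif_similarity(pwm, rc, seed = 1)
  expect_equal(flip$score, 1, tolerance = 1e-9)
  expect_equal(flip$orientation, "revcomp")
  expect_error(motif_similarity(pwm, random_pwm("t", 3), min_overlap = 4),
               "min_overlap")
})

test_that("similarity score is symmetric and the shuffle null is calibrated", {
  set.seed(52)
  for (i in 1:8) {
    q <- random_pwm("q", sample(5:9, 1)); t <- random_pwm("t", sample(5:9, 1))
    s1 <- motif_similarity(q, t, n_shuffles = 50, seed = 2)$score
    s2 <- motif_similarity(t, q, n_shuffles = 50, seed = 2)$score
    expect_equal(s1, s2, tolerance = 1e-9)
  }
  # dissimilar random motif pairs (best score < 0.6, i.e. no chance family
  # resemblance): the null is calibrated, so p <= 0.05 occurs at its nominal
  # ~5% rate -- no significant excess of small p over 100 seeded runs
  ps <- c(); s <- 0
  while (length(ps) < 100) {
    s <- s + 1
    set.seed(1000 + s)
    q <- random_pwm("q", 8); t <- random_pwm("t", 8)
    r <- motif_similarity(q, t, n_shuffles = 1000, seed = s)
    if (r$score < 0.6) ps <- c(ps, r$p_value)
  }
  expect_gte(mean(ps > 0.05), 0.90)
  expect_gt(stats::binom.test(sum(ps <= 0.05), length(ps), 0.05,
                              alternative = "greater")$p.value, 0.01)
})

test_that("concordance calls follow annotation, thresholds, and overrides", {
  set.seed(53)
  own <- random_pwm("M1", 8); own$factor_annotation <- "TFA"
  other <- random_pwm("M2", 8); other$factor_annotation <- "TFB"
  db <- list(own, other)
  same <- classify_concordance(own, "TFA", db, n_shuffles = 500, seed = 4)
  expect_equal(same$call, "concordant")
  expect_equal(same$best_match_id, "M1")
  cross <- classify_concordance(own, "TFC", db, n_shuffles = 500, seed = 4)
  expect_equal(cross$call, "discordant")
  expect_equal(cross$best_match_factor, "TFA")
  # manual override forces the published call
  forced <- classify_concordance(own, "TFA", db, n_shuffles = 500, seed = 4,
                                 overrides = c(M1 = "discordant"))
  expect_equal(forced$call, "discordant")
  expect_true(forced$override_applied)
  expect_warning(nov <- classify_concordance(own, "TFA", list()), "empty")
  expect_equal(nov$call, "novel")
  # determinism given the seed
  rep1 <- classify_concordance(own, "TFA", db, n_shuffles = 300, seed = 7)
  rep2 <- classify_concordance(own, "TFA", db, n_shuffles = 300, seed = 7)
  expect_identical(rep1, rep2)
})

test_that("similarity matrix is symmetric with unit diagonal and clusters families", {
  set.seed(54)
  base <- random_pwm("fam", 8)
  jitter <- function(id) {
    m <- apply(base$matrix, 2, function(col)
      as.numeric(stats::rmultinom(1, 300, col)) / 300)
    m[m == 0] <- 1e-3
    pwm_motif(id, sweep(m, 2, colSums(m), "/"))
  }
  motifs <- c(lapply(paste0("f", 1:3), jitter),
              lapply(paste0("r", 1:3), function(id) random_pwm(id, 8)))
  sm <- similarity_matrix(motifs, motifs)
  expect_equal(unname(diag(sm$scores)), rep(1, 6), tolerance = 1e-9)
  expect_equal(sm$scores, t(sm$scores), tolerance = 1e-9)
  cl <- stats::cutree(sm$row_hclust, k = 2)
  expect_equal(length(unique(cl[paste0("f", 1:3)])), 1)
  expect_false(cl[["f1"]] %in% cl[paste0("r", 1:3)])
})

test_that("motif GC content and information content compute directly", {
  expect_equal(motif_gc_content(pwm_motif("u", matrix(0.25, 4, 3))), 0.5)
  expect_equal(motif_gc_content(pwm_motif("a", matrix(c(1, 0, 0, 0), 4, 2))), 0)
  hand <- pwm_motif("h", matrix(c(1, 0, 0, 0, 0, 0.5, 0.5, 0), 4, 2))
  expect_equal(motif_gc_content(hand), 0.5)   # (0 + 1) / 2
  expect_equal(motif_ic(pwm_motif("i", matrix(c(1, 0, 0, 0), 4, 1))), 2)
  expect_equal(motif_ic(pwm_motif("u", matrix(0.25, 4, 4))), 0)
})
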