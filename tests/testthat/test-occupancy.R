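test_that("occupancy matrices count distinct factors by summit membership", {
  one <- make_collection("A", "chr1", 100, 400, summit = 150)
  expect_warning(empty <- build_loci(list(one), min_factors = 2), NA)
  expect_equal(nrow(empty$loci), 0)

  three <- list(make_collection("A", "chr1", 100, 400, 150),
                make_collection("B", "chr1", 120, 420, 150),
                make_collection("C", "chr1", 90, 390, 160))
  occ <- build_loci(three, mode = "windows")
  expect_equal(unname(rowSums(occ$values)), 3)

  set.seed(71)
  cols <- lapply(LETTERS[1:6], function(f) {
    s <- sample(seq(0, 9000, 10), 40)
    make_collection(f, "chr1", s, s + 200, summit = 100)
  })
  occ2 <- build_loci(cols, mode = "windows", min_factors = 1)
  # brute force: distinct factors whose summit falls in each window
  for (i in seq_len(nrow(occ2$loci))) {
    n <- sum(vapply(cols, function(pc) {
      cent <- peak_centers(pc)
      any(cent >= occ2$loci$start[i] & cent < occ2$loci$end[i])
    }, logical(1)))
    expect_equal(unname(rowSums(occ2$values))[i], n)
  }
  # row sums invariant to collection order
  occ3 <- build_loci(rev(cols), mode = "windows", min_factors = 1)
  expect_equal(rowSums(occ3$values), rowSums(occ2$values))
})

test_that("TSS-proximal fractions use a closed +/-3 kb window on expressed genes", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                      tss = c(10000, 50000), tpm = c(5, 0.2))
  at_tss <- make_collection("A", "chr1", 9900, 10100, 100)
  expect_equal(tss_proximal_fraction(at_tss, genes), 1)
  # center at tss+3000 counts; +3001 does not; low-TPM TSSs never count
  edges <- make_collection("B", "chr1", c(12900, 12901, 49900),
                           c(13100, 13101, 50100), 100)
  expect_equal(tss_proximal_fraction(edges, genes), 1 / 3)
  expect_error(tss_proximal_fraction(
    peak_collection("C", data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0))), genes), "empty")
})

test_that("locus PCA is complete, variance-accounted, and flags rank misuse", {
  x <- cbind(rep(1, 10), c(rep(0, 5), rep(1, 5)))
  p1 <- pca_loci(x, 1)
  expect_equal(abs(unname(p1$loadings[, 1])), c(0, 1))
  expect_equal(unname(p1$variance_fraction[1]), 1)
  expect_error(pca_loci(x, 2), "non-constant|rank")

  set.seed(72)
  m <- matrix(rbinom(200, 1, 0.4), 20, 10)
  pr <- pca_loci(m, n_components = min(10, qr(scale(m, scale = FALSE))$rank))
  recon <- pr$scores %*% t(pr$loadings)
  centered <- scale(m, scale = FALSE)
  expect_lt(max(abs(recon - centered)), 1e-8)
  expect_equal(pr$total_variance, sum(apply(m, 2, stats::var)), tolerance = 1e-8)
})

test_that("variance-weighted PC distances reproduce the hand computation", {
  pca <- structure(list(loadings = rbind(c(1, 0), c(0, 1)),
                        variance_fraction = c(0.6, 0.4)), class = "pca_result")
  D <- factor_pc_distance(pca)
  expect_equal(D[1, 2], 1)                       # sqrt(0.6 + 0.4)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), c(0, 0))
  set.seed(73)
  pca2 <- structure(list(loadings = matrix(rnorm(15), 5),
                         variance_fraction = c(0.5, 0.3, 0.2)),
                    class = "pca_result")
  D2 <- factor_pc_distance(pca2)
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(D2[i, j], D2[i, k] + D2[k, j] + 1e-12)
})

test_that("summit-window overlaps use closed +/-50 bp windows", {
  a <- make_collection("a", "chr1", c(50, 950), c(150, 1050), 50)   # summits 100, 1000
  b <- make_collection("b", "chr1", 70, 170, 50)                    # summit 120
  M <- pairwise_overlap_matrix(list(a, b))
  expect_equal(M["a", "a"], 1)
  expect_equal(M["a", "b"], 0.5)
  expect_equal(M["b", "a"], 1)
  # summits 101 bp apart leave a 1-bp gap between closed windows
  c1 <- make_collection("c", "chr1", 150, 250, 51)                  # summit 201
  M2 <- pairwise_overlap_matrix(list(a, c1))
  expect_equal(M2["a", "c"], 0)
  # duplicating a collection reproduces its row
  dup <- make_collection("a2", "chr1", c(50, 950), c(150, 1050), 50)
  M3 <- pairwise_overlap_matrix(list(a, b, dup))
  expect_equal(unname(M3["a2", c("a", "b")]), unname(M3["a", c("a", "b")]))
  # empty factor flagged undefined
  e <- peak_collection("e", data.frame(chrom = character(0), start = numeric(0),
                                       end = numeric(0)))
  M4 <- pairwise_overlap_matrix(list(a, e))
  expect_true(all(is.na(M4["e", ])))
  expect_equal(attr(M4, "undefined"), "e")
})

test_that("co-binding edges obey the 75% threshold and shrink as it rises", {
  M <- matrix(c(1, 0.749, 0.75, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  net <- cobind_network(M, 0.75)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$from, "b")          # M[b, a] = 0.75 >= threshold
  # duplicated factor: reciprocal unit edges
  dupM <- matrix(1, 2, 2, dimnames = list(c("a", "a2"), c("a", "a2")))
  expect_equal(nrow(cobind_network(dupM, 0.75)$edges), 2)
  # monotone non-increasing edge count in the threshold
  set.seed(74)
  R <- matrix(runif(64), 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  sizes <- vapply(c(0.2, 0.5, 0.8), function(t) nrow(cobind_network(R, t)$edges),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("count correlations are rank-based and match a direct oracle", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 20, 30), c = c(3, 2, 1))
  M <- count_correlation(x)
  expect_equal(M["a", "a"], 1)
  expect_equal(M["a", "b"], 1)
  expect_equal(M["a", "c"], -1)
  set.seed(75)
  y <- matrix(rpois(60, 8), 20, 3, dimnames = list(NULL, c("u", "v", "w")))
  My <- count_correlation(y)
  oracle <- stats::cor(apply(y, 2, rank))
  expect_equal(unname(My), unname(oracle), tolerance = 1e-12,
               ignore_attr = TRUE)
  yc <- cbind(y, k = rep(4, 20))
  Mc <- count_correlation(yc)
  expect_true(is.na(Mc["k", "u"]))
  expect_equal(attr(Mc, "undefined"), "k")
  expect_equal(Mc["k", "k"], 1)
  expect_error(count_correlation(cbind(a = c(-1, 2))), "non-negative")
})

test_that("co-occupancy profiles are normalized distributions over CAP bins", {
  set.seed(76)
  vals <- matrix(0L, 30, 6, dimnames = list(NULL, LETTERS[1:6]))
  vals[1:10, 1] <- 1L                       # factor A: singleton loci only
  vals[11:30, 2:6] <- 1L                    # the rest co-occupy 5-factor loci
  occ <- structure(list(loci = data.frame(chrom = "chr1",
                                          start = seq(0, 29000, 1000),
                                          end = seq(500, 29500, 1000)),
                        factors = LETTERS[1:6], values = vals,
                        provenance = list()), class = "occupancy_matrix")
  prof <- cooccupancy_profile(occ, bin_edges = c(1, 2, 3, 5, 7), k = 2)
  expect_equal(unname(rowSums(prof$profile)), rep(1, 6))
  expect_equal(unname(prof$profile["A", 1]), 1)     # all mass in lowest bin
  expect_equal(length(unique(prof$clusters[c("B", "C")])), 1)
  expect_false(prof$clusters[["A"]] == prof$clusters[["B"]])
})
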