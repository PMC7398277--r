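# Shared fixtures and independent brute-force oracles.

# reduced-scale simulation used by unit tests (the acceptance suite runs the
# reference scale)
small_config <- function(seed = 3, ...) {
  base <- list(seed = seed, n_chroms = 2, chrom_length_bp = 400000,
               n_promoters = 150, n_strong_enhancers = 120,
               n_weak_enhancers = 80, n_hot_loci = 8,
               n_anchor_factors = 24, n_tethered_factors = 10,
               n_chromatin_factors = 10,
               hot_strong_anchor_range = c(1, 3),
               hot_weak_factor_range = c(8, 16),
               n_silent_genes = 40)
  do.call(synth_config, utils::modifyList(base, list(...)))
}

# memoized regulomes so several test files can share one generation
.fixture_env <- new.env(parent = emptyenv())

get_small_regulome <- function() {
  if (is.null(.fixture_env$small)) .fixture_env$small <-
    generate_regulome(small_config())
  .fixture_env$small
}

get_default_regulome <- function() {
  if (is.null(.fixture_env$default)) .fixture_env$default <-
    generate_regulome(synth_config(seed = 1))
  .fixture_env$default
}

get_default_occupancy <- function() {
  if (is.null(.fixture_env$default_occ)) .fixture_env$default_occ <-
    build_loci(get_default_regulome()$collections)
  .fixture_env$default_occ
}

random_intervals <- function(n, max_pos = 1000, max_len = 120,
                             chroms = c("chr1", "chr2")) {
  s <- sample.int(max_pos, n, replace = TRUE) - 1
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + sample.int(max_len, n, replace = TRUE))
}

# per-base coverage set of an interval data.frame, as "chrom:pos" keys
covered_bases <- function(iv) {
  if (!nrow(iv)) return(character(0))
  unlist(lapply(seq_len(nrow(iv)), function(i)
    paste0(iv$chrom[i], ":", seq(iv$start[i], iv$end[i] - 1))))
}

# quadratic brute-force intersection oracle
brute_intersect <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= 1) out[[length(out) + 1]] <-
        data.frame(a_idx = i, b_idx = j, overlap = ov)
  }
  if (!length(out)) return(data.frame(a_idx = integer(0), b_idx = integer(0),
                                      overlap = numeric(0)))
  do.call(rbind, out)
}

# hypergeometric tail by explicit enumeration
enum_fisher <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  if (N == 0 || K == 0 || n == 0) return(1)
  ks <- max(0, n - (N - K)):min(K, n)
  sum(vapply(ks[ks >= a], function(k)
    choose(K, k) * choose(N - K, n - k) / choose(N, n), numeric(1)))
}

# KS statistic by an ECDF sweep over the pooled sample
brute_ks_D <- function(a, b) {
  v <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(v) - stats::ecdf(b)(v)))
}

# Monte Carlo permutation estimate of the two-sample KS p-value
perm_ks_p <- function(a, b, n_perm = 1e5, seed = 99) {
  pool <- c(a, b); n1 <- length(a); n <- length(pool)
  o <- order(pool)
  d_obs <- brute_ks_D(a, b)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    z <- logical(n); z[sample.int(n, n1)] <- TRUE
    zz <- z[o]
    d <- max(abs(cumsum(zz) / n1 - cumsum(!zz) / (n - n1)))
    if (d >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

random_pwm <- function(id, L, conc = 0.8) {
  m <- matrix(stats::rgamma(4 * L, conc), 4, L)
  m <- sweep(m, 2, colSums(m), "/")
  pwm_motif(id, m)
}

# genome built directly from strings (uppercase = unmasked)
genome_from_strings <- function(seqs) {
  tmp <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             tmp)
  on.exit(unlink(tmp))
  read_fasta(tmp)
}

make_collection <- function(factor_id, chrom, start, end, summit = -1) {
  peak_collection(factor_id, data.frame(chrom = chrom, start = start, end = end,
                                        summit = summit))
}
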