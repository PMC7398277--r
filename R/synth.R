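# Synthetic regulome generator.
#
# Builds, from a seed and a configuration, a small soft-masked genome plus
# per-factor peak sets, a chromatin-state segmentation, a motif library,
# expression and count tables, and a planted-truth record. The design mirrors
# the structure large ChIP-seq compendia report: sequence-specific anchor
# factors with strong centered motifs, tethered factors recruited at an
# offset from their anchor's motif, chromatin regulators without motifs,
# regulatory elements averaging a handful of bound factors with most elements
# empty, and a small set of HOT loci bound by the majority of factors with
# 1-5 strong planted motifs and 25-50 degenerate ones.

#' Synthetic regulome configuration
#'
#' Defaults define the reference simulation scale: a 4 x 1.5 Mb genome,
#' 120 factors (60 anchors, 30 tethered, 30 chromatin regulators), ~5,000
#' regulatory elements of which a third are occupied (mean 7 CAPs each), and
#' 50 HOT loci carrying 1-5 strong and 25-50 degenerate planted motifs.
#'
#' @param seed base seed; stage seeds are derived by fixed offsets so adding
#'   a stage never perturbs earlier stages.
#' @param n_chroms,chrom_length_bp genome dimensions.
#' @param background_gc,repeat_fraction background base composition and
#'   soft-masked fraction.
#' @param n_promoters,n_strong_enhancers,n_weak_enhancers,n_hot_loci element
#'   counts.
#' @param n_anchor_factors,n_tethered_factors,n_chromatin_factors factor
#'   counts per role.
#' @param anchor_motif_length,anchor_motif_ic_bits anchor PWM geometry.
#' @param tether_offset_mean_bp,tether_offset_sd_bp tether summit offset from
#'   the anchor motif center.
#' @param tether_cooccurrence_rate fraction of a tethered factor's peaks that
#'   co-occur with its anchor.
#' @param peak_width_bp called peak width.
#' @param hot_strong_anchor_range,hot_weak_factor_range planted strong/weak
#'   motif counts per HOT locus.
#' @param hot_state_props HOT locus class proportions
#'   (promoter/strong_enhancer/other).
#' @param element_width_bp,hot_width_bp element footprints.
#' @param element_occupied_fraction fraction of elements with any binding.
#' @param mean_caps_per_element mean distinct CAPs over occupied elements.
#' @param max_caps_per_element hard cap on CAPs per ordinary element (kept
#'   well below the HOT detection threshold).
#' @param background_peak_rate extra random peaks per factor (fraction of its
#'   true peaks).
#' @param expression_lognormal_params c(meanlog, sdlog) of base expression.
#' @param expression_occupancy_beta meanlog increase per log1p(bound CAPs).
#' @param n_silent_genes unexpressed TSSs placed outside elements.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_chroms = 4, chrom_length_bp = 1500000,
                         background_gc = 0.41, repeat_fraction = 0.12,
                         n_promoters = 2000, n_strong_enhancers = 1800,
                         n_weak_enhancers = 1200, n_hot_loci = 50,
                         n_anchor_factors = 60, n_tethered_factors = 30,
                         n_chromatin_factors = 30,
                         anchor_motif_length = 10, anchor_motif_ic_bits = 13,
                         tether_offset_mean_bp = 30, tether_offset_sd_bp = 8,
                         tether_cooccurrence_rate = 0.9,
                         peak_width_bp = 300,
                         hot_strong_anchor_range = c(1, 5),
                         hot_weak_factor_range = c(25, 50),
                         hot_state_props = c(promoter = 0.42,
                                             strong_enhancer = 0.50,
                                             other = 0.08),
                         element_width_bp = 600, hot_width_bp = 1400,
                         element_occupied_fraction = 0.33,
                         mean_caps_per_element = 7,
                         max_caps_per_element = 25,
                         background_peak_rate = 0.02,
                         expression_lognormal_params = c(1.5, 1.0),
                         expression_occupancy_beta = 0.25,
                         expression_cobind_boost = 1.5,
                         n_silent_genes = 300) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_chroms, cfg$chrom_length_bp, cfg$n_promoters,
              cfg$n_strong_enhancers, cfg$n_weak_enhancers, cfg$n_hot_loci,
              cfg$n_anchor_factors, cfg$n_tethered_factors, cfg$n_chromatin_factors)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (cfg$n_chroms < 1 || cfg$chrom_length_bp < 50000)
    stop("genome too small for the requested layout")
  if (diff(cfg$hot_strong_anchor_range) < 0 || diff(cfg$hot_weak_factor_range) < 0)
    stop("ranges must be ordered (lo, hi)")
  if (cfg$hot_strong_anchor_range[2] + cfg$hot_weak_factor_range[2] >
        cfg$n_anchor_factors - round(cfg$n_anchor_factors / 12))
    stop("HOT strong+weak motif ranges exceed the number of non-solitary ",
         "anchor factors")
  if (cfg$n_tethered_factors > 0 && cfg$n_anchor_factors < 2)
    stop("tethered factors require anchor factors")
  if (cfg$background_gc <= 0 || cfg$background_gc >= 1)
    stop("background_gc must be in (0, 1)")
  if (abs(sum(cfg$hot_state_props) - 1) > 1e-6)
    stop("hot_state_props must sum to 1")
  structure(cfg, class = "synth_config")
}

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + stage * 1000003) %% .Machine$integer.max)
}

distribute <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + as.integer(seq_len(k) <= extra)
}

# --- stage 1: element layout -------------------------------------------------

layout_elements <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chroms))
  np <- distribute(config$n_promoters, config$n_chroms)
  ns <- distribute(config$n_strong_enhancers, config$n_chroms)
  nw <- distribute(config$n_weak_enhancers, config$n_chroms)
  nh <- distribute(config$n_hot_loci, config$n_chroms)
  gap <- 350
  with_seed(stage_seed(config$seed, 1), {
    acc <- list()
    spare <- list()
    for (ci in seq_len(config$n_chroms)) {
      pos <- 10000
      place <- function(n, width, class, state_pool) {
        if (n == 0) return(NULL)
        starts <- integer(n); states <- character(n)
        for (i in seq_len(n)) {
          s <- pos + sample(0:80, 1)
          starts[i] <- s
          states[i] <- state_pool[1 + (i - 1) %% length(state_pool)]
          pos <<- s + width + gap
        }
        data.frame(chrom = chroms[ci], start = starts, end = starts + width,
                   class = class, state = states)
      }
      prom <- place(np[ci], config$element_width_bp, "promoter", c("P1", "P2"))
      pos <- pos + 5000
      str <- place(ns[ci], config$element_width_bp, "strong_enhancer", c("ES1", "ES2"))
      wk <- place(nw[ci], config$element_width_bp, "weak_enhancer", "EW1")
      pos <- pos + 5000
      hot <- place(nh[ci], config$hot_width_bp, "hot", "HOT")
      if (!is.null(hot)) {
        # extra spacing between HOT loci
        sh <- cumsum(c(0, rep(600, max(0, nrow(hot) - 1))))
        hot$start <- hot$start + sh; hot$end <- hot$end + sh
        pos <- pos + sum(rep(600, max(0, nrow(hot) - 1)))
      }
      if (pos + 5000 > config$chrom_length_bp)
        stop("chrom_length_bp too small for the requested elements",
             " (need > ", pos + 5000, " bp)")
      spare[[chroms[ci]]] <- c(pos + 2000, config$chrom_length_bp - 2000)
      acc[[ci]] <- rbind(prom, str, wk, hot)
    }
    elements <- do.call(rbind, acc)
    elements$is_hot <- elements$class == "hot"
    elements$element_id <- sprintf("el%05d", seq_len(nrow(elements)))
    # HOT locus classes drawn from the configured proportions
    hot_idx <- which(elements$is_hot)
    if (length(hot_idx)) {
      cls <- sample(names(config$hot_state_props), length(hot_idx),
                    replace = TRUE, prob = config$hot_state_props)
      elements$class[hot_idx] <- cls
      elements$state[hot_idx] <- c(promoter = "P1", strong_enhancer = "ES1",
                                   other = "Q")[cls]
    }
    rownames(elements) <- NULL
    list(elements = elements, chroms = chroms, spare = spare)
  })
}

# --- stage 2: genome ---------------------------------------------------------

#' Generate the synthetic background genome
#'
#' I.i.d. background sequence at the configured GC with contiguous
#' soft-masked repeat blocks totalling `repeat_fraction` of the genome,
#' placed outside planted elements. Deterministic for a given config.
#'
#' @param config a `synth_config`.
#' @param layout internal element layout (computed when NULL).
#' @return a `genome_sequence`.
#' @export
generate_genome <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- layout_elements(config)
  p <- c((1 - config$background_gc) / 2, config$background_gc / 2,
         config$background_gc / 2, (1 - config$background_gc) / 2)
  with_seed(stage_seed(config$seed, 2), {
    codes <- list(); masks <- list()
    for (ch in layout$chroms) {
      codes[[ch]] <- sample.int(4L, config$chrom_length_bp, replace = TRUE, prob = p)
      masks[[ch]] <- rep(FALSE, config$chrom_length_bp)
    }
    # repeat blocks in element-free space
    target <- round(config$repeat_fraction * config$n_chroms * config$chrom_length_bp)
    if (target > 0) {
      el <- layout$elements
      free <- list()
      for (ch in layout$chroms) {
        e <- el[el$chrom == ch, , drop = FALSE]
        e <- e[order(e$start), , drop = FALSE]
        bnd <- c(0, as.vector(rbind(e$start - 20, e$end + 20)), config$chrom_length_bp)
        s <- bnd[seq(1, length(bnd), 2)]; en <- bnd[seq(2, length(bnd), 2)]
        keep <- en - s > 120
        if (any(keep)) free[[ch]] <- data.frame(chrom = ch, start = s[keep], end = en[keep])
      }
      free <- do.call(rbind, free)
      # chop free space into ~600-bp chunks so each can host one repeat block
      free <- window_partition(sort_intervals(free), 600)
      free <- free[free$end - free$start > 120, , drop = FALSE]
      free <- free[sample.int(nrow(free)), , drop = FALSE]
      placed <- 0
      for (i in seq_len(nrow(free))) {
        if (placed >= target) break
        w <- min(sample(200:400, 1), free$end[i] - free$start[i] - 40,
                 target - placed)
        if (w < 50) next
        s <- free$start[i] + sample.int(free$end[i] - free$start[i] - w, 1)
        masks[[free$chrom[i]]][(s + 1):(s + w)] <- TRUE
        placed <- placed + w
      }
    }
    new_genome_sequence(codes, masks)
  })
}

# --- stage 3: factor models --------------------------------------------------

solve_pmax <- function(ic_per_col) {
  if (ic_per_col >= 2 - 1e-9 || ic_per_col <= 0)
    stop("unreachable per-column information content: ", signif(ic_per_col, 3),
         " bits (must be in (0, 2))")
  f <- function(p) {
    q <- (1 - p) / 3
    h <- -(p * log2(p) + 3 * q * log2(q))
    (2 - h) - ic_per_col
  }
  stats::uniroot(f, c(0.2501, 1 - 1e-9))$root
}

word_to_pwm <- function(id, word, p_max, factor_annotation = "") {
  L <- length(word)
  m <- matrix((1 - p_max) / 3, 4, L)
  m[cbind(word, seq_len(L))] <- p_max
  pwm_motif(id, m, factor_annotation = factor_annotation, source = "synthetic")
}

#' Generate factor motif models and the tether graph
#'
#' Anchor factors receive PWMs with total information content within 0.5 bits
#' of the configured target (single dominant base per column, consensus words
#' at pairwise Hamming distance >= 4); tethered and chromatin factors carry no
#' motif of their own. Tethered factors are attached to distinct non-solitary
#' anchors.
#'
#' @param config a `synth_config`.
#' @return list: `factors` (data.frame id/role/state_class/solitary/anchor_id),
#'   `pwms` (named list, anchors only), `tether_graph`, `annotation`
#'   (motif_id -> factor_id).
#' @export
generate_factor_models <- function(config) {
  na <- config$n_anchor_factors; nt <- config$n_tethered_factors
  nc <- config$n_chromatin_factors
  n_both <- round(na / 6); n_sol <- round(na / 12)
  n_prom <- ceiling((na - n_both - n_sol) / 2)
  n_enh <- na - n_both - n_sol - n_prom
  anchor_class <- c(rep("promoter", n_prom), rep("enhancer", n_enh),
                    rep("both", n_both),
                    rep(c("promoter", "enhancer"), length.out = n_sol))
  solitary <- c(rep(FALSE, na - n_sol), rep(TRUE, n_sol))
  ids_a <- sprintf("AN%02d", seq_len(na))
  ids_t <- if (nt) sprintf("TE%02d", seq_len(nt)) else character(0)
  ids_c <- if (nc) sprintf("CR%02d", seq_len(nc)) else character(0)
  with_seed(stage_seed(config$seed, 3), {
    L <- config$anchor_motif_length
    p_max <- solve_pmax(config$anchor_motif_ic_bits / L)
    # balanced base composition (no homopolymer-like consensus): low-complexity
    # words are chance-matched by column shuffles of themselves and make poor
    # anchor motifs; pairwise Hamming distance >= 4 keeps anchors distinct
    base_counts <- distribute(L, 4)
    words <- list()
    while (length(words) < na) {
      w <- sample(rep.int(1:4, sample(base_counts)))
      ok <- all(vapply(words, function(v) sum(v != w) >= 4, logical(1)))
      if (ok) words[[length(words) + 1]] <- w
    }
    pwms <- stats::setNames(lapply(seq_len(na), function(i)
      word_to_pwm(paste0("M_", ids_a[i]), words[[i]], p_max, ids_a[i])), ids_a)
    host_pool <- ids_a[!solitary]
    hosts <- if (nt) sample(host_pool, nt,
                            replace = nt > length(host_pool)) else character(0)
    factors <- data.frame(
      factor_id = c(ids_a, ids_t, ids_c),
      role = c(rep("anchor", na), rep("tethered", nt), rep("chromatin", nc)),
      state_class = c(anchor_class,
                      anchor_class[match(hosts, ids_a)],
                      rep(NA_character_, nc)),
      solitary = c(solitary, rep(FALSE, nt + nc)),
      anchor_id = c(rep(NA_character_, na), hosts, rep(NA_character_, nc)))
    tether_graph <- data.frame(tether = ids_t, anchor = hosts)
    annotation <- data.frame(motif_id = paste0("M_", ids_a), factor_id = ids_a)
    list(factors = factors, pwms = pwms, tether_graph = tether_graph,
         annotation = annotation, consensus = stats::setNames(words, ids_a),
         p_max = p_max)
  })
}

# --- stages 4-10: full regulome ----------------------------------------------

mutate_word <- function(word, n_sub) {
  pos <- sample.int(length(word), n_sub)
  for (p in pos) word[p] <- sample(setdiff(1:4, word[p]), 1)
  word
}

revcomp_word <- function(word) rev(5L - word)

#' Generate the full synthetic regulome
#'
#' Runs every generator stage and returns the in-memory bundle: genome, peak
#' collections, segmentation, motif library, derived per-factor motifs,
#' expression and count tables, constrained elements, and the planted truth.
#'
#' @param config a `synth_config`.
#' @return a `synthetic_regulome` list (see fields in the implementation).
#' @export
generate_regulome <- function(config) {
  layout <- layout_elements(config)
  genome <- generate_genome(config, layout)
  models <- generate_factor_models(config)
  el <- layout$elements
  fac <- models$factors
  n_fac <- nrow(fac)
  anchors <- fac$factor_id[fac$role == "anchor"]
  reg_anchor <- fac$factor_id[fac$role == "anchor" & !fac$solitary &
                                fac$state_class != "both"]
  both_anchor <- fac$factor_id[fac$role == "anchor" & fac$state_class == "both"]
  sol <- fac$factor_id[fac$role == "anchor" & fac$solitary]
  chromf <- fac$factor_id[fac$role == "chromatin"]
  tethers <- models$tether_graph$tether
  anchor_of <- stats::setNames(models$tether_graph$anchor, tethers)
  tether_of <- stats::setNames(tethers, models$tether_graph$anchor)
  half <- config$peak_width_bp / 2
  L <- config$anchor_motif_length
  halfL <- floor(L / 2)

  # stage 4: element membership
  memb <- with_seed(stage_seed(config$seed, 4), {
    n_el <- nrow(el)
    reg_idx <- which(!el$is_hot)
    occ_n <- round(config$element_occupied_fraction * length(reg_idx))
    occupied <- sort(sample(reg_idx, occ_n))
    simple <- occupied[stats::runif(length(occupied)) < 0.25]
    lambda <- max(0.2, (config$mean_caps_per_element - 0.25 * 1.5) / 0.75 - 2)
    members <- vector("list", n_el)
    class_pool <- function(cl) {
      pref <- if (cl == "promoter") "promoter" else "enhancer"
      list(reg = fac$factor_id[fac$role == "anchor" & !fac$solitary &
                                 fac$state_class %in% c(pref, "both")],
           sol = fac$factor_id[fac$role == "anchor" & fac$solitary &
                                 fac$state_class == pref])
    }
    # weight balancing "both"-class anchors toward equal promoter/enhancer use
    n_p_occ <- sum(el$class[occupied] == "promoter")
    w_both_p <- if (n_p_occ > 0) (length(occupied) - n_p_occ) / n_p_occ else 1
    for (i in occupied) {
      pool <- class_pool(el$class[i])
      if (i %in% simple) {
        ne <- sample(1:2, 1)
        members[[i]] <- sample(pool$sol, min(ne, length(pool$sol)))
        next
      }
      ne <- min(2 + stats::rpois(1, lambda), config$max_caps_per_element)
      cand <- c(pool$reg, chromf)
      w <- c(ifelse(pool$reg %in% both_anchor,
                    if (el$class[i] == "promoter") w_both_p else 1, 1),
             rep(0.12 * ne, length(chromf)))
      sel <- character(0)
      guard <- 0
      while (length(sel) < ne && guard < 200) {
        guard <- guard + 1
        f <- sample(cand, 1, prob = w)
        if (f %in% sel) next
        sel <- c(sel, f)
        # the anchor's tether rides along while room remains
        tt <- tether_of[f]
        if (!is.na(tt) && !tt %in% sel && length(sel) < ne)
          sel <- c(sel, unname(tt))
      }
      members[[i]] <- sel
    }
    # HOT membership: strong + weak anchors (all planted), chromatin, tethers
    hot_idx <- which(el$is_hot)
    hot_truth <- list()
    hot_pool <- setdiff(anchors, sol)  # solitary factors stay element-only
    for (i in hot_idx) {
      ns <- sample(config$hot_strong_anchor_range[1]:config$hot_strong_anchor_range[2], 1)
      nw <- sample(config$hot_weak_factor_range[1]:config$hot_weak_factor_range[2], 1)
      nw <- min(nw, length(hot_pool) - ns)
      strong <- sample(hot_pool, ns)
      weak <- sample(setdiff(hot_pool, strong), nw)
      cr <- chromf[stats::runif(length(chromf)) < 0.8]
      member_anchors <- c(strong, weak)
      tt <- tether_of[member_anchors]
      tt <- unname(tt[!is.na(tt)])
      tt <- tt[stats::runif(length(tt)) < 0.75]
      members[[i]] <- c(strong, weak, cr, tt)
      hot_truth[[el$element_id[i]]] <- list(strong = strong, weak = weak)
    }
    list(members = members, hot_truth = hot_truth, occupied = occupied)
  })

  # stage 5: summit placement and motif planting (mutates genome codes)
  placement <- with_seed(stage_seed(config$seed, 5), {
    acc <- vector("list", nrow(el))
    slot_gap <- 12   # > motif length, so plants never overwrite one another
    for (i in seq_len(nrow(el))) {
      mem <- memb$members[[i]]
      if (is.null(mem) || !length(mem)) next
      ch <- el$chrom[i]; w <- el$end[i] - el$start[i]
      slots <- el$start[i] + seq(150, w - 150, by = slot_gap)
      mem_anchor <- mem[mem %in% anchors]
      mem_other <- setdiff(mem, mem_anchor)
      if (length(mem_anchor) > length(slots))
        stop("element too narrow for ", length(mem_anchor), " motif plants")
      a_pos <- stats::setNames(sample(slots, length(mem_anchor)), mem_anchor)
      is_hot <- el$is_hot[i]
      strong_set <- if (is_hot) memb$hot_truth[[el$element_id[i]]]$strong else mem_anchor
      for (f in mem_anchor) {
        s <- a_pos[[f]]
        word <- models$consensus[[f]]
        if (is_hot && !f %in% strong_set) {
          word <- mutate_word(word, sample(2:3, 1))       # degenerate plant
        } else if (stats::runif(1) < 0.3) {
          word <- mutate_word(word, 1)                    # strong plant, 1 sub
        }
        if (stats::runif(1) < 0.5) word <- revcomp_word(word)
        genome$code[[ch]][(s - halfL + 1):(s - halfL + L)] <- word
      }
      s_other <- vapply(mem_other, function(f) {
        if (f %in% tethers && anchor_of[[f]] %in% mem_anchor) {
          base <- a_pos[[anchor_of[[f]]]]
          off <- max(1, round(stats::rnorm(1, config$tether_offset_mean_bp,
                                           config$tether_offset_sd_bp))) *
            sample(c(-1, 1), 1)
          min(max(base + off, el$start[i] + 120), el$end[i] - 120)
        } else el$start[i] + sample(120:(w - 120), 1)
      }, numeric(1))
      plant <- c(ifelse(is_hot & !mem_anchor %in% strong_set,
                        "degenerate", "strong"),
                 rep("none", length(mem_other)))
      acc[[i]] <- data.frame(factor_id = c(mem_anchor, mem_other),
                             chrom = ch,
                             summit = c(unname(a_pos), unname(s_other)),
                             element_id = el$element_id[i],
                             plant = plant)
    }
    out <- do.call(rbind, acc)
    if (is.null(out))
      out <- data.frame(factor_id = character(0), chrom = character(0),
                        summit = numeric(0), element_id = character(0),
                        plant = character(0))
    rownames(out) <- NULL
    out
  })
  # cum arrays are rebuilt after planting mutated the codes
  genome <- new_genome_sequence(genome$code, genome$mask)

  # stage 8: tether solo peaks and background peaks in spare zones
  extra <- with_seed(stage_seed(config$seed, 8), {
    ev <- list()
    spare_pick <- function(n) {
      ch <- sample(layout$chroms, n, replace = TRUE)
      s <- vapply(ch, function(cc) {
        z <- layout$spare[[cc]]
        z[1] + sample.int(max(1, z[2] - z[1]), 1)
      }, numeric(1))
      data.frame(chrom = ch, summit = s)
    }
    for (f in fac$factor_id) {
      n_true <- sum(placement$factor_id == f)
      n_bg <- round(config$background_peak_rate * n_true)
      if (f %in% tethers) {
        rate <- config$tether_cooccurrence_rate
        n_bg <- n_bg + round(n_true * (1 - rate) / max(rate, 1e-6))
      }
      if (n_bg <= 0) next
      sp <- spare_pick(n_bg)
      ev[[f]] <- data.frame(factor_id = f, chrom = sp$chrom, summit = sp$summit,
                            element_id = NA_character_, plant = "none")
    }
    do.call(rbind, c(ev, list(placement[0, ])))
  })
  events <- rbind(placement, extra)
  rownames(events) <- NULL

  # peak collections
  collections <- lapply(fac$factor_id, function(f) {
    e <- events[events$factor_id == f, , drop = FALSE]
    if (!nrow(e)) return(peak_collection(f, data.frame(chrom = character(0),
                                                       start = numeric(0),
                                                       end = numeric(0))))
    peaks <- data.frame(chrom = e$chrom, start = e$summit - half,
                        end = e$summit + half,
                        name = paste0(f, "_", seq_len(nrow(e))),
                        score = 1000, strand = ".", signal = 10,
                        pvalue = -1, qvalue = -1, summit = half)
    peak_collection(f, peaks, genome = genome)
  })
  names(collections) <- fac$factor_id

  # segmentation: element states plus background "Q"
  seg_el <- el[el$state != "Q", c("chrom", "start", "end", "state")]
  segs <- list(seg_el)
  for (ch in layout$chroms) {
    e <- el[el$chrom == ch & el$state != "Q", , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    b <- c(0, as.vector(rbind(e$start, e$end)), config$chrom_length_bp)
    s <- b[seq(1, length(b), 2)]; en <- b[seq(2, length(b), 2)]
    keep <- en > s
    segs[[length(segs) + 1]] <- data.frame(chrom = ch, start = s[keep],
                                           end = en[keep], state = "Q")
  }
  class_map <- c(P1 = "promoter", P2 = "promoter", ES1 = "strong_enhancer",
                 ES2 = "strong_enhancer", EW1 = "weak_enhancer", Q = "other")
  segmentation <- state_segmentation(do.call(rbind, segs), class_map)

  # stage 6: expression
  n_caps_el <- vapply(memb$members, length, integer(1))
  gene_table <- with_seed(stage_seed(config$seed, 6), {
    gi <- which(el$class == "promoter")
    ml <- config$expression_lognormal_params[1]
    sl <- config$expression_lognormal_params[2]
    # each co-bound anchor+tether pair adds a fixed expression increment at
    # ordinary promoters; HOT promoters carry the (saturating) occupancy term
    cobound <- vapply(memb$members[gi], function(m) {
      tt <- intersect(m, tethers)
      sum(anchor_of[tt] %in% m)
    }, numeric(1))
    cobound[el$is_hot[gi]] <- 0
    tpm <- stats::rlnorm(length(gi),
                         ml + config$expression_occupancy_beta *
                           log1p(pmin(n_caps_el[gi], 12)) +
                           config$expression_cobind_boost * cobound,
                         sl)
    g <- data.frame(gene = paste0("g_", el$element_id[gi]), chrom = el$chrom[gi],
                    tss = floor((el$start[gi] + el$end[gi]) / 2),
                    strand = sample(c("+", "-"), length(gi), replace = TRUE),
                    tpm = tpm, element_id = el$element_id[gi])
    if (config$n_silent_genes > 0) {
      ch <- sample(layout$chroms, config$n_silent_genes, replace = TRUE)
      pos <- vapply(ch, function(cc) {
        z <- layout$spare[[cc]]
        z[1] + sample.int(max(1, z[2] - z[1]), 1)
      }, numeric(1))
      g <- rbind(g, data.frame(gene = sprintf("silent%04d", seq_len(config$n_silent_genes)),
                               chrom = ch, tss = pos,
                               strand = sample(c("+", "-"), length(ch), replace = TRUE),
                               tpm = stats::rlnorm(length(ch), -3, 1),
                               element_id = NA_character_))
    }
    g <- g[order(g$chrom, g$tss, method = "radix"), ]
    rownames(g) <- NULL
    g
  })

  # stage 7: count matrix over peak-center +/- 50 bp loci
  counts <- with_seed(stage_seed(config$seed, 7), {
    site_iv <- data.frame(chrom = events$chrom, start = events$summit - 50,
                          end = events$summit + 51)
    loci <- merge_intervals(site_iv, "none")
    occ <- matrix(FALSE, nrow(loci), n_fac,
                  dimnames = list(NULL, fac$factor_id))
    for (f in seq_len(n_fac)) {
      e <- events[events$factor_id == fac$factor_id[f], , drop = FALSE]
      if (!nrow(e)) next
      li <- locate_points(loci, e$chrom, e$summit)
      occ[unique(li[!is.na(li)]), f] <- TRUE
    }
    m <- matrix(stats::rnbinom(nrow(loci) * n_fac, mu = 5, size = 5),
                nrow(loci), n_fac, dimnames = list(NULL, fac$factor_id))
    hi <- stats::rnbinom(sum(occ), mu = 50, size = 5)
    m[occ] <- hi
    list(loci = loci, matrix = m)
  })

  # stage 9: per-factor derived motifs (what de novo discovery would return)
  derived <- with_seed(stage_seed(config$seed, 9), {
    jitter_pwm <- function(pwm, id) {
      m <- apply(pwm$matrix, 2, function(col)
        as.numeric(stats::rmultinom(1, 400, col)) / 400)
      m[m == 0] <- 1e-3
      pwm_motif(id, sweep(m, 2, colSums(m), "/"))
    }
    out <- list()
    for (i in seq_len(n_fac)) {
      f <- fac$factor_id[i]
      id <- paste0("D_", f)
      out[[f]] <- switch(fac$role[i],
        anchor = jitter_pwm(models$pwms[[f]], id),
        tethered = jitter_pwm(models$pwms[[anchor_of[[f]]]], id),
        chromatin = {
          m <- matrix(stats::rgamma(4 * 8, 0.7), 4, 8)
          pwm_motif(id, sweep(m, 2, colSums(m), "/"))
        })
    }
    out
  })

  # stage 10: constrained elements concentrated at high-occupancy loci
  constrained <- with_seed(stage_seed(config$seed, 10), {
    acc <- list()
    for (i in seq_len(nrow(el))) {
      n <- n_caps_el[i]
      if (n < 1) next
      if (stats::runif(1) > min(1, n / 50)) next
      w <- el$end[i] - el$start[i]
      cw <- round(min(0.06 * n, 0.9) * w)
      if (cw < 10) next
      s <- el$start[i] + sample.int(w - cw, 1)
      acc[[length(acc) + 1]] <- data.frame(chrom = el$chrom[i], start = s,
                                           end = s + cw)
    }
    out <- if (length(acc)) sort_intervals(do.call(rbind, acc))
           else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    rownames(out) <- NULL
    out
  })

  truth <- structure(list(
    seed = config$seed,
    factor_table = fac,
    elements = cbind(el, n_caps = n_caps_el,
                     members = vapply(memb$members, function(m)
                       paste(m, collapse = ","), character(1))),
    hot_truth = memb$hot_truth,
    events = events,
    tether_graph = models$tether_graph,
    gene_table = gene_table,
    consensus = lapply(models$consensus, as.integer),
    p_max = models$p_max), class = "synthetic_truth")

  structure(list(config = config, genome = genome, collections = collections,
                 segmentation = segmentation, motif_db = models$pwms,
                 annotation = models$annotation, derived_motifs = derived,
                 gene_table = gene_table, counts = counts,
                 constrained = constrained, truth = truth),
            class = "synthetic_regulome")
}

#' @export
print.synthetic_regulome <- function(x, ...) {
  cat("synthetic_regulome:", length(x$collections), "factors,",
      nrow(x$truth$elements), "elements (",
      sum(x$truth$elements$is_hot), "HOT ), seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic regulome to standard-format files
#'
#' Emits genome FASTA + chrom.sizes, per-factor narrowPeak files, the
#' segmentation BED, the motif library (MEME minimal) with its annotation
#' table, derived motifs, expression TSV, counts TSV, constrained-element BED
#' and the truth JSON. Byte-identical across runs with the same config.
#'
#' @param config a `synth_config`.
#' @param outdir output directory (created).
#' @param regulome optional pre-generated regulome (regenerated when NULL).
#' @return named list of paths, invisibly.
#' @export
synthesize_datasets <- function(config, outdir, regulome = NULL) {
  if (is.null(regulome)) regulome <- generate_regulome(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  paths <- list(
    fasta = file.path(outdir, "genome.fa"),
    chrom_sizes = file.path(outdir, "genome.chrom.sizes"),
    segmentation = file.path(outdir, "segmentation.bed"),
    motifs = file.path(outdir, "motifs.meme"),
    derived_motifs = file.path(outdir, "derived_motifs.meme"),
    annotation = file.path(outdir, "motif_annotation.tsv"),
    expression = file.path(outdir, "expression.tsv"),
    counts = file.path(outdir, "counts.tsv"),
    counts_loci = file.path(outdir, "counts_loci.bed"),
    constrained = file.path(outdir, "constrained.bed"),
    truth = file.path(outdir, "truth.json"))
  write_fasta(regulome$genome, paths$fasta)
  write_chrom_sizes(regulome$genome, paths$chrom_sizes)
  write_segmentation(regulome$segmentation, paths$segmentation)
  write_meme_motifs(regulome$motif_db, paths$motifs)
  write_meme_motifs(regulome$derived_motifs, paths$derived_motifs)
  utils::write.table(regulome$annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  g <- regulome$gene_table
  g$tpm <- sprintf("%.4f", g$tpm)
  utils::write.table(g[, c("gene", "chrom", "tss", "strand", "tpm")],
                     paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- regulome$counts$matrix
  utils::write.table(cbind(locus = paste0("L", seq_len(nrow(cm))), as.data.frame(cm)),
                     paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- regulome$counts$loci
  writeLines(paste(cl$chrom, fmt_num(cl$start), fmt_num(cl$end), sep = "\t"),
             paths$counts_loci)
  co <- regulome$constrained
  writeLines(paste(co$chrom, fmt_num(co$start), fmt_num(co$end), sep = "\t"),
             paths$constrained)
  for (f in names(regulome$collections))
    write_narrowpeak(regulome$collections[[f]],
                     file.path(outdir, "peaks", paste0(f, ".narrowPeak")))
  paths$peaks <- file.path(outdir, "peaks")
  write_truth(regulome$truth, paths$truth)
  invisible(paths)
}

#' Serialize the planted truth to JSON
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = FALSE)
  invisible(path)
}

#' Read a planted-truth JSON
#' @param path truth file written by [write_truth()].
#' @return a `synthetic_truth`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$factor_table <- as.data.frame(x$factor_table)
  x$elements <- as.data.frame(x$elements)
  x$events <- as.data.frame(x$events)
  x$tether_graph <- as.data.frame(x$tether_graph)
  x$gene_table <- as.data.frame(x$gene_table)
  x$hot_truth <- lapply(x$hot_truth, function(h)
    list(strong = as.character(h$strong), weak = as.character(h$weak)))
  x$consensus <- lapply(x$consensus, as.integer)
  structure(x, class = "synthetic_truth")
}
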