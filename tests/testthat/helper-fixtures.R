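# Build a small trio dataset from genotype strings.
make_trio <- function(pos, pro, mot, fat, af = 0.001, chrom = "chr15",
                      ref = "A", alt = "G") {
  n <- length(pos)
  p <- parse_gt(rep_len(pro, n))
  m <- parse_gt(rep_len(mot, n))
  f <- parse_gt(rep_len(fat, n))
  trio_dataset(tibble::tibble(
    chrom = chrom, pos = as.double(pos),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    pro_a1 = p[, 1], pro_a2 = p[, 2],
    mot_a1 = m[, 1], mot_a2 = m[, 2],
    fat_a1 = f[, 1], fat_a2 = f[, 2],
    pop_af = rep_len(af, n)
  ))
}

# Calls tibble shaped like classify_trio() output, for clustering tests.
make_calls <- function(pos, parent = "maternal", chrom = "chr15",
                       supportive = TRUE) {
  tibble::tibble(chrom = chrom, pos = as.double(pos),
                 supportive = rep_len(supportive, length(pos)),
                 parent = rep_len(parent, length(pos)))
}

# Independent single-pass clustering oracle: split positions at gaps larger
# than max_gap, report span and count per chunk.
oracle_cluster <- function(pos, max_gap) {
  pos <- sort(pos)
  grp <- cumsum(c(1, diff(pos) > max_gap))
  lapply(split(pos, grp), function(p) {
    list(start = min(p), end = max(p), n = length(p))
  })
}

# Per-site probability, for true biallelic genotypes (alt-allele counts in
# 0..2) under the uniform genotype miscall model with rate e, that the
# observed trio shows a supportive pattern. Enumerates the 27 observed
# combinations once; used as the analytic oracle for error-driven
# supportive counts. Vectorised over sites.
supportive_prob_under_error <- function(g_pro, g_mot, g_fat, e) {
  combos <- expand.grid(op = 0:2, om = 0:2, of = 0:2)
  a1 <- function(g) as.integer(g > 1)
  a2 <- function(g) as.integer(g > 0)
  cls <- updtrio:::classify_genotypes(a1(combos$op), a2(combos$op),
                                      a1(combos$om), a2(combos$om),
                                      a1(combos$of), a2(combos$of))
  sup <- cls %in% c("MAT_ISO_SUPPORT", "PAT_ISO_SUPPORT",
                    "MAT_HET_SUPPORT", "PAT_HET_SUPPORT")
  obs_prob <- function(g_true, g_obs) ifelse(g_true == g_obs, 1 - e, e / 2)
  p <- numeric(length(g_pro))
  for (k in which(sup)) {
    p <- p + obs_prob(g_pro, combos$op[k]) *
      obs_prob(g_mot, combos$om[k]) *
      obs_prob(g_fat, combos$of[k])
  }
  p
}

# Study conditions used by the simulation-based tests: maternal meiosis-II
# nondisjunction with trisomy rescue, one crossover on the central half of a
# chr15-like map, 5000 markers, no genotyping error. Clustering gap chosen
# from the supportive-site spacing analysis in the methods vignette.
study_config <- function(seed, crossover_frac = NULL, error = 0,
                         planted_pos = NULL) {
  L <- 102531392
  cx <- if (!is.null(crossover_frac)) crossover_frac * L else NULL
  planted <- if (!is.null(planted_pos)) list(pos = planted_pos) else NULL
  sim_config(
    n_markers = 5000, ndj_stage = "meiosis_II", ndj_parent = "maternal",
    crossover_positions = cx, n_crossovers = 1,
    genotyping_error_rate = error, planted_variant = planted, seed = seed
  )
}

study_cluster_params <- function() cluster_params(max_gap_bp = 8e6)

# Draw the study's random crossover on the central half of the chromosome.
draw_central_crossover <- function() runif(1, 0.25, 0.75)
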