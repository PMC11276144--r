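#' Configuration for the meiotic-nondisjunction trio simulator
#'
#' The simulator emulates a jointly genotyped trio over an acrocentric,
#' chromosome-15-like marker map. Parental haplotypes are drawn per marker
#' from the allele-frequency law; a gamete is formed with meiosis-I
#' recombination, and when `ndj_stage` is not `"none"` a nondisjunction plus
#' trisomy rescue gives the proband both chromatids of the `ndj_parent`
#' gamete (the other parent's contribution is lost). The centromere sits at
#' coordinate 1, so "centromeric" means low coordinates; a meiosis-II event
#' with one crossover yields centromeric isodisomy and telomeric
#' heterodisomy, a meiosis-I event the reverse.
#'
#' @param chrom Chromosome label. Default `"chr15"`.
#' @param chrom_length_bp Chromosome length. Default 102531392 (chr15-like).
#' @param n_markers Number of biallelic markers. Default 5000.
#' @param marker_placement `"random"` (uniform without replacement, default)
#'   or `"grid"` (even spacing).
#' @param af_range Alternate-allele frequency law: uniform on this interval.
#'   Default `c(0.01, 0.5)`; the lower bound keeps sites polymorphic enough
#'   that informative configurations occur at a testable rate.
#' @param ndj_stage `"none"`, `"meiosis_I"` or `"meiosis_II"`.
#' @param ndj_parent `"maternal"` or `"paternal"`.
#' @param n_crossovers Number of crossovers in the NDJ meiosis (fixed count,
#'   or Poisson mean when `crossover_law = "poisson"`). Default 1.
#' @param crossover_law `"fixed"` or `"poisson"`.
#' @param crossover_positions Optional explicit crossover positions in bp
#'   (overrides `n_crossovers`); must lie inside the chromosome.
#' @param genotyping_error_rate Per-genotype miscall probability (the miscall
#'   is uniform over the other two biallelic genotypes). Default 0.
#' @param planted_variant Optional list with `pos` (bp), and optionally
#'   `af` (default 2.3e-4) and `carrier` (default `ndj_parent`): a
#'   deleterious allele carried heterozygously by that parent on the
#'   transmitted chromatid, absent from the other parent.
#' @param seed Integer seed; identical configs give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom = "chr15", chrom_length_bp = 102531392,
                       n_markers = 5000,
                       marker_placement = c("random", "grid"),
                       af_range = c(0.01, 0.5),
                       ndj_stage = c("meiosis_II", "meiosis_I", "none"),
                       ndj_parent = c("maternal", "paternal"),
                       n_crossovers = 1,
                       crossover_law = c("fixed", "poisson"),
                       crossover_positions = NULL,
                       genotyping_error_rate = 0,
                       planted_variant = NULL,
                       seed = 1L) {
  marker_placement <- match.arg(marker_placement)
  ndj_stage <- match.arg(ndj_stage)
  ndj_parent <- match.arg(ndj_parent)
  crossover_law <- match.arg(crossover_law)
  stopifnot(
    chrom_length_bp >= n_markers, n_markers >= 1,
    af_range[1] > 0, af_range[2] <= 0.5, af_range[1] <= af_range[2],
    n_crossovers >= 0,
    genotyping_error_rate >= 0, genotyping_error_rate < 1
  )
  if (!is.null(crossover_positions)) {
    if (any(crossover_positions <= 1 | crossover_positions >= chrom_length_bp)) {
      abort("crossover positions must lie strictly inside the chromosome")
    }
    crossover_positions <- sort(crossover_positions)
  }
  if (!is.null(planted_variant)) {
    if (is.null(planted_variant$pos) ||
        planted_variant$pos < 1 || planted_variant$pos > chrom_length_bp) {
      abort("planted variant position must lie inside the chromosome")
    }
    planted_variant$af <- planted_variant$af %||% 2.3e-4
    planted_variant$carrier <- planted_variant$carrier %||% ndj_parent
  }
  structure(list(
    chrom = chrom, chrom_length_bp = chrom_length_bp, n_markers = n_markers,
    marker_placement = marker_placement, af_range = af_range,
    ndj_stage = ndj_stage, ndj_parent = ndj_parent,
    n_crossovers = n_crossovers, crossover_law = crossover_law,
    crossover_positions = crossover_positions,
    genotyping_error_rate = genotyping_error_rate,
    planted_variant = planted_variant, seed = as.integer(seed)
  ), class = "sim_config")
}

# Source-haplotype index (1 or 2) of the recombinant chromatid at each
# position: starts on haplotype 1 and flips at every crossover.
recombinant_source <- function(pos, crossovers) {
  1L + (vapply(pos, function(p) sum(crossovers < p), integer(1)) %% 2L)
}

#' Simulate the disomic gamete of a nondisjunction meiosis
#'
#' Models one meiosis with crossovers between one chromatid of each homolog,
#' then a nondisjunction: meiosis II retains the two sister chromatids of
#' one homolog (identical — hence isodisomic — on the centromeric side of
#' each crossover), meiosis I retains one chromatid of each homolog
#' (heterodisomic centromere-side, isodisomic distal to an odd number of
#' crossovers). Ground-truth segments follow exactly from the chromatid
#' identity by descent.
#'
#' @param hap1,hap2 Integer allele vectors of the parent's two homologs over
#'   the marker positions.
#' @param pos Marker positions.
#' @param crossovers Crossover positions in bp (sorted).
#' @param stage `"meiosis_I"` or `"meiosis_II"`.
#' @param chrom,chrom_length_bp Chromosome label and length for the truth
#'   segments.
#' @return A list with `allele1`, `allele2` (the two transmitted allele
#'   vectors), `source1`, `source2` (their haplotype of origin per marker)
#'   and `truth` (tibble of `chrom`, `start`, `end`, `disomy_type`).
#' @export
simulate_gamete_with_ndj <- function(hap1, hap2, pos, crossovers,
                                     stage = c("meiosis_II", "meiosis_I"),
                                     chrom = "chr15",
                                     chrom_length_bp = max(pos)) {
  stage <- match.arg(stage)
  if (length(crossovers) > 0 &&
      any(crossovers <= 1 | crossovers >= chrom_length_bp)) {
    abort("crossover positions must lie strictly inside the chromosome")
  }
  s_b <- recombinant_source(pos, crossovers)
  # meiosis II keeps both sisters of homolog 1: the intact chromatid plus
  # the recombinant; meiosis I keeps the recombinant plus an intact
  # homolog-2 chromatid.
  s1 <- if (stage == "meiosis_II") rep(1L, length(pos)) else rep(2L, length(pos))
  s2 <- s_b
  haps <- cbind(hap1, hap2)
  allele1 <- haps[cbind(seq_along(pos), s1)]
  allele2 <- haps[cbind(seq_along(pos), s2)]

  starts <- c(1, floor(sort(crossovers)) + 1)
  ends <- c(floor(sort(crossovers)), chrom_length_bp)
  k <- seq_along(starts)
  # segment i sits distal to i-1 crossovers
  same_source <- if (stage == "meiosis_II") (k - 1) %% 2 == 0 else (k - 1) %% 2 == 1
  truth <- tibble(
    chrom = chrom, start = starts, end = ends,
    disomy_type = ifelse(same_source, "isodisomy", "heterodisomy")
  )
  list(allele1 = allele1, allele2 = allele2, source1 = s1, source2 = s2,
       truth = truth)
}

# Apply uniform genotype-level miscalls to biallelic allele-pair columns.
apply_genotyping_error <- function(a1, a2, rate) {
  if (rate <= 0) return(list(a1 = a1, a2 = a2))
  n <- length(a1)
  flip <- runif(n) < rate
  if (any(flip)) {
    g <- a1 + a2  # 0, 1 or 2 alt copies
    new_g <- vapply(g[flip], function(x) sample(setdiff(0:2, x), 1), numeric(1))
    a1[flip] <- as.integer(new_g > 1)
    a2[flip] <- as.integer(new_g > 0)
  }
  list(a1 = a1, a2 = a2)
}

#' Simulate a genotyped trio with optional segmental UPD
#'
#' Draws parental haplotypes, forms the proband per the configured meiotic
#' mechanism, optionally plants a carrier-parent heterozygous deleterious
#' allele on the transmitted chromatid, applies genotyping error, and
#' returns the dataset together with its ground truth. Deterministic under a
#' fixed seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `trio_sim`: a list with `data` (a
#'   [trio_dataset()]), `truth` (tibble of ground-truth segments: `chrom`,
#'   `start`, `end`, `parent`, `disomy_type`; empty when `ndj_stage` is
#'   `"none"`), `crossovers`, `planted` (position and `"chrom:pos:ref:alt"`
#'   key of the planted variant, or `NULL`) and `config`.
#' @export
simulate_trio <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_trio_impl(config))
}

simulate_trio_impl <- function(config) {
  L <- config$chrom_length_bp
  n <- config$n_markers
  pos <- if (config$marker_placement == "grid") {
    round(seq(1, L, length.out = n))
  } else {
    sort(sample.int(L, n))
  }
  af <- runif(n, config$af_range[1], config$af_range[2])

  m1 <- rbinom(n, 1, af); m2 <- rbinom(n, 1, af)
  f1 <- rbinom(n, 1, af); f2 <- rbinom(n, 1, af)

  draw_crossovers <- function() {
    if (!is.null(config$crossover_positions)) return(config$crossover_positions)
    k <- if (config$crossover_law == "poisson") {
      rpois(1, config$n_crossovers)
    } else {
      config$n_crossovers
    }
    if (k == 0) numeric(0) else sort(runif(k, 2, L - 1))
  }

  planted <- config$planted_variant
  crossovers <- draw_crossovers()

  if (config$ndj_stage == "none") {
    cx_m <- crossovers
    cx_f <- draw_crossovers()
    sm <- recombinant_source(pos, cx_m)
    sf <- recombinant_source(pos, cx_f)
    pro1 <- cbind(m1, m2)[cbind(seq_len(n), sm)]
    pro2 <- cbind(f1, f2)[cbind(seq_len(n), sf)]
    truth <- tibble(chrom = character(), start = double(), end = double(),
                    parent = character(), disomy_type = character())
    src_at <- function(p, parent) {
      if (parent == "maternal") recombinant_source(p, cx_m)
      else recombinant_source(p, cx_f)
    }
  } else {
    if (config$ndj_parent == "maternal") {
      g <- simulate_gamete_with_ndj(m1, m2, pos, crossovers,
                                    stage = config$ndj_stage,
                                    chrom = config$chrom, chrom_length_bp = L)
    } else {
      g <- simulate_gamete_with_ndj(f1, f2, pos, crossovers,
                                    stage = config$ndj_stage,
                                    chrom = config$chrom, chrom_length_bp = L)
    }
    pro1 <- g$allele1
    pro2 <- g$allele2
    truth <- dplyr::mutate(g$truth, parent = config$ndj_parent) |>
      dplyr::select("chrom", "start", "end", "parent", "disomy_type")
    src_at <- function(p, parent) {
      if (parent != config$ndj_parent) return(NULL)  # carrier lost by rescue
      c(if (config$ndj_stage == "meiosis_II") 1L else 2L,
        recombinant_source(p, crossovers))
    }
  }

  sites <- tibble(
    chrom = config$chrom, pos = as.double(pos),
    ref = "A", alt = "G",
    pro_a1 = as.integer(pro1), pro_a2 = as.integer(pro2),
    mot_a1 = as.integer(m1), mot_a2 = as.integer(m2),
    fat_a1 = as.integer(f1), fat_a2 = as.integer(f2),
    pop_af = af
  )

  planted_out <- NULL
  if (!is.null(planted)) {
    p <- planted$pos
    if (p %in% pos) abort("planted variant collides with an existing marker")
    src <- src_at(p, planted$carrier)
    # the planted allele rides the transmitted chromatid: set it on that
    # chromatid's source haplotype, leave the other haplotype reference
    carrier_gt <- c(0L, 0L)
    if (is.null(src)) {
      # carrier parent's whole contribution was lost in the trisomy rescue
      carrier_gt[1] <- 1L
      pro_gt <- c(0L, 0L)
    } else {
      carrier_gt[src[1]] <- 1L
      if (config$ndj_stage == "none") {
        pro_gt <- c(1L, 0L)  # one carrier allele + other parent's reference
      } else {
        pro_gt <- c(carrier_gt[src[1]], carrier_gt[src[2]])
      }
    }
    is_mat <- planted$carrier == "maternal"
    row <- tibble(
      chrom = config$chrom, pos = as.double(p), ref = "C", alt = "T",
      pro_a1 = pro_gt[1], pro_a2 = pro_gt[2],
      mot_a1 = if (is_mat) carrier_gt[1] else 0L,
      mot_a2 = if (is_mat) carrier_gt[2] else 0L,
      fat_a1 = if (is_mat) 0L else carrier_gt[1],
      fat_a2 = if (is_mat) 0L else carrier_gt[2],
      pop_af = planted$af
    )
    sites <- dplyr::bind_rows(sites, row) |> dplyr::arrange(.data$pos)
    planted_out <- list(pos = p,
                        key = paste(config$chrom, p, "C", "T", sep = ":"))
  }

  e <- config$genotyping_error_rate
  if (e > 0) {
    pro <- apply_genotyping_error(sites$pro_a1, sites$pro_a2, e)
    mot <- apply_genotyping_error(sites$mot_a1, sites$mot_a2, e)
    fat <- apply_genotyping_error(sites$fat_a1, sites$fat_a2, e)
    sites$pro_a1 <- pro$a1; sites$pro_a2 <- pro$a2
    sites$mot_a1 <- mot$a1; sites$mot_a2 <- mot$a2
    sites$fat_a1 <- fat$a1; sites$fat_a2 <- fat$a2
  }

  structure(list(
    data = trio_dataset(sites),
    truth = truth,
    crossovers = crossovers,
    planted = planted_out,
    config = config
  ), class = "trio_sim")
}

#' Compare called UPD segments and breakpoints with simulator truth
#'
#' @param landscape An `upd_landscape` result (or a list with `segments` and
#'   `breakpoints` tibbles).
#' @param truth Ground-truth segment tibble from [simulate_trio()].
#' @return A one-row tibble: `n_segments`, `n_true_segments`,
#'   `type_accuracy` and `parent_accuracy` (length-weighted over the
#'   called/truth overlap; `NA` when there is no overlap),
#'   `segment_type_accuracy` and `segment_parent_accuracy` (fraction of
#'   called segments whose majority-overlap truth segment matches — boundary
#'   placement inside the uninformative marker gap does not count against
#'   these), `false_positive_segments` (called segments with no truth
#'   overlap), `breakpoint_error_bp` (largest distance from a called
#'   breakpoint to the nearest truth boundary; `NA` without breakpoints or
#'   interior truth boundaries).
#' @export
evaluate_recovery <- function(landscape, truth) {
  segs <- landscape$segments
  bps <- landscape$breakpoints

  overlap_len <- function(a_start, a_end, b_start, b_end) {
    pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
  }

  tot <- 0; type_ok <- 0; parent_ok <- 0; fp <- 0L
  seg_type_ok <- 0L; seg_parent_ok <- 0L; n_matched <- 0L
  if (nrow(segs) > 0) {
    for (i in seq_len(nrow(segs))) {
      tr <- truth[truth$chrom == segs$chrom[i], ]
      if (nrow(tr) == 0) { fp <- fp + 1L; next }
      ov <- overlap_len(segs$start[i], segs$end[i], tr$start, tr$end)
      if (sum(ov) == 0) { fp <- fp + 1L; next }
      tot <- tot + sum(ov)
      type_ok <- type_ok + sum(ov[tr$disomy_type == segs$disomy_type[i]])
      parent_ok <- parent_ok + sum(ov[tr$parent == segs$parent[i]])
      best <- which.max(ov)
      n_matched <- n_matched + 1L
      seg_type_ok <- seg_type_ok +
        (tr$disomy_type[best] == segs$disomy_type[i])
      seg_parent_ok <- seg_parent_ok + (tr$parent[best] == segs$parent[i])
    }
  }

  interior <- truth |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(.data$end < max(.data$end)) |>
    dplyr::pull(.data$end)
  bp_err <- NA_real_
  if (nrow(bps) > 0 && length(interior) > 0) {
    bp_err <- max(vapply(bps$breakpoint,
                         function(b) min(abs(b - interior)), numeric(1)))
  }

  tibble(
    n_segments = nrow(segs),
    n_true_segments = nrow(truth),
    type_accuracy = if (tot > 0) type_ok / tot else NA_real_,
    parent_accuracy = if (tot > 0) parent_ok / tot else NA_real_,
    segment_type_accuracy = if (n_matched > 0) seg_type_ok / n_matched else NA_real_,
    segment_parent_accuracy = if (n_matched > 0) seg_parent_ok / n_matched else NA_real_,
    false_positive_segments = fp,
    breakpoint_error_bp = bp_err
  )
}
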