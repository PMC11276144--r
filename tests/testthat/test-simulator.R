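test_that("gamete truth segments follow the meiotic mechanism", {
  pos <- seq(1e6, 1e8, by = 1e6)
  hap1 <- rep(1L, length(pos))
  hap2 <- rep(0L, length(pos))

  # meiosis II, no crossover: both transmitted chromatids are the same
  # homolog -> one isodisomy segment over the whole chromosome
  g <- simulate_gamete_with_ndj(hap1, hap2, pos, numeric(0),
                                stage = "meiosis_II",
                                chrom_length_bp = 1.02e8)
  expect_equal(g$truth$disomy_type, "isodisomy")
  expect_equal(g$truth$start, 1)
  expect_equal(g$truth$end, 1.02e8)
  expect_equal(g$allele1, g$allele2)

  # meiosis I, no crossover: one chromatid of each homolog -> heterodisomy
  g1 <- simulate_gamete_with_ndj(hap1, hap2, pos, numeric(0),
                                 stage = "meiosis_I",
                                 chrom_length_bp = 1.02e8)
  expect_equal(g1$truth$disomy_type, "heterodisomy")
  expect_equal(g1$allele1, hap2)
  expect_equal(g1$allele2, hap1)

  # meiosis II with one crossover at 0.6 L: isodisomy on the centromeric
  # side, heterodisomy distal
  cx <- 0.6 * 1.02e8
  g2 <- simulate_gamete_with_ndj(hap1, hap2, pos, cx, stage = "meiosis_II",
                                 chrom_length_bp = 1.02e8)
  expect_equal(g2$truth$disomy_type, c("isodisomy", "heterodisomy"))
  expect_equal(g2$truth$start, c(1, floor(cx) + 1))
  expect_equal(g2$truth$end, c(floor(cx), 1.02e8))
  expect_equal(g2$allele1, hap1)
  expect_equal(g2$allele2, ifelse(pos <= cx, hap1, hap2))

  # crossovers outside the chromosome are rejected
  expect_error(simulate_gamete_with_ndj(hap1, hap2, pos, 2e8,
                                        chrom_length_bp = 1.02e8),
               "inside")
})

test_that("truth segments always tile the chromosome", {
  set.seed(61)
  for (i in 1:20) {
    k <- sample(0:4, 1)
    cx <- sort(runif(k, 2, 1e8 - 1))
    g <- simulate_gamete_with_ndj(rep(0L, 10), rep(1L, 10),
                                  seq(1e6, 1e7, by = 1e6), cx,
                                  stage = sample(c("meiosis_I",
                                                   "meiosis_II"), 1),
                                  chrom_length_bp = 1e8)
    tr <- g$truth
    expect_equal(tr$start[1], 1)
    expect_equal(tr$end[nrow(tr)], 1e8)
    if (nrow(tr) > 1) {
      expect_equal(tr$start[-1], tr$end[-nrow(tr)] + 1)
      # adjacent segments alternate type
      expect_true(all(tr$disomy_type[-1] != tr$disomy_type[-nrow(tr)]))
    }
  }
})

test_that("simulation is fully deterministic under a seed", {
  cfg <- study_config(seed = 71, crossover_frac = 0.55)
  s1 <- simulate_trio(cfg)
  s2 <- simulate_trio(cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$crossovers, s2$crossovers)

  # and the serialised VCF is byte-identical in content
  p1 <- file.path(tempdir(), "det1.vcf.gz")
  p2 <- file.path(tempdir(), "det2.vcf.gz")
  write_trio_vcf(s1$data, p1)
  write_trio_vcf(s2$data, p2)
  expect_identical(readLines(gzfile(p1)), readLines(gzfile(p2)))

  # a different seed changes the data
  s3 <- simulate_trio(study_config(seed = 72, crossover_frac = 0.55))
  expect_false(identical(s1$data, s3$data))
})

test_that("error-free genotypes obey the truth segment constraints", {
  sim <- simulate_trio(study_config(seed = 73, crossover_frac = 0.35))
  d <- sim$data
  tr <- sim$truth
  expect_equal(tr$parent, rep("maternal", nrow(tr)))

  seg_of <- function(p) tr$disomy_type[tr$start <= p & tr$end >= p]
  types <- vapply(d$pos, seg_of, character(1))

  # isodisomy: two copies of one maternal chromatid -> proband homozygous
  iso <- types == "isodisomy"
  expect_true(all(d$pro_a1[iso] == d$pro_a2[iso]))
  # and the proband allele is carried by the mother
  expect_true(all(d$pro_a1[iso] == d$mot_a1[iso] |
                    d$pro_a1[iso] == d$mot_a2[iso]))

  # heterodisomy: the proband's unordered genotype equals the mother's
  het <- !iso
  expect_true(all(pmin(d$pro_a1, d$pro_a2)[het] ==
                    pmin(d$mot_a1, d$mot_a2)[het]))
  expect_true(all(pmax(d$pro_a1, d$pro_a2)[het] ==
                    pmax(d$mot_a1, d$mot_a2)[het]))

  # no paternal contribution anywhere -> no paternal supportive calls
  calls <- classify_trio(d, af_threshold = 1)
  expect_equal(sum(startsWith(as.character(calls$category), "PAT_")), 0)
})

test_that("a biparental simulation has empty truth and Mendelian consistency", {
  sim <- simulate_trio(sim_config(ndj_stage = "none", n_markers = 1000,
                                  seed = 74))
  expect_equal(nrow(sim$truth), 0)
  calls <- classify_trio(sim$data, af_threshold = 1)
  expect_equal(sum(calls$category == "MENDELIAN_ERROR_OTHER"), 0)
  expect_equal(sum(calls$supportive), 0)
})

test_that("genotyping error perturbs approximately the configured fraction", {
  cfg0 <- sim_config(n_markers = 5000, ndj_stage = "none", seed = 75)
  cfgE <- sim_config(n_markers = 5000, ndj_stage = "none", seed = 75,
                     genotyping_error_rate = 0.01)
  clean <- simulate_trio(cfg0)$data
  noisy <- simulate_trio(cfgE)$data
  expect_equal(clean$pos, noisy$pos)
  diff_frac <- function(a1c, a2c, a1n, a2n) {
    mean((a1c + a2c) != (a1n + a2n))
  }
  fracs <- c(
    diff_frac(clean$pro_a1, clean$pro_a2, noisy$pro_a1, noisy$pro_a2),
    diff_frac(clean$mot_a1, clean$mot_a2, noisy$mot_a1, noisy$mot_a2),
    diff_frac(clean$fat_a1, clean$fat_a2, noisy$fat_a1, noisy$fat_a2)
  )
  # each is Binomial(5000, 0.01)/5000: mean 0.01, sd 0.0014
  expect_true(all(fracs > 0.01 - 5 * 0.0014))
  expect_true(all(fracs < 0.01 + 5 * 0.0014))
})

test_that("evaluate_recovery scores perfect and empty calls correctly", {
  sim <- simulate_trio(study_config(seed = 76, crossover_frac = 0.5))

  # a landscape whose segments equal the truth scores 1 everywhere
  perfect <- structure(
    list(segments = dplyr::mutate(sim$truth, n_support = 100L,
                                  roh_coverage = NA_real_,
                                  size_mbp = segment_size(start, end)),
         breakpoints = tibble::tibble(breakpoint = sim$truth$end[1]),
         calls = tibble::tibble(), roh = tibble::tibble()),
    class = "upd_landscape")
  m <- evaluate_recovery(perfect, sim$truth)
  expect_equal(m$type_accuracy, 1)
  expect_equal(m$parent_accuracy, 1)
  expect_equal(m$segment_type_accuracy, 1)
  expect_equal(m$segment_parent_accuracy, 1)
  expect_equal(m$false_positive_segments, 0L)
  expect_equal(m$breakpoint_error_bp, 0)

  # an empty call set: accuracies undefined (NA), no false positives
  none <- structure(
    list(segments = sim$truth[0, ], breakpoints = tibble::tibble(),
         calls = tibble::tibble(), roh = tibble::tibble()),
    class = "upd_landscape")
  m0 <- evaluate_recovery(none, sim$truth)
  expect_equal(m0$n_segments, 0L)
  expect_true(is.na(m0$type_accuracy))
  expect_true(is.na(m0$breakpoint_error_bp))
  expect_equal(m0$false_positive_segments, 0L)
})
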