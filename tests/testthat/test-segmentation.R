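test_that("clustering applies the span, support and gap thresholds", {
  p <- cluster_params()

  # 20 variants evenly spaced over 4.5 Mbp: one candidate
  calls <- make_calls(round(seq(1e6, 5.5e6, length.out = 20)))
  cl <- cluster_supportive(calls, p)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_support, 20L)
  expect_equal(cl$start, 1e6)
  expect_equal(cl$end, 5.5e6)

  # 19 variants over 5 Mbp: below the support minimum
  expect_equal(nrow(cluster_supportive(
    make_calls(round(seq(1e6, 6e6, length.out = 19))), p)), 0)

  # 25 variants over 3.9 Mbp: below the span minimum
  expect_equal(nrow(cluster_supportive(
    make_calls(round(seq(1e6, 4.9e6 - 1, length.out = 25))), p)), 0)

  # AF-filtered or non-supportive calls never enter clusters
  none <- make_calls(round(seq(1e6, 5.5e6, length.out = 20)),
                     supportive = FALSE)
  expect_equal(nrow(cluster_supportive(none, p)), 0)
})

test_that("a gap larger than max_gap splits a cluster, matching the oracle", {
  # 40 variants with a single 3 Mbp internal gap, max_gap 2 Mbp
  left <- round(seq(1e6, 6e6, length.out = 20))
  right <- round(seq(9e6, 14e6, length.out = 20))
  pos <- c(left, right)
  p <- cluster_params()
  cl <- cluster_supportive(make_calls(pos), p)

  oracle <- oracle_cluster(pos, p$max_gap_bp)
  expect_equal(length(oracle), 2)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start, unname(vapply(oracle, `[[`, numeric(1), "start")))
  expect_equal(cl$end, unname(vapply(oracle, `[[`, numeric(1), "end")))
  expect_equal(cl$n_support,
               unname(vapply(oracle, function(x) as.integer(x$n),
                             integer(1))))
})

test_that("parent attribution follows the strict only-contributor rule", {
  pos <- round(seq(1e6, 6e6, length.out = 32))
  mat <- cluster_supportive(make_calls(pos, parent = "maternal"),
                            cluster_params())
  expect_equal(assign_parent(mat)$parent, "maternal")

  pat <- cluster_supportive(make_calls(pos, parent = "paternal"),
                            cluster_params())
  expect_equal(assign_parent(pat)$parent, "paternal")

  mixed <- cluster_supportive(
    make_calls(pos, parent = c(rep("maternal", 30), rep("paternal", 2))),
    cluster_params())
  expect_warning(res <- assign_parent(mixed), "ambiguous")
  expect_equal(res$parent, "ambiguous")

  # subsampling an all-maternal cluster can never change its attribution
  set.seed(5)
  for (i in 1:10) {
    sub <- sort(sample(pos, sample(20:31, 1)))
    cl <- cluster_supportive(make_calls(sub, parent = "maternal"),
                             cluster_params())
    if (nrow(cl) > 0) {
      expect_true(all(assign_parent(cl)$parent == "maternal"))
    }
  }
})

test_that("disomy typing uses the coverage threshold with >= at the boundary", {
  p <- cluster_params()
  seg <- tibble::tibble(chrom = "chr15", start = 1e6, end = 10999999)

  full <- tibble::tibble(chrom = "chr15", start = 1e6, end = 10999999)
  expect_equal(type_disomy(seg, full, p)$disomy_type, "isodisomy")

  none <- full[0, ]
  expect_equal(type_disomy(seg, none, p)$disomy_type, "heterodisomy")

  # exactly 80 percent covered: isodisomy by the >= convention
  partial <- tibble::tibble(chrom = "chr15", start = 1e6, end = 8999999)
  typed <- type_disomy(seg, partial, p)
  expect_equal(typed$roh_coverage, 0.8)
  expect_equal(typed$disomy_type, "isodisomy")

  below <- tibble::tibble(chrom = "chr15", start = 1e6, end = 8999998)
  expect_equal(type_disomy(seg, below, p)$disomy_type, "heterodisomy")
})

test_that("breakpoint localisation reproduces the chr15 segment geometry", {
  # maternal isodisomy evidence (mother het, proband hom) up to 60,984,740;
  # heterodisomy evidence (proband het) from 60,984,741 on
  iso_pos <- seq(22373341, 60984740, length.out = 40)
  iso_pos[length(iso_pos)] <- 60984740
  het_pos <- seq(60984741, 102531392, length.out = 40)
  het_pos[1] <- 60984741
  d <- make_trio(round(c(iso_pos, het_pos)),
                 pro = c(rep("1/1", 40), rep("0/1", 40)),
                 mot = "0/1", fat = "0/0")

  proximal <- tibble::tibble(chrom = "chr15", start = 22373341,
                             end = 60984740, parent = "maternal",
                             disomy_type = "isodisomy")
  distal <- tibble::tibble(chrom = "chr15", start = 60984741,
                           end = 102531392, parent = "maternal",
                           disomy_type = "heterodisomy")
  bp <- locate_breakpoint(proximal, distal, d)
  expect_equal(bp$breakpoint, 60984740)
  expect_equal(bp$uncertainty_end, 60984741)
  expect_equal(bp$proximal_type, "isodisomy")

  # the adjacency convention and the reported sizes
  expect_equal(proximal$end + 1, distal$start)
  expect_equal(segment_size(proximal$start, bp$breakpoint), 38.61)
  expect_equal(segment_size(bp$breakpoint + 1, distal$end), 41.55)

  # malformed segment pairs are rejected
  expect_error(locate_breakpoint(proximal,
                                 dplyr::mutate(distal, parent = "paternal"),
                                 d), "parent")
  expect_error(locate_breakpoint(proximal,
                                 dplyr::mutate(distal,
                                               disomy_type = "isodisomy"),
                                 d), "differ")
  expect_error(locate_breakpoint(proximal,
                                 dplyr::mutate(distal, chrom = "chr1"),
                                 d), "chromosome")
})

test_that("the pipeline recovers a maternal meiosis-II segmental UPD", {
  sim <- simulate_trio(study_config(seed = 201, crossover_frac = 0.6))
  res <- run_upd_landscape(sim$data, af_threshold = 1,
                           cluster = study_cluster_params())
  segs <- tidy(res)

  expect_equal(nrow(segs), 2)
  expect_equal(segs$parent, c("maternal", "maternal"))
  expect_equal(segs$disomy_type, c("isodisomy", "heterodisomy"))
  expect_equal(segs$end[1] + 1, segs$start[2])
  expect_true(all(segs$n_support >= study_cluster_params()$min_support))
  expect_true(all(segs$end - segs$start + 1 >=
                    study_cluster_params()$min_span_bp))
  expect_equal(nrow(res$breakpoints), 1)

  # the called breakpoint lies inside the informative-marker gap spanning
  # the true crossover
  cx <- sim$crossovers
  mo_het <- sim$data$mot_a1 != sim$data$mot_a2
  g <- max(sim$data$pos[mo_het & sim$data$pos < cx])
  h <- min(sim$data$pos[mo_het & sim$data$pos > cx])
  expect_gte(res$breakpoints$breakpoint, g)
  expect_lte(res$breakpoints$breakpoint, h)
  expect_lte(abs(res$breakpoints$breakpoint - cx), h - g)

  metrics <- evaluate_recovery(res, sim$truth)
  expect_equal(metrics$segment_type_accuracy, 1)
  expect_equal(metrics$segment_parent_accuracy, 1)
  expect_equal(metrics$false_positive_segments, 0L)
})

test_that("a biparental trio yields no UPD segments", {
  sim <- simulate_trio(sim_config(ndj_stage = "none", n_markers = 5000,
                                  seed = 202))
  res <- run_upd_landscape(sim$data, af_threshold = 1,
                           cluster = study_cluster_params())
  expect_equal(nrow(tidy(res)), 0)
  expect_equal(nrow(res$breakpoints), 0)
  expect_equal(glance(res)$n_supportive, 0)
})

test_that("meiosis-I events give telomeric isodisomy instead", {
  sim <- simulate_trio(sim_config(ndj_stage = "meiosis_I",
                                  crossover_positions = 0.5 * 102531392,
                                  n_markers = 5000, seed = 203))
  res <- run_upd_landscape(sim$data, af_threshold = 1,
                           cluster = study_cluster_params())
  segs <- tidy(res)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$disomy_type, c("heterodisomy", "isodisomy"))
  expect_equal(evaluate_recovery(res, sim$truth)$segment_type_accuracy, 1)
})

test_that("landscape results are deterministic and well-formed", {
  sim <- simulate_trio(study_config(seed = 204, crossover_frac = 0.4))
  r1 <- run_upd_landscape(sim$data, af_threshold = 1,
                          cluster = study_cluster_params())
  r2 <- run_upd_landscape(sim$data, af_threshold = 1,
                          cluster = study_cluster_params())
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$breakpoints, r2$breakpoints)

  segs <- tidy(r1)
  expect_true(all(diff(segs$start) > 0))
  expect_true(all(segs$start[-1] > segs$end[-nrow(segs)]))
  expect_equal(segs$size_mbp, segment_size(segs$start, segs$end))

  g <- glance(r1)
  expect_equal(g$n_segments, nrow(segs))
  expect_s3_class(autoplot(r1), "ggplot")
})
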