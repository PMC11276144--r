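#' Parameters for UPD segment calling
#'
#' @param min_span_bp Minimum genomic span (first to last supportive variant,
#'   1-based inclusive) of a reported cluster. Default 4e6 (4 Mbp).
#' @param min_support Minimum number of supportive variants per cluster.
#'   Default 20.
#' @param max_gap_bp Maximum distance between consecutive supportive variants
#'   within one cluster; a larger gap starts a new cluster. Default 2e6.
#'   Informative-site density varies with marker panel and allele-frequency
#'   spectrum, so tune this to keep the chance of splitting a true segment
#'   negligible (see the methods vignette for the calculation).
#' @param iso_coverage_threshold ROH coverage fraction at or above which a
#'   segment is typed isodisomy. Default 0.8.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(min_span_bp = 4e6, min_support = 20,
                           max_gap_bp = 2e6, iso_coverage_threshold = 0.8) {
  stopifnot(min_span_bp > 0, min_support >= 1, max_gap_bp > 0,
            iso_coverage_threshold > 0, iso_coverage_threshold < 1)
  structure(list(min_span_bp = min_span_bp, min_support = min_support,
                 max_gap_bp = max_gap_bp,
                 iso_coverage_threshold = iso_coverage_threshold),
            class = "cluster_params")
}

#' Cluster supportive variants into candidate UPD regions
#'
#' Greedy single pass per chromosome: consecutive supportive variants
#' separated by at most `max_gap_bp` join one cluster; clusters below the
#' span or support minima are discarded. Parent of origin is not used for
#' joining; mixed-parent clusters are surfaced so that [assign_parent()] can
#' reject them under the strict only-contributor rule.
#'
#' @param calls Output of [classify_trio()].
#' @param params A [cluster_params()] object.
#' @return A tibble of candidate clusters: `chrom`, `start`, `end`,
#'   `n_support`, `n_mat`, `n_pat`, `span_bp`.
#' @export
cluster_supportive <- function(calls, params = cluster_params()) {
  sup <- calls |>
    dplyr::filter(.data$supportive) |>
    dplyr::arrange(.data$chrom, .data$pos)
  empty <- tibble(chrom = character(), start = double(), end = double(),
                  n_support = integer(), n_mat = integer(),
                  n_pat = integer(), span_bp = double())
  if (nrow(sup) == 0) return(empty)
  sup |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(cluster = cumsum(c(1, diff(.data$pos) > params$max_gap_bp))) |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos),
      n_support = dplyr::n(),
      n_mat = sum(.data$parent == "maternal"),
      n_pat = sum(.data$parent == "paternal"),
      .groups = "drop"
    ) |>
    dplyr::mutate(span_bp = .data$end - .data$start + 1) |>
    dplyr::filter(.data$span_bp >= params$min_span_bp,
                  .data$n_support >= params$min_support) |>
    dplyr::select(-"cluster") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Attribute parent of origin to candidate clusters
#'
#' A cluster is maternal only if every supportive variant in it is maternal
#' (and symmetrically paternal); anything mixed is `"ambiguous"` and should
#' be rejected rather than majority-voted.
#'
#' @param clusters Output of [cluster_supportive()].
#' @param warn Emit a warning for ambiguous clusters. Default `TRUE`.
#' @return `clusters` with an added `parent` column.
#' @export
assign_parent <- function(clusters, warn = TRUE) {
  out <- dplyr::mutate(clusters, parent = dplyr::case_when(
    .data$n_mat == .data$n_support ~ "maternal",
    .data$n_pat == .data$n_support ~ "paternal",
    TRUE ~ "ambiguous"
  ))
  amb <- which(out$parent == "ambiguous")
  if (warn && length(amb) > 0) {
    warn(paste0(length(amb), " cluster(s) with mixed parental support ",
                "rejected as ambiguous (e.g. ", out$chrom[amb[1]], ":",
                out$start[amb[1]], "-", out$end[amb[1]], ")"))
  }
  out
}

#' Type segments as isodisomy or heterodisomy by ROH coverage
#'
#' Isodisomy duplicates one parental chromatid, so the proband is homozygous
#' across the segment and it maps onto a run of homozygosity; heterodisomy
#' carries the parent's two different homologs and stays heterozygous. A
#' segment is typed isodisomy when the fraction of its length covered by ROH
#' is at least `iso_coverage_threshold`.
#'
#' @param segments Tibble with `chrom`, `start`, `end`.
#' @param roh_segments ROH tibble from [call_roh()].
#' @param params A [cluster_params()] object.
#' @return `segments` with `roh_coverage` and `disomy_type` columns.
#' @export
type_disomy <- function(segments, roh_segments, params = cluster_params()) {
  segments |>
    roh_coverage(roh_segments) |>
    dplyr::mutate(disomy_type = ifelse(
      .data$roh_coverage >= params$iso_coverage_threshold,
      "isodisomy", "heterodisomy"))
}

# Evidence sites that discriminate the two disomy types, given the parent of
# origin. Isodisomy-pattern supportive variants keep occurring inside a
# heterodisomy region wherever the transmitting parent is homozygous, so the
# only discriminating markers are parent-heterozygous sites: proband
# homozygous there => isodisomy, proband heterozygous there => heterodisomy.
evidence_sites <- function(data, parent) {
  if (parent == "maternal") {
    par1 <- data$mot_a1; par2 <- data$mot_a2
  } else {
    par1 <- data$fat_a1; par2 <- data$fat_a2
  }
  pro_called <- !is.na(data$pro_a1) & !is.na(data$pro_a2)
  par_het <- !is.na(par1) & !is.na(par2) & par1 != par2
  pro_het <- pro_called & data$pro_a1 != data$pro_a2
  list(iso = which(par_het & pro_called & !pro_het),
       het = which(pro_het))
}

#' Localise the breakpoint between adjacent iso- and heterodisomy segments
#'
#' For two adjacent same-parent segments of different disomy type on one
#' chromosome, the breakpoint is placed at the last discriminating site of
#' the centromere-proximal segment type: the last parent-heterozygous,
#' proband-homozygous site when the proximal segment is isodisomy (the last
#' site that can only be explained by isodisomy), or the last
#' proband-heterozygous site when it is heterodisomy. The first
#' discriminating site of the distal type bounds the uncertainty interval;
#' the true recombination point lies between the two. The distal segment is
#' reported starting at breakpoint + 1 so that adjacent segments tile.
#'
#' @param proximal,distal One-row tibbles with `chrom`, `start`, `end`,
#'   `parent`, `disomy_type`; `proximal` must lie before `distal`, share its
#'   chromosome and parent, and differ in type.
#' @param data The [trio_dataset()] the segments were called from.
#' @return A one-row tibble: `chrom`, `parent`, `breakpoint`,
#'   `uncertainty_start`, `uncertainty_end`, `proximal_type`, `distal_type`.
#' @export
locate_breakpoint <- function(proximal, distal, data) {
  if (proximal$chrom != distal$chrom) abort("segments on different chromosomes")
  if (proximal$parent != distal$parent) abort("segments with different parents")
  if (proximal$disomy_type == distal$disomy_type) {
    abort("adjacent segments must differ in disomy type")
  }
  if (proximal$end >= distal$start) abort("segments must be ordered and disjoint")

  d <- data[data$chrom == proximal$chrom, ]
  ev <- evidence_sites(d, proximal$parent)
  pos_iso <- d$pos[ev$iso]
  pos_het <- d$pos[ev$het]

  window_lo <- proximal$start
  window_hi <- distal$end
  if (proximal$disomy_type == "isodisomy") {
    prox_pos <- pos_iso; dist_pos <- pos_het
  } else {
    prox_pos <- pos_het; dist_pos <- pos_iso
  }
  first_distal <- dist_pos[dist_pos > proximal$end & dist_pos <= window_hi]
  first_distal <- if (length(first_distal) > 0) min(first_distal) else distal$start
  bp <- prox_pos[prox_pos >= window_lo & prox_pos < first_distal]
  bp <- if (length(bp) > 0) max(bp) else proximal$end

  tibble(chrom = proximal$chrom, parent = proximal$parent,
         breakpoint = bp,
         uncertainty_start = bp, uncertainty_end = first_distal,
         proximal_type = proximal$disomy_type,
         distal_type = distal$disomy_type)
}

# Split one parent-attributed cluster into runs of supportive variants that
# are inside vs outside called ROH, yielding candidate iso/hetero
# sub-segments. Sub-segments are re-checked against the span/support minima.
split_cluster_by_roh <- function(cluster, calls, roh_segments, params) {
  members <- calls |>
    dplyr::filter(.data$supportive, .data$chrom == cluster$chrom,
                  .data$pos >= cluster$start, .data$pos <= cluster$end) |>
    dplyr::arrange(.data$pos)
  r <- roh_segments[roh_segments$chrom == cluster$chrom, ]
  if (nrow(r) > 0) {
    q <- IRanges::IRanges(start = members$pos, width = 1)
    s <- IRanges::reduce(IRanges::IRanges(start = r$start, end = r$end))
    in_roh <- IRanges::overlapsAny(q, s)
  } else {
    in_roh <- rep(FALSE, nrow(members))
  }
  runs <- rle(in_roh)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segs <- tibble(
    chrom = cluster$chrom,
    start = members$pos[starts],
    end = members$pos[ends],
    n_support = runs$lengths,
    parent = cluster$parent
  )
  dplyr::filter(segs,
                .data$end - .data$start + 1 >= params$min_span_bp,
                .data$n_support >= params$min_support)
}

#' Run the full UPD landscape pipeline
#'
#' Chains classification, ROH calling, supportive-variant clustering, parent
#' attribution, disomy typing and breakpoint localisation:
#'
#' 1. every site is classified ([classify_trio()]);
#' 2. ROH are decoded from the proband genotypes ([call_roh()]);
#' 3. supportive variants are clustered ([cluster_supportive()]) and clusters
#'    attributed to a parent ([assign_parent()]; ambiguous clusters dropped
#'    with a warning);
#' 4. each cluster is split at transitions between ROH-covered and uncovered
#'    supportive variants, sub-segments are re-checked against the cluster
#'    minima and typed by ROH coverage ([type_disomy()]);
#' 5. breakpoints between adjacent same-parent iso/hetero segments are
#'    refined to the last discriminating marker ([locate_breakpoint()]) and
#'    segment bounds adjusted so the pair tiles (end + 1 = next start).
#'
#' The result is deterministic given the inputs and parameters.
#'
#' @param data A [trio_dataset()].
#' @param af_threshold See [classify_trio()].
#' @param cluster A [cluster_params()] object.
#' @param roh An [roh_params()] object.
#' @return An object of class `upd_landscape`: a list with `segments`
#'   (tibble: `chrom`, `start`, `end`, `parent`, `disomy_type`, `n_support`,
#'   `roh_coverage`, `size_mbp`), `breakpoints`, `calls`, `roh`, `clusters`
#'   and the parameters used. Use [tidy()], [glance()] and [autoplot()] on
#'   it.
#' @export
run_upd_landscape <- function(data, af_threshold = 0.01,
                              cluster = cluster_params(),
                              roh = roh_params()) {
  calls <- classify_trio(data, af_threshold = af_threshold)
  roh_segs <- call_roh(data, roh)

  clusters <- cluster_supportive(calls, cluster) |> assign_parent()
  kept <- dplyr::filter(clusters, .data$parent != "ambiguous")

  segments <- purrr::map(seq_len(nrow(kept)), function(i) {
    dplyr::mutate(split_cluster_by_roh(kept[i, ], calls, roh_segs, cluster),
                  .cluster_id = i)
  }) |>
    dplyr::bind_rows()

  if (nrow(segments) > 0) {
    segments <- segments |>
      type_disomy(roh_segs, cluster) |>
      dplyr::arrange(.data$chrom, .data$start)
  } else {
    segments <- tibble(chrom = character(), start = double(), end = double(),
                       n_support = integer(), parent = character(),
                       roh_coverage = double(), disomy_type = character())
  }

  breakpoints <- tibble(chrom = character(), parent = character(),
                        breakpoint = double(), uncertainty_start = double(),
                        uncertainty_end = double(), proximal_type = character(),
                        distal_type = character())
  if (nrow(segments) > 1) {
    for (i in seq_len(nrow(segments) - 1)) {
      a <- segments[i, ]; b <- segments[i + 1, ]
      adjacent <- a$chrom == b$chrom && a$parent == b$parent &&
        a$disomy_type != b$disomy_type &&
        a$.cluster_id == b$.cluster_id
      if (!adjacent) next
      bp <- locate_breakpoint(a, b, data)
      segments$end[i] <- bp$breakpoint
      segments$start[i + 1] <- bp$breakpoint + 1
      breakpoints <- dplyr::bind_rows(breakpoints, bp)
    }
  }

  if (nrow(segments) > 0) {
    # recount support and coverage over the final, refined intervals
    sup <- dplyr::filter(calls, .data$supportive)
    segments$n_support <- vapply(seq_len(nrow(segments)), function(i) {
      sum(sup$chrom == segments$chrom[i] &
            sup$pos >= segments$start[i] & sup$pos <= segments$end[i])
    }, integer(1))
    segments <- segments |>
      dplyr::select(-"roh_coverage") |>
      roh_coverage(roh_segs) |>
      dplyr::mutate(size_mbp = segment_size(.data$start, .data$end)) |>
      dplyr::select("chrom", "start", "end", "parent", "disomy_type",
                    "n_support", "roh_coverage", "size_mbp")
  } else {
    segments <- dplyr::mutate(segments, size_mbp = double(0)) |>
      dplyr::select("chrom", "start", "end", "parent", "disomy_type",
                    "n_support", "roh_coverage", "size_mbp")
  }

  structure(
    list(segments = segments, breakpoints = breakpoints, calls = calls,
         roh = roh_segs, clusters = clusters,
         params = list(af_threshold = af_threshold, cluster = cluster,
                       roh = roh)),
    class = "upd_landscape"
  )
}
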