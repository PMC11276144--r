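#' Scan isodisomy segments for unmasked recessive alleles
#'
#' Within isodisomy, the proband carries two copies of one parental
#' chromatid, so any allele the transmitting parent carries heterozygously
#' on that chromatid becomes homozygous in the proband — a recessive variant
#' can be "unmasked" with only one carrier parent. This scan reports every
#' site inside an isodisomy segment where the proband is homozygous
#' non-reference, the segment's parent carries the allele (het or hom), and
#' the other parent lacks it.
#'
#' @param data A [trio_dataset()].
#' @param segments Segment tibble (as from [run_upd_landscape()]); only rows
#'   with `disomy_type == "isodisomy"` are scanned.
#' @param pathogenic Optional character vector of variant keys
#'   (`"chrom:pos:ref:alt"`, e.g. from [read_pathogenic_list()]); matching
#'   candidates are flagged.
#' @return A tibble of candidates sorted by position: `chrom`, `pos`, `ref`,
#'   `alt` (the homozygous allele), `gt_proband`, `gt_carrier`,
#'   `carrier_parent`, `pop_af`, `segment_start`, `segment_end`,
#'   `flagged_pathogenic`.
#' @export
scan_unmasked <- function(data, segments, pathogenic = NULL) {
  iso <- dplyr::filter(segments, .data$disomy_type == "isodisomy")
  empty <- tibble(chrom = character(), pos = double(), ref = character(),
                  alt = character(), gt_proband = character(),
                  gt_carrier = character(), carrier_parent = character(),
                  pop_af = double(), segment_start = double(),
                  segment_end = double(), flagged_pathogenic = logical())
  if (nrow(iso) == 0) return(empty)

  out <- purrr::map(seq_len(nrow(iso)), function(i) {
    seg <- iso[i, ]
    d <- data[data$chrom == seg$chrom &
                data$pos >= seg$start & data$pos <= seg$end, ]
    if (nrow(d) == 0) return(NULL)
    if (seg$parent == "maternal") {
      c1 <- d$mot_a1; c2 <- d$mot_a2; o1 <- d$fat_a1; o2 <- d$fat_a2
    } else {
      c1 <- d$fat_a1; c2 <- d$fat_a2; o1 <- d$mot_a1; o2 <- d$mot_a2
    }
    a <- d$pro_a1
    hom_alt <- !is.na(d$pro_a1) & !is.na(d$pro_a2) &
      d$pro_a1 == d$pro_a2 & d$pro_a1 > 0
    carrier_has <- !is.na(c1) & !is.na(c2) & (c1 == a | c2 == a)
    other_lacks <- !is.na(o1) & !is.na(o2) & o1 != a & o2 != a
    hit <- hom_alt & carrier_has & other_lacks
    if (!any(hit)) return(NULL)
    h <- d[hit, ]
    alt_seq <- vapply(seq_len(nrow(h)), function(j) {
      strsplit(h$alt[j], ",", fixed = TRUE)[[1]][h$pro_a1[j]]
    }, character(1))
    tibble(
      chrom = h$chrom, pos = h$pos, ref = h$ref, alt = alt_seq,
      gt_proband = format_gt(h$pro_a1, h$pro_a2),
      gt_carrier = if (seg$parent == "maternal") {
        format_gt(h$mot_a1, h$mot_a2)
      } else {
        format_gt(h$fat_a1, h$fat_a2)
      },
      carrier_parent = seg$parent,
      pop_af = h$pop_af,
      segment_start = seg$start, segment_end = seg$end
    )
  }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) return(empty)
  out |>
    dplyr::mutate(flagged_pathogenic =
                    paste(.data$chrom, .data$pos, .data$ref, .data$alt,
                          sep = ":") %in% (pathogenic %||% character(0))) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Aggregate in-silico missense prediction scores
#'
#' Combines a set of per-tool scores (each in `[0, 1]`) by their unweighted
#' mean and classifies the result: mean at or above 0.7 is deleterious,
#' below 0.15 benign, otherwise uncertain.
#'
#' @param scores Numeric vector of at least one tool score in `[0, 1]`.
#' @param deleterious_threshold,benign_threshold Class boundaries; defaults
#'   0.7 and 0.15.
#' @return `"deleterious"`, `"benign"` or `"uncertain"`.
#' @export
#' @examples
#' aggregate_insilico(c(0.9, 0.8, 0.7))  # deleterious
#' aggregate_insilico(c(0.1, 0.05))      # benign
aggregate_insilico <- function(scores, deleterious_threshold = 0.7,
                               benign_threshold = 0.15) {
  if (length(scores) == 0) abort("at least one prediction score is required")
  if (any(is.na(scores)) || any(scores < 0 | scores > 1)) {
    abort("prediction scores must be in [0, 1]")
  }
  m <- mean(scores)
  if (m >= deleterious_threshold) "deleterious"
  else if (m < benign_threshold) "benign"
  else "uncertain"
}

#' Classify a splice prediction score
#'
#' Applies the splice-model thresholds: scores at or above 0.7 are
#' deleterious, at or below 0.2 benign, in between uncertain.
#'
#' @param splice_score Numeric vector of scores in `[0, 1]`.
#' @param upper,lower Thresholds; defaults 0.7 and 0.2.
#' @return Character vector of classes.
#' @export
classify_splice <- function(splice_score, upper = 0.7, lower = 0.2) {
  if (any(is.na(splice_score)) || any(splice_score < 0 | splice_score > 1)) {
    abort("splice scores must be in [0, 1]")
  }
  dplyr::case_when(
    splice_score >= upper ~ "deleterious",
    splice_score <= lower ~ "benign",
    TRUE ~ "uncertain"
  )
}
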