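#' Classify every site of a trio dataset
#'
#' Assigns each variant site exactly one inheritance category based on the
#' three genotypes:
#'
#' * `MAT_ISO_SUPPORT` / `PAT_ISO_SUPPORT` — proband homozygous for a
#'   non-reference allele, the relevant parent carries it (het or hom) and the
#'   other parent is homozygous reference. These are the classical
#'   UPD-supportive variants of isodisomy type.
#' * `MAT_HET_SUPPORT` / `PAT_HET_SUPPORT` — proband heterozygous, no
#'   one-allele-per-parent transmission is consistent, but both proband
#'   alleles can come from a single parent (heterodisomy type; requires a
#'   multiallelic site or a non-reference other parent).
#' * `BIPARENTAL_CONSISTENT` — a transmission with one allele from each
#'   parent exists.
#' * `MENDELIAN_ERROR_OTHER` — the proband carries an allele absent from
#'   both parents.
#' * `UNINFORMATIVE` — a genotype is missing, or no category above applies.
#'
#' Sites whose population allele frequency is at or above `af_threshold` keep
#' their pattern category but are flagged `af_filtered` and never count as
#' supportive: common alleles can be present in the other parent by chance
#' (with an undetected genotype), so they are excluded from UPD evidence.
#'
#' @param data A [trio_dataset()].
#' @param af_threshold Population allele frequency at or above which a site is
#'   excluded from supportive status. Default 0.01 (the 1 percent filter).
#'   Set to 1 to disable, e.g. for simulated data with complete genotypes.
#'
#' @return A tibble with one row per site: `chrom`, `pos`, `category`,
#'   `af_filtered`, `supportive` (pattern supportive and not AF-filtered),
#'   `parent` (`"maternal"`/`"paternal"`/`NA`) and `support_type`
#'   (`"iso"`/`"het"`/`NA`).
#' @export
#' @examples
#' sites <- tibble::tibble(
#'   chrom = "chr15", pos = c(100, 200), ref = "A", alt = "G",
#'   pro_a1 = c(1L, 0L), pro_a2 = c(1L, 1L),
#'   mot_a1 = c(0L, 0L), mot_a2 = c(1L, 1L),
#'   fat_a1 = c(0L, 0L), fat_a2 = c(0L, 1L),
#'   pop_af = 0.001
#' )
#' classify_trio(trio_dataset(sites))
classify_trio <- function(data, af_threshold = 0.01) {
  stopifnot(af_threshold >= 0, af_threshold <= 1)
  cls <- classify_genotypes(data$pro_a1, data$pro_a2,
                            data$mot_a1, data$mot_a2,
                            data$fat_a1, data$fat_a2)
  af_filtered <- !is.na(data$pop_af) & data$pop_af >= af_threshold
  supportive <- cls %in% SUPPORTIVE_CATEGORIES & !af_filtered
  parent <- dplyr::case_when(
    startsWith(cls, "MAT_") ~ "maternal",
    startsWith(cls, "PAT_") ~ "paternal",
    TRUE ~ NA_character_
  )
  support_type <- dplyr::case_when(
    endsWith(cls, "ISO_SUPPORT") ~ "iso",
    endsWith(cls, "HET_SUPPORT") ~ "het",
    TRUE ~ NA_character_
  )
  tibble(
    chrom = data$chrom, pos = data$pos,
    category = factor(cls, levels = CATEGORY_LEVELS),
    af_filtered = af_filtered,
    supportive = supportive,
    parent = parent,
    support_type = support_type
  )
}

#' Classify a single trio genotype configuration
#'
#' Scalar convenience wrapper around the vectorised classifier; see
#' [classify_trio()] for the category definitions.
#'
#' @param gt_proband,gt_mother,gt_father Genotypes as length-2 integer
#'   vectors of allele indices, or VCF-style strings such as `"0/1"`.
#' @param pop_af Population allele frequency (`NA` if unknown).
#' @param af_threshold See [classify_trio()].
#' @return A one-row tibble with `category`, `af_filtered` and `supportive`.
#' @export
classify_site <- function(gt_proband, gt_mother, gt_father,
                          pop_af = NA_real_, af_threshold = 0.01) {
  as_pair <- function(g) {
    if (is.character(g)) g <- parse_gt(g)[1, ]
    as.integer(g)
  }
  p <- as_pair(gt_proband); m <- as_pair(gt_mother); f <- as_pair(gt_father)
  cls <- classify_genotypes(p[1], p[2], m[1], m[2], f[1], f[2])
  af_filtered <- !is.na(pop_af) && pop_af >= af_threshold
  tibble(
    category = factor(cls, levels = CATEGORY_LEVELS),
    af_filtered = af_filtered,
    supportive = cls %in% SUPPORTIVE_CATEGORIES && !af_filtered
  )
}

# Vectorised classification core over allele index columns.
# Genotypes are unordered pairs; all rules are written on the sorted pair so
# allele order within a call never matters.
classify_genotypes <- function(p1, p2, m1, m2, f1, f2) {
  pa1 <- pmin(p1, p2)
  pa2 <- pmax(p1, p2)
  missing <- is.na(pa1) | is.na(m1) | is.na(m2) | is.na(f1) | is.na(f2)

  has_m <- function(a) !is.na(a) & (m1 == a | m2 == a)
  has_f <- function(a) !is.na(a) & (f1 == a | f2 == a)

  hom_alt <- !is.na(pa1) & pa1 == pa2 & pa1 > 0
  mat_iso <- hom_alt & has_m(pa1) & f1 == 0 & f2 == 0
  pat_iso <- hom_alt & has_f(pa1) & m1 == 0 & m2 == 0

  # one allele from each parent, in either assignment
  consistent <- (has_m(pa1) & has_f(pa2)) | (has_m(pa2) & has_f(pa1))

  het <- !is.na(pa1) & pa1 != pa2
  mat_only <- het & has_m(pa1) & has_m(pa2)
  pat_only <- het & has_f(pa1) & has_f(pa2)

  absent <- (!has_m(pa1) & !has_f(pa1)) | (!has_m(pa2) & !has_f(pa2))

  dplyr::case_when(
    missing ~ "UNINFORMATIVE",
    mat_iso ~ "MAT_ISO_SUPPORT",
    pat_iso ~ "PAT_ISO_SUPPORT",
    consistent ~ "BIPARENTAL_CONSISTENT",
    mat_only & !pat_only ~ "MAT_HET_SUPPORT",
    pat_only & !mat_only ~ "PAT_HET_SUPPORT",
    absent ~ "MENDELIAN_ERROR_OTHER",
    TRUE ~ "UNINFORMATIVE"
  )
}

#' Summarise inheritance calls per chromosome
#'
#' @param calls Output of [classify_trio()].
#' @return A tibble of counts per chromosome and category, plus the number of
#'   AF-filtered and effective supportive sites.
#' @export
count_calls <- function(calls) {
  calls |>
    dplyr::group_by(.data$chrom, .data$category, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_af_filtered = sum(.data$af_filtered),
      n_supportive = sum(.data$supportive),
      .groups = "drop"
    )
}
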