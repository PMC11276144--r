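#' Construct a trio genotype dataset
#'
#' A trio dataset is a tibble with one row per variant site and the genotypes
#' of proband, mother and father stored as pairs of allele indices
#' (0 = reference, >= 1 = alternate; `NA` = missing call). Positions are
#' 1-based and inclusive throughout the package; conversion to BED's 0-based
#' half-open convention happens only in [write_segments_bed()].
#'
#' @param sites A data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated string for multiallelic records), `pro_a1`, `pro_a2`,
#'   `mot_a1`, `mot_a2`, `fat_a1`, `fat_a2` and `pop_af` (population allele
#'   frequency of the least-frequent non-reference allele, `NA` if unknown).
#' @param sample_ids Named character vector with elements `proband`, `mother`
#'   and `father` giving the sample identifiers.
#'
#' @return A tibble of class `trio_dataset`, sorted by chromosome and
#'   position, with a `sample_ids` attribute.
#' @export
trio_dataset <- function(sites,
                         sample_ids = c(proband = "PROBAND",
                                        mother = "MOTHER",
                                        father = "FATHER")) {
  required <- c("chrom", "pos", "ref", "alt",
                "pro_a1", "pro_a2", "mot_a1", "mot_a2", "fat_a1", "fat_a2",
                "pop_af")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("trio_dataset is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(c("proband", "mother", "father") %in% names(sample_ids))) {
    abort("sample_ids must name a proband, a mother and a father")
  }
  x <- as_tibble(sites)
  if (any(x$pos < 1, na.rm = TRUE)) abort("positions must be >= 1")

  # genotypes with one missing allele are treated as fully missing
  for (role in c("pro", "mot", "fat")) {
    a1 <- x[[paste0(role, "_a1")]]
    a2 <- x[[paste0(role, "_a2")]]
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) {
      x[[paste0(role, "_a1")]][half] <- NA_integer_
      x[[paste0(role, "_a2")]][half] <- NA_integer_
    }
  }

  n_alt <- lengths(strsplit(x$alt, ",", fixed = TRUE))
  max_idx <- pmax(x$pro_a1, x$pro_a2, x$mot_a1, x$mot_a2, x$fat_a1, x$fat_a2,
                  na.rm = TRUE)
  bad <- !is.na(max_idx) & max_idx > n_alt
  if (any(bad)) {
    abort(paste0("allele index exceeds the number of ALT alleles at ",
                 x$chrom[bad][1], ":", x$pos[bad][1]))
  }

  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  dup <- duplicated(x[, c("chrom", "pos")])
  if (any(dup)) {
    abort(paste0("duplicated site position at ",
                 x$chrom[dup][1], ":", x$pos[dup][1]))
  }

  attr(x, "sample_ids") <- sample_ids
  class(x) <- c("trio_dataset", class(x))
  x
}

#' Check that positions are strictly increasing within each chromosome
#' @noRd
assert_sorted_sites <- function(chrom, pos, what = "input") {
  ord <- order(chrom, pos)
  bad <- which(diff(ord) != 1)
  by_chrom <- split(pos, chrom)
  for (ch in names(by_chrom)) {
    p <- by_chrom[[ch]]
    i <- which(diff(p) <= 0)
    if (length(i) > 0) {
      abort(paste0(what, " is not position-sorted: ", ch, ":", p[i[1] + 1],
                   " follows ", ch, ":", p[i[1]]))
    }
  }
  invisible(TRUE)
}

#' Format allele index pairs as VCF-style genotype strings
#'
#' @param a1,a2 Integer vectors of allele indices; `NA` for missing.
#' @return Character vector such as `"0/1"` or `"./."`.
#' @export
format_gt <- function(a1, a2) {
  out <- paste0(a1, "/", a2)
  out[is.na(a1) | is.na(a2)] <- "./."
  out
}

#' Parse VCF genotype strings into allele index pairs
#'
#' Accepts `/` or `|` separators; any missing allele renders the whole
#' genotype missing.
#'
#' @param gt Character vector of GT strings.
#' @return A two-column integer matrix (`a1`, `a2`).
#' @export
parse_gt <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, function(p) p[1] %||% NA_character_, "")))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  cbind(a1 = a1, a2 = a2)
}

#' Segment size in megabases
#'
#' Size of a 1-based inclusive interval in Mbp, rounded half-up to two
#' decimals (the precision at which segment sizes are conventionally
#' reported).
#'
#' @param start,end Interval bounds, 1-based inclusive.
#' @return Numeric vector of sizes in Mbp.
#' @export
#' @examples
#' segment_size(22373341, 60984740)  # 38.61
segment_size <- function(start, end) {
  if (any(end < start)) abort("end must be >= start")
  mbp <- (end - start + 1) / 1e6
  floor(mbp * 100 + 0.5) / 100
}
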