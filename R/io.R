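#' Read a multi-sample VCF into a trio dataset
#'
#' Parses a jointly genotyped VCF, keeps autosomal sites with at least one
#' called genotype among the three trio members, and preserves multiallelic
#' records unsplit. Sites where one member's genotype is missing are kept
#' (the classifier treats them as uninformative). Input must be
#' position-sorted within each chromosome.
#'
#' @param path Path to a VCF (plain or bgzip/gzip).
#' @param proband,mother,father Sample identifiers in the VCF.
#' @param af_field INFO tag carrying the population allele frequency
#'   (comma-separated per ALT allele for multiallelic records; the
#'   least-frequent non-reference allele is retained). `NULL` to skip; a
#'   named tag absent from the file yields unknown frequencies with a
#'   warning.
#' @return A [trio_dataset()].
#' @export
read_trio_vcf <- function(path, proband = "PROBAND", mother = "MOTHER",
                          father = "FATHER", af_field = "AF") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  roles <- c(proband = proband, mother = mother, father = father)
  missing_roles <- roles[!roles %in% samples]
  if (length(missing_roles) > 0) {
    abort(paste0("sample(s) not present in VCF: ",
                 paste(names(missing_roles), "=", missing_roles,
                       collapse = ", ")))
  }

  fix <- vcf@fix
  chrom <- fix[, "CHROM"]
  pos <- as.double(fix[, "POS"])

  autosomal <- !grepl("^(chr)?(x|y|m|mt)$", chrom, ignore.case = TRUE)
  keep <- which(autosomal)
  if (length(keep) == 0) abort("no autosomal records in VCF")

  assert_sorted_sites(chrom[keep], pos[keep], "VCF")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  pro <- parse_gt(gt[keep, proband])
  mot <- parse_gt(gt[keep, mother])
  fat <- parse_gt(gt[keep, father])

  any_called <- !is.na(pro[, 1]) | !is.na(mot[, 1]) | !is.na(fat[, 1])

  pop_af <- rep(NA_real_, length(keep))
  if (!is.null(af_field)) {
    raw <- suppressWarnings(vcfR::extract.info(vcf, element = af_field))
    if (is.null(raw) || all(is.na(raw))) {
      warn(paste0("INFO tag '", af_field,
                  "' not found; population allele frequencies set to unknown"))
    } else {
      pop_af <- vapply(raw[keep], function(x) {
        if (is.na(x)) return(NA_real_)
        suppressWarnings(min(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])))
      }, numeric(1), USE.NAMES = FALSE)
    }
  }

  sites <- tibble(
    chrom = chrom[keep], pos = pos[keep],
    ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
    pro_a1 = pro[, 1], pro_a2 = pro[, 2],
    mot_a1 = mot[, 1], mot_a2 = mot[, 2],
    fat_a1 = fat[, 1], fat_a2 = fat[, 2],
    pop_af = pop_af
  )[any_called, ]

  trio_dataset(sites, sample_ids = roles)
}

#' Write a trio dataset as a multi-sample VCF
#'
#' Emits a VCFv4.3 file (gzipped when `path` ends in `.gz`, which is what
#' [vcfR::write.vcf()] produces in all cases) with an `AF` INFO tag and the
#' three samples in proband/mother/father order.
#'
#' @param data A [trio_dataset()].
#' @param path Output path (conventionally `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(data, path) {
  ids <- attr(data, "sample_ids") %||%
    c(proband = "PROBAND", mother = "MOTHER", father = "FATHER")
  meta <- c(
    "##fileformat=VCFv4.3",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  info <- ifelse(is.na(data$pop_af), ".",
                 paste0("AF=", format(data$pop_af, scientific = FALSE,
                                      trim = TRUE, digits = 10)))
  fix <- cbind(
    CHROM = data$chrom,
    POS = format(data$pos, scientific = FALSE, trim = TRUE),
    ID = ".", REF = data$ref, ALT = data$alt,
    QUAL = ".", FILTER = "PASS", INFO = info
  )
  gt <- cbind(
    FORMAT = "GT",
    format_gt(data$pro_a1, data$pro_a2),
    format_gt(data$mot_a1, data$mot_a2),
    format_gt(data$fat_a1, data$fat_a2)
  )
  colnames(gt) <- c("FORMAT", ids[["proband"]], ids[["mother"]],
                    ids[["father"]])
  # resolve the S4 class in vcfR's namespace: the package may be loaded
  # without being attached (e.g. from Rscript)
  out <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}

#' Write segments to a BED file
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention (start - 1, end unchanged). The name column encodes
#' the segment annotation (`disomy_type:parent` for UPD segments, `ROH`
#' otherwise) and the score column the supporting-variant or marker count.
#'
#' @param segments A segment tibble (UPD or ROH); must be sorted and
#'   non-overlapping within each chromosome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  if (nrow(segments) > 0) {
    s <- dplyr::arrange(segments, .data$chrom, .data$start)
    by_chrom <- split(s, s$chrom)
    for (g in by_chrom) {
      if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)])) {
        abort("segments overlap; refusing to write BED")
      }
    }
    name <- if (all(c("disomy_type", "parent") %in% names(s))) {
      paste0(s$disomy_type, ":", s$parent)
    } else {
      rep("ROH", nrow(s))
    }
    score <- if ("n_support" %in% names(s)) {
      s$n_support
    } else if ("n_markers" %in% names(s)) {
      s$n_markers
    } else {
      rep(0L, nrow(s))
    }
    bed <- tibble(chrom = s$chrom, start = s$start - 1, end = s$end,
                  name = name, score = score)
  } else {
    bed <- tibble(chrom = character(), start = double(), end = double(),
                  name = character(), score = integer())
  }
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file of segments
#'
#' Inverse of [write_segments_bed()]: restores the 1-based inclusive
#' convention (start + 1, end unchanged).
#'
#' @param path BED file path.
#' @return A tibble with `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_segments_bed <- function(path) {
  bed <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end", "name",
                                       "score"),
                         col_types = "cddci", progress = FALSE)
  dplyr::mutate(bed, start = .data$start + 1)
}

#' Write the per-site zygosity/classification table
#'
#' One row per site with the trio genotypes and the inheritance category, as
#' a nine-column TSV (`chrom`, `pos`, `ref`, `alt`, `gt_proband`,
#' `gt_mother`, `gt_father`, `pop_af`, `category`).
#'
#' @param data A [trio_dataset()].
#' @param calls Matching output of [classify_trio()] (one call per site, in
#'   order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(data, calls, path) {
  if (nrow(data) != nrow(calls)) {
    abort("dataset and calls differ in length")
  }
  tab <- tibble(
    chrom = data$chrom, pos = data$pos, ref = data$ref, alt = data$alt,
    gt_proband = format_gt(data$pro_a1, data$pro_a2),
    gt_mother = format_gt(data$mot_a1, data$mot_a2),
    gt_father = format_gt(data$fat_a1, data$fat_a2),
    pop_af = data$pop_af,
    category = as.character(calls$category)
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a pathogenic-variant list
#'
#' Accepts either a four-column TSV (`chrom`, `pos`, `ref`, `alt`, with or
#' without a header, `#` comments ignored) or a minimal VCF, and returns the
#' variant keys used by [scan_unmasked()].
#'
#' @param path File path.
#' @return Character vector of `"chrom:pos:ref:alt"` keys.
#' @export
read_pathogenic_list <- function(path) {
  first <- readLines(path, n = 50L)
  if (any(grepl("^##fileformat=VCF", first)) || grepl("\\.vcf(\\.gz)?$", path)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcf@fix
    return(paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
                 sep = ":"))
  }
  tab <- suppressWarnings(
    readr::read_tsv(path, comment = "#",
                    col_names = c("chrom", "pos", "ref", "alt"),
                    col_types = "cdcc", progress = FALSE))
  # tolerate a header row
  if (is.na(tab$pos[1])) tab <- tab[-1, ]
  paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
}
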