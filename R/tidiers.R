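#' Tidy a UPD landscape result
#'
#' @param x An `upd_landscape` object from [run_upd_landscape()].
#' @param ... Unused.
#' @return The segment table as a tibble, one row per reported UPD segment.
#' @exportS3Method generics::tidy
tidy.upd_landscape <- function(x, ...) {
  x$segments
}

#' One-row summary of a UPD landscape result
#'
#' @param x An `upd_landscape` object.
#' @param ... Unused.
#' @return A one-row tibble: site, supportive-variant, segment, breakpoint
#'   and ROH counts plus total UPD extent in Mbp.
#' @exportS3Method generics::glance
glance.upd_landscape <- function(x, ...) {
  tibble(
    n_sites = nrow(x$calls),
    n_supportive = sum(x$calls$supportive),
    n_af_filtered = sum(x$calls$af_filtered),
    n_segments = nrow(x$segments),
    n_isodisomy = sum(x$segments$disomy_type == "isodisomy"),
    n_heterodisomy = sum(x$segments$disomy_type == "heterodisomy"),
    n_breakpoints = nrow(x$breakpoints),
    n_roh = nrow(x$roh),
    upd_mbp = sum(x$segments$size_mbp)
  )
}

#' @export
print.upd_landscape <- function(x, ...) {
  g <- glance(x)
  cat("UPD landscape:", g$n_segments, "segment(s) (",
      g$n_isodisomy, "isodisomy /", g$n_heterodisomy, "heterodisomy ),",
      g$n_breakpoints, "breakpoint(s),", g$n_roh, "ROH segment(s)\n")
  cat("Sites:", g$n_sites, "|| supportive:", g$n_supportive,
      "|| AF-filtered:", g$n_af_filtered, "\n")
  if (nrow(x$segments) > 0) {
    cat("\nSegments:\n")
    print(x$segments, ...)
  }
  if (nrow(x$breakpoints) > 0) {
    cat("\nBreakpoints:\n")
    print(x$breakpoints, ...)
  }
  invisible(x)
}

#' @export
print.trio_sim <- function(x, ...) {
  cat("Simulated trio:", nrow(x$data), "sites on", x$config$chrom,
      "| mechanism:", x$config$ndj_stage,
      if (x$config$ndj_stage != "none") paste0("(", x$config$ndj_parent, ")"),
      "\n")
  if (nrow(x$truth) > 0) {
    cat("Truth segments:\n")
    print(x$truth, ...)
  }
  invisible(x)
}
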