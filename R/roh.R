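#' Parameters for the run-of-homozygosity HMM
#'
#' The caller is a two-state (ROH / non-ROH) hidden Markov model over the
#' proband's called genotypes, emitting heterozygous or homozygous at each
#' marker. Inside an ROH a heterozygous call can only arise from genotyping
#' error (`p_het_in_roh`). Outside, the per-site heterozygosity probability
#' defaults to the Hardy-Weinberg expectation `2*af*(1-af)` from the site's
#' population allele frequency, floored at `het_floor` (and equal to
#' `het_floor` when the frequency is unknown); supplying `p_het_outside`
#' overrides it with a constant. The state-switch probability per adjacent
#' marker pair is `t_switch`, and the initial state distribution is uniform.
#'
#' @param p_het_in_roh Emission probability of a heterozygous call inside an
#'   ROH. Default 0.005.
#' @param p_het_outside Constant outside-ROH heterozygosity probability, or
#'   `NULL` (default) for the per-site Hardy-Weinberg value.
#' @param het_floor Lower bound for the outside-ROH heterozygosity
#'   probability. Default 0.05.
#' @param t_switch Per-adjacent-marker state switch probability. Default 1e-4.
#' @param min_length_bp Minimum reported segment length. Default 1e6.
#' @param min_markers Minimum markers per reported segment. Default 25.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(p_het_in_roh = 0.005, p_het_outside = NULL,
                       het_floor = 0.05, t_switch = 1e-4,
                       min_length_bp = 1e6, min_markers = 25) {
  stopifnot(
    p_het_in_roh > 0, p_het_in_roh < 1,
    is.null(p_het_outside) || (p_het_outside > 0 && p_het_outside < 1),
    het_floor > 0, het_floor < 1,
    t_switch > 0, t_switch < 1,
    min_length_bp >= 0, min_markers >= 1
  )
  structure(list(p_het_in_roh = p_het_in_roh, p_het_outside = p_het_outside,
                 het_floor = het_floor, t_switch = t_switch,
                 min_length_bp = min_length_bp, min_markers = min_markers),
            class = "roh_params")
}

# Per-site outside-ROH heterozygosity emission probabilities.
outside_het_prob <- function(pop_af, params) {
  if (!is.null(params$p_het_outside)) {
    rep(params$p_het_outside, length(pop_af))
  } else {
    hw <- 2 * pop_af * (1 - pop_af)
    out <- pmax(hw, params$het_floor)
    out[is.na(out)] <- params$het_floor
    out
  }
}

# Viterbi decoding of the two-state chain. Returns a logical in-ROH vector.
# Ties resolve toward the non-ROH state (final state and back-pointers),
# which makes the decoded path the reverse-lexicographically smallest among
# all maximum-probability paths -- the same convention the brute-force
# oracle applies.
viterbi_path <- function(het, p_out, p_in, t_switch) {
  n <- length(het)
  if (n == 0) return(logical(0))
  e_out <- ifelse(het, log(p_out), log1p(-p_out))
  e_in <- ifelse(het, log(p_in), log1p(-p_in))
  ls <- log1p(-t_switch)
  lw <- log(t_switch)

  v_out <- log(0.5) + e_out[1]
  v_in <- log(0.5) + e_in[1]
  ptr_out <- ptr_in <- logical(n)  # TRUE = previous state was ROH
  if (n > 1) {
    for (t in 2:n) {
      from_out <- v_out + ls; from_in <- v_in + lw
      ptr_out[t] <- from_in > from_out
      new_out <- max(from_out, from_in) + e_out[t]
      from_out2 <- v_out + lw; from_in2 <- v_in + ls
      ptr_in[t] <- from_in2 > from_out2
      new_in <- max(from_out2, from_in2) + e_in[t]
      v_out <- new_out; v_in <- new_in
    }
  }
  path <- logical(n)
  path[n] <- v_in > v_out
  if (n > 1) {
    for (t in n:2) {
      path[t - 1] <- if (path[t]) ptr_in[t] else ptr_out[t]
    }
  }
  path
}

# Maximal in-ROH runs -> segment tibble, with length/marker filters.
path_to_segments <- function(path, pos, het, chrom, params) {
  empty <- tibble(chrom = character(), start = double(), end = double(),
                  n_markers = integer(), mean_het_rate = double())
  if (length(path) == 0 || !any(path)) return(empty)
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  segs <- tibble(
    chrom = chrom,
    start = pos[starts[keep]],
    end = pos[ends[keep]],
    n_markers = r$lengths[keep],
    mean_het_rate = vapply(keep, function(i) {
      mean(het[starts[i]:ends[i]])
    }, numeric(1))
  )
  dplyr::filter(segs,
                .data$end - .data$start + 1 >= params$min_length_bp,
                .data$n_markers >= params$min_markers)
}

#' Call runs of homozygosity in the proband
#'
#' Viterbi-decodes the two-state HMM described in [roh_params()] over the
#' proband's called genotypes of each chromosome and reports maximal ROH
#' runs passing the minimum length and marker-count filters. Segment bounds
#' are the first and last marker positions of the run.
#'
#' @param data A [trio_dataset()].
#' @param params An [roh_params()] object.
#' @return A tibble of ROH segments: `chrom`, `start`, `end`, `n_markers`,
#'   `mean_het_rate`.
#' @export
call_roh <- function(data, params = roh_params()) {
  assert_sorted_sites(data$chrom, data$pos, "trio dataset")
  called <- !is.na(data$pro_a1) & !is.na(data$pro_a2)
  d <- data[called, ]
  if (nrow(d) == 0) {
    return(path_to_segments(logical(0), double(0), logical(0), character(0),
                            params))
  }
  d |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(g, key) {
      het <- g$pro_a1 != g$pro_a2
      p_out <- outside_het_prob(g$pop_af, params)
      path <- viterbi_path(het, p_out, params$p_het_in_roh, params$t_switch)
      path_to_segments(path, g$pos, het, key$chrom, params)
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Exhaustive-enumeration ROH caller (test oracle)
#'
#' Scores every one of the `2^n` state paths explicitly and returns the
#' segments of the globally optimal one, applying the same post-filters as
#' [call_roh()]. Among score-tied paths the reverse-lexicographically
#' smallest with non-ROH < ROH is chosen, which is exactly the path the
#' Viterbi tie-break selects. Guarded to small inputs; this exists to verify
#' the dynamic program, not to be fast.
#'
#' @param het Logical vector: is the proband heterozygous at each marker.
#' @param pos Marker positions (sorted, 1-based).
#' @param pop_af Population allele frequencies (may be `NA`).
#' @param params An [roh_params()] object.
#' @param chrom Chromosome label for the output.
#' @return A tibble of ROH segments as in [call_roh()].
#' @export
brute_force_roh <- function(het, pos, pop_af = rep(NA_real_, length(het)),
                            params = roh_params(), chrom = "chr1") {
  n <- length(het)
  stopifnot(length(pos) == n, length(pop_af) == n)
  if (n == 0) {
    return(path_to_segments(logical(0), double(0), logical(0), chrom, params))
  }
  if (n > 15) abort("brute_force_roh is an oracle for <= 15 markers")

  p_out <- outside_het_prob(pop_af, params)
  e_out <- ifelse(het, log(p_out), log1p(-p_out))
  e_in <- ifelse(het, log(params$p_het_in_roh), log1p(-params$p_het_in_roh))
  ls <- log1p(-params$t_switch)
  lw <- log(params$t_switch)

  paths <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  emit <- as.vector(paths %*% (e_in - e_out)) + sum(e_out)
  if (n > 1) {
    switches <- rowSums(paths[, -1, drop = FALSE] != paths[, -n, drop = FALSE])
    trans <- switches * lw + (n - 1 - switches) * ls
  } else {
    trans <- 0
  }
  score <- log(0.5) + emit + trans

  best <- which(score == max(score))
  if (length(best) > 1) {
    tied <- paths[best, , drop = FALSE]
    ord <- do.call(order, as.data.frame(tied[, n:1, drop = FALSE]))
    best <- best[ord[1]]
  }
  path_to_segments(as.logical(paths[best, ]), pos, het, chrom, params)
}

#' Fraction of each segment covered by runs of homozygosity
#'
#' Computes, per query segment, the fraction of its length covered by the
#' union of the ROH intervals on the same chromosome. A maternal isodisomy
#' segment maps completely onto ROH; a heterodisomy segment does not.
#'
#' @param segments Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param roh_segments ROH tibble from [call_roh()].
#' @return `segments` with an added `roh_coverage` column in `[0, 1]`.
#' @export
roh_coverage <- function(segments, roh_segments) {
  cov <- vapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    r <- roh_segments[roh_segments$chrom == seg$chrom, ]
    if (nrow(r) == 0) return(0)
    q <- IRanges::IRanges(start = seg$start, end = seg$end)
    s <- IRanges::reduce(IRanges::IRanges(start = r$start, end = r$end))
    hit <- IRanges::intersect(q, s)
    sum(IRanges::width(hit)) / IRanges::width(q)
  }, numeric(1))
  dplyr::mutate(segments, roh_coverage = cov)
}
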