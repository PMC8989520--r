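#' Per-length read counts and normalised frequencies for one retron
#'
#' Tallies the number of trimmed reads at each RT-DNA length and normalises
#' by the total number of reads that contained RT-DNA of that retron (reads
#' per length / total RT-DNA reads).
#'
#' @param trimmed a `trimmed_reads` frame (classified or not); only
#'   non-discarded reads of `retron` are used. If no `retron` column is
#'   present all non-discarded reads are used.
#' @param retron retron label to profile; NULL = all reads in the frame.
#' @return object of class `length_profile`: `retron`, `counts` (named by
#'   length), `frequencies`, `total_rtdna_reads`, `modal_length`.
#' @export
length_profile <- function(trimmed, retron = NULL) {
  keep <- !trimmed$discarded
  if (!is.null(retron) && "retron" %in% names(trimmed))
    keep <- keep & trimmed$retron == retron
  lens <- nchar(trimmed$rtdna_sequence[keep])
  if (!length(lens))
    stop_empty("no reads to profile (empty profile)")
  counts <- table(lens)
  counts <- setNames(as.integer(counts), names(counts))
  freqs <- counts / sum(counts)
  structure(list(retron = if (is.null(retron)) "all" else retron,
                 counts = counts, frequencies = freqs,
                 total_rtdna_reads = sum(counts),
                 modal_length = as.integer(names(counts)[which.max(counts)])),
            class = "length_profile")
}

#' @export
print.length_profile <- function(x, ...) {
  cat(sprintf("<length_profile> %s: %d reads, %d distinct lengths\n",
              x$retron, x$total_rtdna_reads, length(x$counts)))
  cat(sprintf("  modal length %d (frequency %.3f)\n", x$modal_length,
              max(x$frequencies)))
  invisible(x)
}

#' @export
plot.length_profile <- function(x, ...) {
  lens <- as.integer(names(x$frequencies))
  graphics::barplot(as.numeric(x$frequencies), names.arg = lens,
                    xlab = "RT-DNA length (bases)",
                    ylab = "relative frequency",
                    main = sprintf("%s length distribution", x$retron), ...)
  invisible(x)
}

## Expand a length profile back into per-read lengths (for rank tests).
profile_lengths <- function(profile) {
  rep(as.integer(names(profile$counts)), times = profile$counts)
}

#' Ungapped placement of a trimmed read on the reference
#'
#' Places the read (and its reverse complement) at every offset of the
#' reference, takes the minimal-mismatch placement, and reports it when the
#' mismatch fraction is at most `max_mismatch_frac`. Ties are broken by the
#' lowest reference start, then by the sense strand. The RT-DNA is the
#' reverse complement of the template, so RT-DNA-sense reads typically place
#' on the antisense strand of the reference.
#'
#' @param trimmed a `trimmed_reads` frame (discarded reads are skipped).
#' @param ref an `ncrna_reference`.
#' @param max_mismatch_frac maximal tolerated mismatch fraction.
#' @return data.frame: `read_id`, `ref_start`, `ref_end` (1-based
#'   inclusive), `strand` (sense/antisense), `mismatches`, `aligned`.
#' @export
align_reads <- function(trimmed, ref, max_mismatch_frac = 0.1) {
  stopifnot(inherits(ref, "ncrna_reference"))
  refcodes <- utf8ToInt(ref$sequence)
  n <- nrow(trimmed)
  ref_start <- ref_end <- mismatches <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  aligned <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (trimmed$discarded[i]) next
    seq <- trimmed$rtdna_sequence[i]
    m <- nchar(seq)
    if (m > length(refcodes)) next
    cand <- list(sense = best_ungapped_offsets(refcodes, utf8ToInt(seq)),
                 antisense = best_ungapped_offsets(refcodes,
                                                   utf8ToInt(revcomp(seq))))
    best_mm <- vapply(cand, function(x) x$mismatches, numeric(1))
    ## choose overall minimum; for equal mismatch counts the lowest start
    ## wins, sense before antisense at identical starts
    ord <- order(best_mm,
                 vapply(cand, function(x) min(x$offsets), numeric(1)),
                 c(sense = 1L, antisense = 2L)[names(cand)])
    pick <- names(cand)[ord[1]]
    mm <- cand[[pick]]$mismatches
    if (mm / m > max_mismatch_frac) next
    st <- min(cand[[pick]]$offsets)
    ref_start[i] <- st
    ref_end[i] <- st + m - 1L
    strand[i] <- pick
    mismatches[i] <- mm
    aligned[i] <- TRUE
  }
  data.frame(read_id = trimmed$read_id, ref_start = ref_start,
             ref_end = ref_end, strand = strand, mismatches = mismatches,
             aligned = aligned, stringsAsFactors = FALSE)
}

#' Coverage and end-site histograms over the reference
#'
#' Coverage at each nucleotide is the number of aligned reads covering that
#' position divided by the total number of aligned RT-DNA reads. Alignment
#' boundaries are mapped to RT-DNA 5' and 3' termini via the reference
#' orientation flag: with the 5' terminus at the high coordinate (default),
#' `start_hist` counts `ref_end` positions and `end_hist` counts
#' `ref_start` positions.
#'
#' @param alignments frame from [align_reads()].
#' @param ref an `ncrna_reference`.
#' @return object of class `end_site_profile`: `coverage` (per-position
#'   fraction), `start_hist`, `end_hist` (named count vectors),
#'   `n_aligned`, `orientation_flag`.
#' @export
end_site_profile <- function(alignments, ref) {
  stopifnot(inherits(ref, "ncrna_reference"))
  aln <- alignments[alignments$aligned, , drop = FALSE]
  if (!nrow(aln)) stop_empty("no aligned reads (empty profile)")
  len <- nchar(ref$sequence)
  cov <- integer(len)
  ## difference-array accumulation of interval coverage
  for (i in seq_len(nrow(aln))) {
    cov[aln$ref_start[i]] <- cov[aln$ref_start[i]] + 1L
    if (aln$ref_end[i] < len)
      cov[aln$ref_end[i] + 1L] <- cov[aln$ref_end[i] + 1L] - 1L
  }
  cov <- cumsum(cov)
  hi_is_5p <- ref$rtdna_five_prime_at_high_coord
  p5 <- if (hi_is_5p) aln$ref_end else aln$ref_start
  p3 <- if (hi_is_5p) aln$ref_start else aln$ref_end
  tab <- function(v) {
    t <- table(v)
    setNames(as.integer(t), names(t))
  }
  structure(list(coverage = cov / nrow(aln), start_hist = tab(p5),
                 end_hist = tab(p3), n_aligned = nrow(aln),
                 orientation_flag = hi_is_5p),
            class = "end_site_profile")
}

#' @export
print.end_site_profile <- function(x, ...) {
  cat(sprintf("<end_site_profile> %d aligned reads\n", x$n_aligned))
  cat(sprintf("  RT-DNA 5' terminus at %s reference coordinate\n",
              if (x$orientation_flag) "high" else "low"))
  sp <- termination_span(x$end_hist)
  cat(sprintf("  majority 3'-termination span: %d base(s) from position %d\n",
              sp$width, sp$window_start))
  invisible(x)
}

#' @export
plot.end_site_profile <- function(x, ...) {
  graphics::plot(seq_along(x$coverage), 100 * x$coverage, type = "l",
                 xlab = "reference position", ylab = "% coverage",
                 ylim = c(0, 100), ...)
  invisible(x)
}

#' Majority termination span
#'
#' The smallest contiguous window of 3'-end positions whose summed frequency
#' strictly exceeds `mass` (default: a majority, 0.5). Ties are broken by the
#' leftmost window. A width of 1 means essentially all molecules terminate at
#' one site; tight termination corresponds to a span of at most ~3 bases.
#'
#' @param end_hist named count vector (names = reference positions), e.g.
#'   the `end_hist` field of an [end_site_profile()].
#' @param mass frequency threshold that the window must strictly exceed.
#' @return list with `window_start` (reference position) and `width`
#'   (bases).
#' @export
termination_span <- function(end_hist, mass = 0.5) {
  if (!length(end_hist)) stop_empty("empty end-site histogram")
  pos <- as.integer(names(end_hist))
  lo <- min(pos); hi <- max(pos)
  counts <- integer(hi - lo + 1L)
  counts[pos - lo + 1L] <- as.integer(end_hist)
  total <- sum(counts)
  csum <- cumsum(c(0L, counts))
  L <- length(counts)
  for (w in seq_len(L)) {
    sums <- csum[(w + 1L):(L + 1L)] - csum[1L:(L - w + 1L)]
    ok <- which(sums > mass * total)
    if (length(ok))
      return(list(window_start = lo + ok[1] - 1L, width = w))
  }
  list(window_start = lo, width = L)
}

#' Compare two conditions (e.g. with vs without RNase H1)
#'
#' Contrasts two length profiles by modal length and a Mann-Whitney test on
#' the underlying per-read lengths, optionally adding majority-span
#' statistics when end-site histograms are supplied.
#'
#' @param profile_a,profile_b `length_profile` objects.
#' @param end_hist_a,end_hist_b optional end-site histograms (named counts).
#' @param mass span threshold passed to [termination_span()].
#' @return list of class `condition_comparison`: modal lengths and their
#'   difference, the `mw_test`, and (if histograms given) the two spans.
#' @export
compare_conditions <- function(profile_a, profile_b,
                               end_hist_a = NULL, end_hist_b = NULL,
                               mass = 0.5) {
  stopifnot(inherits(profile_a, "length_profile"),
            inherits(profile_b, "length_profile"))
  mw <- mann_whitney_u(profile_lengths(profile_a),
                       profile_lengths(profile_b))
  out <- list(retron_a = profile_a$retron, retron_b = profile_b$retron,
              modal_length_a = profile_a$modal_length,
              modal_length_b = profile_b$modal_length,
              modal_difference = profile_b$modal_length -
                profile_a$modal_length,
              mann_whitney = mw)
  if (!is.null(end_hist_a)) out$span_a <- termination_span(end_hist_a, mass)
  if (!is.null(end_hist_b)) out$span_b <- termination_span(end_hist_b, mass)
  class(out) <- "condition_comparison"
  out
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s vs %s\n", x$retron_a, x$retron_b))
  cat(sprintf("  modal lengths: %d vs %d (difference %+d)\n",
              x$modal_length_a, x$modal_length_b, x$modal_difference))
  if (!is.null(x$span_a))
    cat(sprintf("  majority spans: %d vs %d bases\n", x$span_a$width,
                x$span_b$width))
  cat(sprintf("  Mann-Whitney U = %g, two-sided p = %.3g (%s)\n",
              x$mann_whitney$U, x$mann_whitney$p_two_sided,
              x$mann_whitney$method))
  invisible(x)
}

#' Write a length profile / end-site profile as TSV
#'
#' @param x a `length_profile` or `end_site_profile`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  if (inherits(x, "length_profile")) {
    df <- data.frame(length = as.integer(names(x$counts)),
                     count = as.integer(x$counts),
                     frequency = as.numeric(x$frequencies))
  } else if (inherits(x, "end_site_profile")) {
    len <- length(x$coverage)
    sh <- eh <- integer(len)
    sh[as.integer(names(x$start_hist))] <- as.integer(x$start_hist)
    eh[as.integer(names(x$end_hist))] <- as.integer(x$end_hist)
    df <- data.frame(position_1based = seq_len(len),
                     coverage_fraction = x$coverage,
                     start_count = sh, end_count = eh)
  } else stop_validation("unsupported profile type")
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
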