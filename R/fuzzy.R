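#' Fuzzy substring search under Hamming distance
#'
#' Finds every offset at which `pattern` matches a window of `haystack` with
#' at most `max_sub` substitutions (no indels). This is the matching rule
#' used for the 10-base retron probes; the full-oligo terminal-base search
#' uses edit distance instead (see [terminal_base_bias()]).
#'
#' @param haystack subject string (A/C/G/T/N; N never matches).
#' @param pattern query string, no longer than `haystack`.
#' @param max_sub maximum substitutions tolerated.
#' @return ascending integer vector of 1-based start offsets (possibly empty).
#' @examples
#' find_fuzzy_matches("ACGTACGT", "ACGT", 0)  # 1, 5
#' find_fuzzy_matches("ACGTT", "ACGA", 1)     # 1
#' @export
find_fuzzy_matches <- function(haystack, pattern, max_sub = 1L) {
  if (!nzchar(pattern)) stop_validation("empty pattern")
  n <- nchar(haystack)
  m <- nchar(pattern)
  if (m > n) return(integer(0))
  h <- utf8ToInt(haystack)
  p <- utf8ToInt(pattern)
  k <- n - m + 1L
  mm <- hamming_window_counts(h, p, k)
  which(mm <= max_sub)
}

## Per-offset mismatch counts of pattern `p` against all k windows of `h`,
## vectorised over offsets (one pass per pattern position). N (any case)
## counts as a mismatch on either side.
hamming_window_counts <- function(h, p, k) {
  m <- length(p)
  n_code <- utf8ToInt("N")
  mm <- integer(k)
  for (j in seq_len(m)) {
    hj <- h[j:(j + k - 1L)]
    mm <- mm + (hj != p[j] | hj == n_code | p[j] == n_code)
  }
  mm
}

## Minimal-mismatch placement of `read` over `refseq` at every offset;
## returns list(offsets, mismatches) restricted to the best count.
best_ungapped_offsets <- function(refcodes, readcodes) {
  k <- length(refcodes) - length(readcodes) + 1L
  if (k < 1L) return(NULL)
  mm <- hamming_window_counts(refcodes, readcodes, k)
  best <- min(mm)
  list(offsets = which(mm == best), mismatches = best)
}
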