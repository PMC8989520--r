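## Shared fixtures and independent brute-force oracles for the test suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Naive sliding-window Hamming scan: the oracle for find_fuzzy_matches().
bf_fuzzy <- function(haystack, pattern, max_sub) {
  n <- nchar(haystack); m <- nchar(pattern)
  hits <- integer(0)
  if (m > n) return(hits)
  for (i in seq_len(n - m + 1)) {
    win <- substr(haystack, i, i + m - 1)
    d <- sum(strsplit(win, "")[[1]] != strsplit(pattern, "")[[1]])
    if (d <= max_sub) hits <- c(hits, i)
  }
  hits
}

## Naive all-offset minimal-Hamming placement on both strands: the oracle
## for align_reads(). Tie-break: fewest mismatches, then lowest start, then
## sense strand.
bf_align <- function(read, refseq) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  best <- NULL
  for (strand in c("sense", "antisense")) {
    q <- if (strand == "sense") read else rc(read)
    m <- nchar(q)
    for (i in seq_len(nchar(refseq) - m + 1)) {
      d <- sum(strsplit(substr(refseq, i, i + m - 1), "")[[1]] !=
                 strsplit(q, "")[[1]])
      cand <- list(start = i, end = i + m - 1, strand = strand, mm = d)
      if (is.null(best) || d < best$mm ||
          (d == best$mm && i < best$start) ||
          (d == best$mm && i == best$start && strand == "sense" &&
             best$strand == "antisense"))
        best <- cand
    }
  }
  best
}

## Exact two-sided Mann-Whitney p by enumeration, computing U by direct
## pair-counting (not midranks) for each assignment of pooled values to A.
bf_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a); nB <- length(b); N <- nA + nB
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(a, b)
  mu <- nA * nB / 2
  sel <- utils::combn(N, nA)
  us <- apply(sel, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

## One synthetic retron system shared across tests.
syn_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_retron()
    cache
  }
})

## Broad 3'-end distribution restricted to non-T reference positions, so the
## RT-DNA/tail junction base is never an A and trimming is exact.
non_t_end_dist <- function(ref, sd = 4, halfwidth = 8) {
  site <- ref$canonical_term_site
  pos <- (site - halfwidth):(site + halfwidth)
  base <- strsplit(ref$sequence, "")[[1]][pos]
  pos <- pos[base != "T"]
  w <- stats::dnorm(pos, site, sd)
  dist_pmf(pos, w / sum(w))
}

## Total variation distance between the trimmed length distribution of
## classified reads and the ground-truth length distribution.
length_tv <- function(profile, truth) {
  lv <- sort(unique(c(truth$length, as.integer(names(profile$counts)))))
  tf <- table(factor(truth$length, levels = lv)) / nrow(truth)
  of <- table(factor(rep(as.integer(names(profile$counts)), profile$counts),
                     levels = lv)) / profile$total_rtdna_reads
  0.5 * sum(abs(of - tf))
}
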