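#' Mann-Whitney U comparison of two length distributions
#'
#' U is computed from midranks (ties share their average rank). For small
#' problems (`nA * nB <= 64`) the two-sided p-value is exact, by full
#' enumeration of all ways to assign the pooled observations to group A
#' (which conditions on the observed ties); otherwise a normal approximation
#' with tie correction and continuity correction is used. The method actually
#' applied is recorded in the result.
#'
#' @param lengths_a,lengths_b numeric vectors of per-read lengths (or any
#'   two samples to compare).
#' @return object of class `mw_test`: `U` (statistic for sample A),
#'   `p_two_sided`, `method` ("exact" or "normal-approximation"), `nA`,
#'   `nB`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(lengths_a, lengths_b) {
  a <- as.numeric(lengths_a); b <- as.numeric(lengths_b)
  if (!length(a) || !length(b))
    stop_validation("both samples must be non-empty")
  nA <- length(a); nB <- length(b); N <- nA + nB
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  mu <- nA * nB / 2
  if (nA * nB <= 64) {
    sel <- utils::combn(N, nA)
    csel <- colSums(matrix(r[sel], nrow = nA))
    Us <- csel - nA * (nA + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(nA * nB / 12 * ((N + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sigma
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  structure(list(U = U, p_two_sided = p, method = method, nA = nA, nB = nB),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s)\n", x$method))
  cat(sprintf("  U = %g (nA = %d, nB = %d), two-sided p = %.4g\n",
              x$U, x$nA, x$nB, x$p_two_sided))
  invisible(x)
}

## Best approximate occurrence of `stem` in `s`: first a substitution-only
## scan (covers the common case cheaply), then a windowed Levenshtein scan.
## Returns list(dist, end) for the best window, or NULL.
best_stem_match <- function(s, stem, max_edits) {
  Ls <- nchar(stem)
  hits <- find_fuzzy_matches(s, stem, max_edits)
  if (length(hits)) {
    h <- utf8ToInt(s); p <- utf8ToInt(stem)
    d <- vapply(hits, function(i) sum(h[i:(i + Ls - 1L)] != p), integer(1))
    best <- which.min(d)
    return(list(dist = d[best], end = hits[best] + Ls - 1L))
  }
  n <- nchar(s)
  if (n < Ls - max_edits) return(NULL)
  best <- NULL
  for (i in seq_len(n - (Ls - max_edits) + 1L)) {
    wmax <- min(Ls + max_edits, n - i + 1L)
    wlens <- seq.int(max(Ls - max_edits, 1L), wmax)
    if (!length(wlens)) next
    wins <- substring(s, i, i + wlens - 1L)
    d <- as.integer(adist(stem, wins))
    j <- which.min(d)
    if (d[j] <= max_edits && (is.null(best) || d[j] < best$dist))
      best <- list(dist = d[j], end = i + wlens[j] - 1L)
  }
  best
}

#' Terminal-base bias of the tailing chemistry
#'
#' Control for TdT tailing bias: reads from an equimolar spike-in of four
#' oligos identical except at their final base are matched against the
#' common oligo body with the terminal position wildcarded, allowing up to
#' `max_edits` edits (Levenshtein, mirroring a fuzzy full-oligo search).
#' Matched reads are binned by the observed base at the terminal position
#' and the bin counts are tested against the equimolar expectation with a
#' chi-square test. An unbiased prep yields near-equal fractions.
#'
#' @param reads data.frame with a `sequence` column (raw, untrimmed reads;
#'   both orientations are searched).
#' @param oligo_templates the 4 oligo sequences (equal length, differing
#'   only at the final base).
#' @param max_edits maximal edit distance for the body match (default 2).
#' @return object of class `terminal_base_tally`: `counts` (A/C/G/T),
#'   `n_matched`, `fractions`, `chi_square_p`.
#' @export
terminal_base_bias <- function(reads, oligo_templates, max_edits = 2L) {
  oligo_templates <- toupper(oligo_templates)
  L <- unique(nchar(oligo_templates))
  if (length(L) != 1L)
    stop_validation("oligo templates must share one length")
  stems <- unique(substr(oligo_templates, 1L, L - 1L))
  if (length(stems) != 1L)
    stop_validation("oligo templates must differ only at the terminal base")
  stem <- stems
  counts <- setNames(integer(4), DNA_BASES)
  for (s in toupper(reads$sequence)) {
    fwd <- best_stem_match(s, stem, max_edits)
    rc <- best_stem_match(revcomp(s), stem, max_edits)
    pick <- NULL; seq_used <- NULL
    if (!is.null(fwd) && (is.null(rc) || fwd$dist <= rc$dist)) {
      pick <- fwd; seq_used <- s
    } else if (!is.null(rc)) {
      pick <- rc; seq_used <- revcomp(s)
    }
    if (is.null(pick)) next
    if (pick$end >= nchar(seq_used)) next
    base <- substr(seq_used, pick$end + 1L, pick$end + 1L)
    if (base %in% DNA_BASES) counts[base] <- counts[base] + 1L
  }
  n <- sum(counts)
  if (n == 0L) stop_empty("no reads matched the oligo body")
  chisq_p <- suppressWarnings(
    chisq.test(counts, p = rep(0.25, 4))$p.value)
  structure(list(counts = counts, n_matched = n, fractions = counts / n,
                 chi_square_p = chisq_p),
            class = "terminal_base_tally")
}

#' @export
print.terminal_base_tally <- function(x, ...) {
  cat(sprintf("<terminal_base_tally> %d matched reads\n", x$n_matched))
  for (b in names(x$counts))
    cat(sprintf("  %s: %6d (%.3f)\n", b, x$counts[b], x$fractions[b]))
  cat(sprintf("  chi-square vs equimolar: p = %.3g\n", x$chi_square_p))
  invisible(x)
}
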