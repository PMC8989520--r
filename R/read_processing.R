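## Trimming and retron classification: raw reads -> canonical RT-DNA-sense
## sequences labelled by retron.

## Strip fuzzy adapter occurrences anchored at either read end. Tolerance:
## one substitution per 10 adapter bases for full matches; truncated
## adapters at the 3' read end are accepted as prefix matches of >= 8 bases.
strip_adapters <- function(seq, adapters, end_slack = 3L, prefix_min = 8L) {
  found <- FALSE
  for (ad in adapters) {
    m <- nchar(ad)
    if (m > nchar(seq)) next
    tol <- m %/% 10L
    hits <- find_fuzzy_matches(seq, ad, tol)
    lead <- hits[hits <= end_slack]
    if (length(lead)) {
      seq <- substr(seq, max(lead) + m, nchar(seq))
      found <- TRUE
      hits <- find_fuzzy_matches(seq, ad, tol)
    }
    trail <- hits[hits + m - 1L >= nchar(seq) - end_slack + 1L]
    if (length(trail)) {
      seq <- substr(seq, 1L, min(trail) - 1L)
      found <- TRUE
    }
  }
  ## truncated adapter prefix hanging off the 3' end
  repeat {
    cut <- FALSE
    for (ad in adapters) {
      m <- nchar(ad)
      kmax <- min(m - 1L, nchar(seq))
      if (kmax < prefix_min) next
      for (k in seq.int(kmax, prefix_min)) {
        tailseq <- substr(seq, nchar(seq) - k + 1L, nchar(seq))
        d <- sum(utf8ToInt(tailseq) != utf8ToInt(substr(ad, 1L, k)))
        if (d <= k %/% 10L) {
          seq <- substr(seq, 1L, nchar(seq) - k)
          found <- TRUE; cut <- TRUE
          break
        }
      }
      if (cut) break
    }
    if (!cut) break
  }
  list(seq = seq, found = found)
}

#' Trim adapters and poly-A tails, canonicalising reads to RT-DNA sense
#'
#' Reproduces the read clean-up of the sequencing pipeline: fuzzy adapter
#' occurrences (at most one substitution per 10 adapter bases; truncated
#' adapters at the read 3' end accepted from 8 bases) are removed from both
#' ends, then the maximal terminal A run of at least `polyA_min_run` bases
#' (the TdT tail) is trimmed. Reads carrying the second-strand image -- a
#' leading T run after adapter removal -- are reverse-complemented into
#' RT-DNA sense. A template-encoded terminal A adjacent to the tail is
#' necessarily absorbed into the tail (documented limitation of maximal-run
#' trimming).
#'
#' A single substitution error inside the tail is bridged (the run continues
#' across it) when at least four tail bases follow, so sequencing errors in
#' the tail do not leave residual tail bases on the molecule.
#'
#' @param reads data.frame with `read_id`, `sequence` (and optionally
#'   `quality`), e.g. from [read_fastq()].
#' @param adapters character vector of adapter sequences; their reverse
#'   complements are searched too.
#' @param polyA_min_run minimal terminal A (or leading T) run treated as a
#'   tail; shorter runs are considered template-encoded.
#' @param min_length reads shorter than this after trimming are flagged
#'   `discarded`.
#' @return data.frame of class `trimmed_reads`: `read_id`,
#'   `rtdna_sequence`, `trimmed_tail_len`, `adapter_found`, `orientation`
#'   (sense/antisense), `discarded`.
#' @export
trim_reads <- function(reads,
                       adapters = c("AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                                    "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"),
                       polyA_min_run = 5L, min_length = 15L) {
  if (!nrow(reads)) stop_empty("no reads to trim")
  adapters <- toupper(adapters)
  all_adapters <- unique(c(adapters, revcomp(adapters)))
  out <- lapply(reads$sequence, function(s) {
    st <- strip_adapters(toupper(s), all_adapters)
    seq <- st$seq
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    ra <- tolerant_run_length(rev(chars), "A")
    rt <- tolerant_run_length(chars, "T")
    tail_len <- 0L
    orientation <- "sense"
    if (ra >= polyA_min_run && ra >= rt) {
      tail_len <- ra
      seq <- substr(seq, 1L, nchar(seq) - ra)
    } else if (rt >= polyA_min_run) {
      tail_len <- rt
      seq <- revcomp(substr(seq, rt + 1L, nchar(seq)))
      orientation <- "antisense"
    }
    ## iterate the 3'-tail strip to a fixpoint: a tail with several
    ## substitution errors can exceed one pass's skip budget, and repeating
    ## the same rule until stable makes trimming idempotent
    while (tail_len > 0L) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      ra <- tolerant_run_length(rev(chars), "A")
      if (ra < polyA_min_run) break
      tail_len <- tail_len + ra
      seq <- substr(seq, 1L, nchar(seq) - ra)
    }
    list(seq = seq, tail = tail_len, found = st$found, orient = orientation)
  })
  res <- data.frame(
    read_id = reads$read_id,
    rtdna_sequence = vapply(out, `[[`, character(1), "seq"),
    trimmed_tail_len = vapply(out, `[[`, integer(1), "tail"),
    adapter_found = vapply(out, `[[`, logical(1), "found"),
    orientation = vapply(out, `[[`, character(1), "orient"),
    stringsAsFactors = FALSE)
  res$discarded <- nchar(res$rtdna_sequence) < min_length
  class(res) <- c("trimmed_reads", "data.frame")
  res
}

## Does any probe of `ps` hit `codes` (utf8 codes of a sequence) or
## `codes_rc` with at most ps$max_mismatches substitutions?
probeset_hits <- function(ps, seq, seq_rc) {
  for (p in ps$probes) {
    if (length(find_fuzzy_matches(seq, p, ps$max_mismatches)) ||
        length(find_fuzzy_matches(seq_rc, p, ps$max_mismatches)))
      return(TRUE)
  }
  FALSE
}

#' Assign trimmed reads to retrons by fuzzy 10-mer probes
#'
#' A read is assigned to the unique retron for which at least one of the
#' three 10-base probes occurs (on either strand) with at most the probe
#' set's allowed substitutions; reads matching no retron are `unassigned`,
#' reads matching more than one are `ambiguous` and excluded from profiles.
#' Classification is orientation-invariant by construction.
#'
#' @param trimmed a `trimmed_reads` frame from [trim_reads()].
#' @param probesets list of [probe_set()] objects.
#' @return `trimmed` with a `retron` column added.
#' @export
classify_reads <- function(trimmed, probesets) {
  if (inherits(probesets, "probe_set")) probesets <- list(probesets)
  labels <- vapply(seq_len(nrow(trimmed)), function(i) {
    if (trimmed$discarded[i]) return("unassigned")
    seq <- trimmed$rtdna_sequence[i]
    seq_rc <- revcomp(seq)
    hit <- vapply(probesets, probeset_hits, logical(1), seq = seq,
                  seq_rc = seq_rc)
    if (sum(hit) == 1L) probesets[[which(hit)]]$retron
    else if (sum(hit) == 0L) "unassigned"
    else "ambiguous"
  }, character(1))
  trimmed$retron <- labels
  trimmed
}

#' Summarise read-processing QC
#'
#' @param classified output of [classify_reads()].
#' @return list of counts: `reads_in`, `adapter_found`, `discarded`,
#'   `classified`, `unassigned`, `ambiguous` (conserving
#'   `reads_in = classified + unassigned + ambiguous + discarded`, with
#'   discarded reads counted only under `discarded`).
#' @export
qc_summary <- function(classified) {
  keep <- !classified$discarded
  lab <- classified$retron[keep]
  list(reads_in = nrow(classified),
       adapter_found = sum(classified$adapter_found),
       discarded = sum(classified$discarded),
       classified = sum(!lab %in% c("unassigned", "ambiguous")),
       unassigned = sum(lab == "unassigned"),
       ambiguous = sum(lab == "ambiguous"))
}
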