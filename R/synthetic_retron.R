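#' Deterministic synthetic retron for end-to-end runs
#'
#' Builds a labelled, fully synthetic retron system: an annotated ncRNA
#' reference (a1 / msr / msd / a2 regions, canonical termination site), the
#' matching three-probe set drawn from the expected RT-DNA, and the 5'
#' initiation site. The sequence is sampled without homopolymer runs of four
#' or more bases (so tail trimming cannot collide with template-encoded
#' runs) and without T bases across the termination window (canonical site
#' +/- 12), so wherever the 3' end lands under either termination preset the
#' RT-DNA/tail junction base is not an A and round-trip recovery is exact.
#'
#' The default geometry mirrors a retron whose RT-DNA is 85 bases, the
#' canonical Eco1-like product; `rtdna_length = 45` gives an Eco6-like
#' product.
#'
#' @param name retron identifier.
#' @param rtdna_length length (bases) of the canonical RT-DNA product.
#' @param seed integer seed making the whole system reproducible.
#' @return list with `ref` (an `ncrna_reference`), `probes` (a
#'   `probe_set`), `start5` (RT-DNA 5'-terminus reference position), and
#'   `rtdna` (the canonical RT-DNA sequence).
#' @export
synthetic_retron <- function(name = "synEco1", rtdna_length = 85L,
                             seed = 42L) {
  if (rtdna_length < 30L)
    stop_config("rtdna_length must be >= 30 to fit three 10-base probes")
  msd_start <- 83L
  msd_end <- msd_start + rtdna_length + 2L
  total <- msd_end + 20L
  start5 <- msd_end - 1L
  term <- start5 - rtdna_length + 1L
  term_window <- max(1L, term - 12L):min(total, term + 12L)
  seq <- with_seed(seed, {
    chars <- character(total)
    for (i in seq_len(total)) {
      cand <- DNA_BASES
      if (i %in% term_window) cand <- setdiff(cand, "T")
      if (i >= 4L && chars[i - 1L] == chars[i - 2L] &&
          chars[i - 2L] == chars[i - 3L])
        cand <- setdiff(cand, chars[i - 1L])
      chars[i] <- sample(cand, 1L)
    }
    chars
  })
  sequence <- paste(seq, collapse = "")
  ref <- ncrna_reference(
    name = name, sequence = sequence,
    regions = data.frame(
      name = c("a1", "msr", "msd", "a2"),
      start = c(1L, 13L, msd_start, msd_end + 1L),
      end = c(12L, msd_start - 1L, msd_end, msd_end + 12L)),
    canonical_term_site = term,
    branch_g_pos = 20L,
    rtdna_five_prime_at_high_coord = TRUE)
  rtdna <- revcomp(substr(sequence, term, start5))
  offs <- c(1L, (rtdna_length - 10L) %/% 2L + 1L, rtdna_length - 9L)
  probes <- probe_set(name, substring(rtdna, offs, offs + 9L))
  list(ref = ref, probes = probes, start5 = start5, rtdna = rtdna)
}
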