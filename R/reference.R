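#' Construct an annotated retron ncRNA reference
#'
#' Bundles the retron non-coding RNA sequence (written in the DNA alphabet,
#' 5'->3') with its canonical region annotation (`a1`, `msr`, `msd`, `a2`),
#' the canonical RT-DNA termination site, and the branching guanosine
#' position. Coordinates are 1-based inclusive throughout the package; the
#' on-disk annotation format is BED-like (0-based half-open) and converted on
#' load/write.
#'
#' The RT-DNA is the reverse complement of (part of) the msd region, so its
#' 5' and 3' termini map back onto reference coordinates. By default the
#' RT-DNA 5' terminus sits at the *higher* reference coordinate (the reverse
#' transcriptase reads its template 3'->5'), controlled by
#' `rtdna_five_prime_at_high_coord`.
#'
#' @param name identifier for the retron.
#' @param sequence DNA string (A/C/G/T only; degenerate bases are rejected).
#' @param regions data.frame with columns `name`, `start`, `end` (1-based
#'   inclusive) naming at least the `msd` region.
#' @param canonical_term_site optional reference position of the canonical
#'   RT-DNA 3' end; must fall inside `msd`.
#' @param branch_g_pos optional reference position of the branching guanosine
#'   carrying the 2'-5' linkage.
#' @param rtdna_five_prime_at_high_coord logical orientation flag (see above).
#' @return an object of class `ncrna_reference`.
#' @export
ncrna_reference <- function(name, sequence, regions,
                            canonical_term_site = NULL,
                            branch_g_pos = NULL,
                            rtdna_five_prime_at_high_coord = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (!is_dna(sequence))
    stop_validation("reference sequence must contain only A/C/G/T")
  len <- nchar(sequence)
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  need <- c("name", "start", "end")
  if (!all(need %in% names(regions)))
    stop_config("region table needs columns name/start/end")
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (any(regions$start < 1L | regions$end > len))
    stop_validation("region interval outside the reference sequence")
  if (any(regions$end < regions$start))
    stop_validation("empty or inverted region interval")
  if (all(c("msr", "msd") %in% regions$name)) {
    msr <- regions[regions$name == "msr", ][1, ]
    msd <- regions[regions$name == "msd", ][1, ]
    if (msr$start <= msd$end && msd$start <= msr$end)
      stop_validation("msr and msd regions overlap")
  }
  if (!is.null(canonical_term_site)) {
    canonical_term_site <- as.integer(canonical_term_site)
    if (!"msd" %in% regions$name)
      stop_config("canonical_term_site given but no msd region annotated")
    msd <- regions[regions$name == "msd", ][1, ]
    if (canonical_term_site < msd$start || canonical_term_site > msd$end)
      stop_validation("canonical_term_site lies outside the msd region")
  }
  if (!is.null(branch_g_pos)) {
    branch_g_pos <- as.integer(branch_g_pos)
    if (branch_g_pos < 1L || branch_g_pos > len)
      stop_validation("branch_g_pos outside the reference")
  }
  structure(list(name = as.character(name), sequence = sequence,
                 regions = regions[, need],
                 canonical_term_site = canonical_term_site,
                 branch_g_pos = branch_g_pos,
                 rtdna_five_prime_at_high_coord =
                   isTRUE(rtdna_five_prime_at_high_coord)),
            class = "ncrna_reference")
}

#' @export
print.ncrna_reference <- function(x, ...) {
  cat(sprintf("<ncrna_reference> %s (%d nt)\n", x$name, nchar(x$sequence)))
  for (i in seq_len(nrow(x$regions)))
    cat(sprintf("  %-4s %4d-%4d\n", x$regions$name[i], x$regions$start[i],
                x$regions$end[i]))
  if (!is.null(x$canonical_term_site))
    cat(sprintf("  canonical RT-DNA 3' end: position %d\n",
                x$canonical_term_site))
  cat(sprintf("  RT-DNA 5' terminus at %s reference coordinate\n",
              if (x$rtdna_five_prime_at_high_coord) "high" else "low"))
  invisible(x)
}

region <- function(ref, name) {
  r <- ref$regions[ref$regions$name == name, ]
  if (nrow(r) == 0L) stop_config(sprintf("region '%s' not annotated", name))
  r[1, ]
}

region_seq <- function(ref, name) {
  r <- region(ref, name)
  substr(ref$sequence, r$start, r$end)
}

#' Load a reference from FASTA plus a BED-like region annotation
#'
#' @param fasta_path FASTA file holding exactly one record.
#' @param annotation_path tab-separated annotation: columns name, start, end
#'   in BED convention (0-based half-open), plus optional single-row entries
#'   named `canonical_term_site` and `branch_g_pos` whose `start` column holds
#'   the 0-based position.
#' @param rtdna_five_prime_at_high_coord orientation flag (see
#'   [ncrna_reference()]).
#' @return an `ncrna_reference`.
#' @export
load_reference <- function(fasta_path, annotation_path,
                           rtdna_five_prime_at_high_coord = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L)
    stop_config("reference FASTA must contain exactly one record")
  ann <- utils::read.table(annotation_path, header = FALSE, sep = "\t",
                           col.names = c("name", "start", "end"),
                           stringsAsFactors = FALSE)
  term <- ann[ann$name == "canonical_term_site", ]
  branch <- ann[ann$name == "branch_g_pos", ]
  reg <- ann[!ann$name %in% c("canonical_term_site", "branch_g_pos"), ]
  ncrna_reference(
    name = sub("\\s.*$", "", names(seqs)[1]),
    sequence = as.character(seqs[[1]]),
    regions = data.frame(name = reg$name, start = reg$start + 1L,
                         end = reg$end, stringsAsFactors = FALSE),
    canonical_term_site = if (nrow(term)) term$start[1] + 1L else NULL,
    branch_g_pos = if (nrow(branch)) branch$start[1] + 1L else NULL,
    rtdna_five_prime_at_high_coord = rtdna_five_prime_at_high_coord)
}

#' Write a reference back to FASTA + BED-like annotation
#'
#' Inverse of [load_reference()]: `load_reference(write_reference(ref))`
#' reproduces `ref`.
#'
#' @param ref an `ncrna_reference`.
#' @param fasta_path,annotation_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta_path, annotation_path) {
  stopifnot(inherits(ref, "ncrna_reference"))
  seqs <- Biostrings::DNAStringSet(ref$sequence)
  names(seqs) <- ref$name
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- data.frame(name = ref$regions$name,
                    start = ref$regions$start - 1L,
                    end = ref$regions$end, stringsAsFactors = FALSE)
  if (!is.null(ref$canonical_term_site))
    ann <- rbind(ann, data.frame(name = "canonical_term_site",
                                 start = ref$canonical_term_site - 1L,
                                 end = ref$canonical_term_site))
  if (!is.null(ref$branch_g_pos))
    ann <- rbind(ann, data.frame(name = "branch_g_pos",
                                 start = ref$branch_g_pos - 1L,
                                 end = ref$branch_g_pos))
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta_path, annotation = annotation_path))
}

#' Retron-specific probe set
#'
#' Three 10-base sequences present along the RT-DNA of one retron, used to
#' classify reads by fuzzy matching with at most `max_mismatches`
#' substitutions.
#'
#' @param retron retron identifier.
#' @param probes character vector of exactly three 10-base A/C/G/T strings.
#' @param max_mismatches allowed substitutions per probe match (default 1).
#' @return an object of class `probe_set`.
#' @export
probe_set <- function(retron, probes, max_mismatches = 1L) {
  probes <- toupper(as.character(probes))
  if (length(probes) != 3L)
    stop_validation("a probe set holds exactly three probes")
  if (any(nchar(probes) != 10L))
    stop_validation("probes must be exactly 10 bases long")
  if (!is_dna(probes))
    stop_validation("probes must contain only A/C/G/T")
  structure(list(retron = as.character(retron), probes = probes,
                 max_mismatches = as.integer(max_mismatches)),
            class = "probe_set")
}

#' Read probe sets from a YAML configuration
#'
#' Expected layout: a top-level `probe_sets` list whose entries have fields
#' `retron`, `probes` (three 10-mers) and optional `max_mismatches`.
#'
#' @param path YAML file.
#' @return list of `probe_set` objects.
#' @export
load_probe_sets <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$probe_sets)) cfg$probe_sets else cfg
  lapply(entries, function(e) {
    probe_set(e$retron, unlist(e$probes),
              if (is.null(e$max_mismatches)) 1L else e$max_mismatches)
  })
}

#' Locate probes within the expected RT-DNA of a reference
#'
#' Each probe should occur (exactly) in the reverse complement of the msd
#' region, i.e. in the RT-DNA sequence itself. Returns, per probe, the
#' 1-based offsets of all occurrences within that reverse complement; a probe
#' absent everywhere triggers a warning and yields an empty vector.
#'
#' @param probes a `probe_set`.
#' @param ref an `ncrna_reference` with an annotated msd region.
#' @return named list of integer offset vectors, one per probe.
#' @export
validate_probes <- function(probes, ref) {
  stopifnot(inherits(probes, "probe_set"), inherits(ref, "ncrna_reference"))
  rtdna <- revcomp(region_seq(ref, "msd"))
  out <- lapply(probes$probes, function(p) {
    if (nchar(p) != 10L) stop_validation("probe of length != 10")
    find_fuzzy_matches(rtdna, p, 0L)
  })
  names(out) <- probes$probes
  missing <- vapply(out, length, integer(1)) == 0L
  if (any(missing))
    warning(sprintf("probe(s) absent from RT-DNA of %s: %s", ref$name,
                    paste(names(out)[missing], collapse = ", ")))
  out
}
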