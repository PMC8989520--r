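#' Discrete distributions over reference positions
#'
#' Termination and initiation of RT-DNA synthesis are modelled as discrete
#' distributions over reference coordinates. `dist_point()` places all mass
#' on one position (tight termination, as seen with RNase H1 present);
#' `dist_discretized_normal()` spreads mass over integer positions with
#' normal weights (heterogeneous termination, as seen without RNase H1);
#' `dist_pmf()` takes an explicit mass function.
#'
#' @param pos,mean,sd,positions,probs distribution parameters; `positions`
#'   are 1-based reference coordinates.
#' @param support integer range (inclusive) to which a discretized normal is
#'   truncated before renormalisation.
#' @return an object of class `position_dist` with fields `positions`,
#'   `probs`.
#' @export
dist_point <- function(pos) {
  dist_pmf(as.integer(pos), 1)
}

#' @rdname dist_point
#' @export
dist_discretized_normal <- function(mean, sd, support = NULL) {
  if (sd <= 0) stop_config("sd must be positive; use dist_point() for sd = 0")
  lo <- floor(mean - 6 * sd); hi <- ceiling(mean + 6 * sd)
  if (!is.null(support)) {
    lo <- max(lo, support[1]); hi <- min(hi, support[2])
  }
  pos <- seq.int(lo, hi)
  w <- dnorm(pos, mean, sd)
  dist_pmf(pos, w / sum(w))
}

#' @rdname dist_point
#' @export
dist_pmf <- function(positions, probs) {
  positions <- as.integer(positions)
  probs <- as.numeric(probs)
  if (length(positions) != length(probs) || !length(positions))
    stop_config("positions and probs must be non-empty and equal length")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop_config("probability masses must be non-negative and sum to 1")
  structure(list(positions = positions, probs = probs),
            class = "position_dist")
}

sample_dist <- function(d, n) {
  stopifnot(inherits(d, "position_dist"))
  if (length(d$positions) == 1L) rep(d$positions, n)
  else sample(d$positions, n, replace = TRUE, prob = d$probs)
}

#' Molecule-sampling configuration
#'
#' @param n_molecules number of RT-DNA molecules to draw.
#' @param start_dist `position_dist` for the RT-DNA 5' terminus (reference
#'   coordinate).
#' @param end_dist `position_dist` for the RT-DNA 3' terminus.
#' @param seed integer RNG seed.
#' @return a `molecule_config` list.
#' @export
molecule_config <- function(n_molecules, start_dist, end_dist, seed) {
  stopifnot(inherits(start_dist, "position_dist"),
            inherits(end_dist, "position_dist"))
  if (n_molecules < 1L) stop_config("n_molecules must be >= 1")
  structure(list(n_molecules = as.integer(n_molecules),
                 start_dist = start_dist, end_dist = end_dist,
                 seed = as.integer(seed)),
            class = "molecule_config")
}

#' Termination presets emulating the RNase H1 contrast
#'
#' `"+rnaseH1"` puts all 3'-end mass on the canonical termination site
#' (tight termination). `"-rnaseH1"` spreads the 3' end as a discretized
#' normal (default sd 4 bases) whose centre is displaced one sd beyond the
#' canonical site toward the template 5' end: without RNase H1 the reverse
#' transcriptase runs past the normal stop, producing longer, heterogeneous
#' products.
#'
#' @param ref `ncrna_reference` with `canonical_term_site` set.
#' @param mode `"+rnaseH1"` or `"-rnaseH1"`.
#' @param sd spread (bases) of the broad preset; also sets its displacement.
#' @return a `position_dist` for use as `end_dist`.
#' @export
termination_preset <- function(ref, mode = c("+rnaseH1", "-rnaseH1"), sd = 4) {
  mode <- match.arg(mode)
  if (is.null(ref$canonical_term_site))
    stop_config("reference has no canonical_term_site")
  site <- ref$canonical_term_site
  if (mode == "+rnaseH1") return(dist_point(site))
  shift <- if (ref$rtdna_five_prime_at_high_coord) -sd else sd
  dist_discretized_normal(site + shift, sd,
                          support = c(1L, nchar(ref$sequence)))
}

#' Simulate RT-DNA molecules from a reference
#'
#' Draws 5' and 3' termini from the configured distributions and emits, for
#' each molecule, the reverse complement of the template slice between them
#' (or the forward slice when `rtdna_five_prime_at_high_coord` is FALSE).
#' Deterministic under the configured seed.
#'
#' @param cfg a `molecule_config`.
#' @param ref an `ncrna_reference`.
#' @return data.frame with columns `molecule_id`, `sequence`, `retron`,
#'   `start5` (5'-terminus reference position), `end3` (3'-terminus
#'   position), `length`.
#' @export
simulate_molecules <- function(cfg, ref) {
  stopifnot(inherits(cfg, "molecule_config"), inherits(ref, "ncrna_reference"))
  len <- nchar(ref$sequence)
  for (d in list(cfg$start_dist, cfg$end_dist))
    if (any(d$positions < 1L | d$positions > len))
      stop_config("distribution mass outside the reference")
  with_seed(cfg$seed, {
    start5 <- sample_dist(cfg$start_dist, cfg$n_molecules)
    end3 <- sample_dist(cfg$end_dist, cfg$n_molecules)
    hi_is_5p <- ref$rtdna_five_prime_at_high_coord
    lo <- if (hi_is_5p) end3 else start5
    hi <- if (hi_is_5p) start5 else end3
    if (any(lo > hi))
      stop_config("sampled termini define an empty molecule (5'/3' order)")
    slice <- substring(ref$sequence, lo, hi)
    seqs <- if (hi_is_5p) revcomp(slice) else slice
    data.frame(molecule_id = sprintf("mol%06d", seq_len(cfg$n_molecules)),
               sequence = seqs, retron = ref$name, start5 = start5,
               end3 = end3, length = hi - lo + 1L,
               stringsAsFactors = FALSE)
  })
}

#' Library-chemistry configuration
#'
#' Emulates the sequencing prep: the single-stranded RT-DNA 3' end is
#' poly-A tailed by TdT (aiming at ~25 adenosines), a second strand is
#' primed with an adapter + nine thymines + non-T (V) anchor, and adapters
#' are ligated, so a sense read is
#' `adapter_a + molecule + poly(A) + adapter_b` and an antisense read is its
#' reverse complement (poly-T run in front of the molecule complement).
#'
#' @param adapter_a,adapter_b adapter sequences flanking the insert.
#' @param tail_dist `position_dist`-style distribution over tail lengths;
#'   default discretized normal, mean 25, sd 5, floored at 5.
#' @param anchor second-strand primer anchor (nine T's + V), recorded for
#'   provenance; the antisense read image carries the full tail complement.
#' @param substitution_error_rate per-base substitution probability.
#' @param orientation_mix named fractions `c(sense=, antisense=)`, summing
#'   to 1.
#' @param read_length emitted read length (5' truncation); NULL = full
#'   construct.
#' @param seed integer RNG seed.
#' @return a `library_config` list.
#' @export
library_config <- function(adapter_a = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                           adapter_b = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT",
                           tail_dist = NULL,
                           anchor = "TTTTTTTTTV",
                           substitution_error_rate = 0,
                           orientation_mix = c(sense = 0.5, antisense = 0.5),
                           read_length = NULL,
                           seed = 1L) {
  if (is.null(tail_dist)) {
    tail_dist <- dist_discretized_normal(25, 5, support = c(5L, 60L))
  }
  if (substitution_error_rate < 0 || substitution_error_rate > 1)
    stop_config("substitution_error_rate must lie in [0, 1]")
  if (abs(sum(orientation_mix) - 1) > 1e-9 ||
      !all(c("sense", "antisense") %in% names(orientation_mix)))
    stop_config("orientation_mix needs sense/antisense fractions summing to 1")
  if (!is.null(read_length) &&
      read_length <= max(nchar(adapter_a), nchar(adapter_b)))
    stop_config("read_length shorter than the adapters")
  structure(list(adapter_a = toupper(adapter_a),
                 adapter_b = toupper(adapter_b),
                 tail_dist = tail_dist, anchor = anchor,
                 substitution_error_rate = substitution_error_rate,
                 orientation_mix = orientation_mix,
                 read_length = read_length, seed = as.integer(seed)),
            class = "library_config")
}

apply_substitutions <- function(seqs, rate) {
  if (rate == 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in pos) {
      chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a sequencing library from RT-DNA molecules
#'
#' @param molecules data.frame from [simulate_molecules()] (or any frame with
#'   `molecule_id`, `sequence`, `retron`, `start5`, `end3`, `length`).
#' @param cfg a `library_config`.
#' @return list with `reads` (data.frame read_id/sequence/quality) and
#'   `truth` (per-read ground truth: retron, start5, end3, length,
#'   orientation, tail_len).
#' @export
simulate_library <- function(molecules, cfg) {
  stopifnot(inherits(cfg, "library_config"))
  if (!nrow(molecules)) stop_empty("no molecules to build a library from")
  with_seed(cfg$seed, {
    n <- nrow(molecules)
    tails <- sample_dist(cfg$tail_dist, n)
    orient <- sample(c("sense", "antisense"), n, replace = TRUE,
                     prob = cfg$orientation_mix[c("sense", "antisense")])
    sense <- paste0(cfg$adapter_a, molecules$sequence,
                    strrep("A", tails), cfg$adapter_b)
    seqs <- ifelse(orient == "antisense", revcomp(sense), sense)
    seqs <- apply_substitutions(seqs, cfg$substitution_error_rate)
    if (!is.null(cfg$read_length))
      seqs <- substr(seqs, 1L, cfg$read_length)
    reads <- data.frame(read_id = sprintf("read%06d", seq_len(n)),
                        sequence = seqs,
                        quality = strrep("I", nchar(seqs)),
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = reads$read_id,
                        retron = molecules$retron,
                        start5 = molecules$start5, end3 = molecules$end3,
                        length = molecules$length, orientation = orient,
                        tail_len = tails, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Simulate an equimolar oligo spike-in for the terminal-base bias control
#'
#' Four oligos identical except at their final base are mixed (by default at
#' equal proportion), optionally skewed by a per-terminal-base tailing
#' efficiency (emission probability proportional to proportion x
#' efficiency, renormalised), and passed through the library chemistry.
#'
#' @param oligos character vector of 4 sequences differing only at the final
#'   base.
#' @param n_reads number of reads to emit.
#' @param proportions 4 mixing proportions summing to 1.
#' @param bias optional named numeric efficiency per terminal base
#'   (e.g. `c(A = 2, C = 1, G = 1, T = 1)`).
#' @param seed integer RNG seed.
#' @param library a `library_config`; its seed is derived from `seed`.
#' @return list with `reads`, `truth` (truth carries `terminal_base`).
#' @export
simulate_oligo_spike <- function(oligos, n_reads,
                                 proportions = rep(0.25, 4), bias = NULL,
                                 seed = 1L, library = library_config()) {
  oligos <- toupper(oligos)
  if (length(oligos) != 4L) stop_config("exactly four oligos are required")
  L <- unique(nchar(oligos))
  if (length(L) != 1L) stop_validation("oligos must share one length")
  stems <- substr(oligos, 1L, L - 1L)
  if (length(unique(stems)) != 1L)
    stop_validation("oligos must be identical except at the terminal base")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_config("proportions must sum to 1")
  term <- substr(oligos, L, L)
  w <- proportions
  if (!is.null(bias)) {
    eff <- bias[term]
    if (any(is.na(eff))) stop_config("bias must name each terminal base")
    w <- w * as.numeric(eff)
  }
  w <- w / sum(w)
  idx <- with_seed(seed, sample.int(4L, n_reads, replace = TRUE, prob = w))
  molecules <- data.frame(molecule_id = sprintf("oligo%06d", seq_len(n_reads)),
                          sequence = oligos[idx],
                          retron = sprintf("oligo_%s", term[idx]),
                          start5 = NA_integer_, end3 = NA_integer_,
                          length = L, stringsAsFactors = FALSE)
  library$seed <- as.integer((seed * 7919L + 13L) %% .Machine$integer.max)
  out <- simulate_library(molecules, library)
  out$truth$terminal_base <- term[idx]
  out
}

#' Simulate phenotype tables (OD600 growth and plaque counts)
#'
#' Growth records get `od600 = mean x lognormal(cv)` noise (unit mean);
#' plaque records get Poisson counting noise around the design mean. With
#' `noise_cv = 0` the design means are returned exactly (plaque means must
#' then be integral to be representable as counts).
#'
#' @param design data.frame. For growth rows: columns `strain`, `construct`,
#'   `induced`, `od600_mean`. For plaque rows: `strain`, `construct`,
#'   `phage`, `pfu_mean` (expected plaque count), `lysate_volume_ul`,
#'   `dilution_factor`.
#' @param noise_cv coefficient of variation of the lognormal OD noise.
#' @param n_replicates biological replicates per design row.
#' @param seed integer RNG seed.
#' @return data.frame: the design expanded by `replicate` plus an `od600` or
#'   `plaque_count` column.
#' @export
simulate_phenotypes <- function(design, noise_cv = 0.1, n_replicates = 3L,
                                seed = 1L) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  is_od <- "od600_mean" %in% names(design)
  is_pfu <- "pfu_mean" %in% names(design)
  if (!xor(is_od, is_pfu))
    stop_config("design must have exactly one of od600_mean / pfu_mean")
  mean_col <- if (is_od) design$od600_mean else design$pfu_mean
  if (any(mean_col < 0)) stop_config("design means must be non-negative")
  out <- design[rep(seq_len(nrow(design)), each = n_replicates), ,
                drop = FALSE]
  out$replicate <- rep(seq_len(n_replicates), times = nrow(design))
  mu <- rep(mean_col, each = n_replicates)
  with_seed(seed, {
    if (is_od) {
      if (noise_cv == 0) {
        out$od600 <- mu
      } else {
        sdlog <- sqrt(log(1 + noise_cv^2))
        out$od600 <- mu * rlnorm(length(mu), meanlog = -sdlog^2 / 2,
                                 sdlog = sdlog)
      }
    } else {
      out$plaque_count <- if (noise_cv == 0) as.integer(round(mu))
                          else rpois(length(mu), mu)
    }
  })
  rownames(out) <- NULL
  out
}

#' Read and write FASTQ read tables
#'
#' Thin wrappers around Biostrings' quality-scaled string sets; reading is
#' gzip-transparent.
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path FASTQ file path.
#' @return `read_fastq()` returns a reads data.frame; `write_fastq()` its
#'   path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$quality)
  qss <- Biostrings::QualityScaledDNAStringSet(ss, q)
  ## Biostrings warns that (empty) metadata columns are dropped on write;
  ## nothing of ours is lost
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(qss, path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop_empty(sprintf("FASTQ '%s' is missing or empty", path))
  qss <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!length(qss)) stop_empty(sprintf("FASTQ '%s' holds no reads", path))
  data.frame(read_id = sub("\\s.*$", "", names(qss)),
             sequence = as.character(qss),
             quality = as.character(Biostrings::quality(qss)),
             stringsAsFactors = FALSE)
}
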