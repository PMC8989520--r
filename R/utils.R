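#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm pnorm rbinom rlnorm rpois sd chisq.test setNames
#' @importFrom utils adist
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Reverse complement on plain character vectors. Biostrings carries the
## heavy-duty machinery; for short reads a chartr round-trip is lighter and
## keeps plain-character pipelines allocation-free.
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

is_dna <- function(x, allow_n = FALSE) {
  alpha <- if (allow_n) "ACGTN" else "ACGT"
  all(grepl(sprintf("^[%s]+$", alpha), x))
}

## Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Classed conditions so the CLI can map error families to exit codes.
stop_retroterm <- function(msg, class, ...) {
  stop(structure(class = c(class, "retroterm_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

stop_config <- function(msg, ...) stop_retroterm(msg, "retroterm_config_error", ...)
stop_validation <- function(msg, ...) stop_retroterm(msg, "retroterm_validation_error", ...)
stop_empty <- function(msg, ...) stop_retroterm(msg, "retroterm_empty_input_error", ...)

## Longest terminal run of `base` at the given end of a string.
terminal_run_length <- function(seq, base, end = c("3prime", "5prime")) {
  end <- match.arg(end)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (end == "3prime") chars <- rev(chars)
  run <- 0L
  for (ch in chars) {
    if (ch == base) run <- run + 1L else break
  }
  run
}

## Terminal run of `base` tolerating isolated substitutions: a non-matching
## base is bridged only when at least `anchor` matching bases continue
## beyond it and the skip budget (one per `per` consumed bases, plus one)
## is not exhausted. The accepted run always ends on a matching base, so a
## non-`base` junction character is never absorbed.
tolerant_run_length <- function(chars, base, anchor = 4L, per = 10L) {
  n <- length(chars)
  i <- 1L; run <- 0L; skips <- 0L
  while (i <= n) {
    if (chars[i] == base) {
      run <- i
      i <- i + 1L
      next
    }
    budget <- run %/% per + 1L
    if (skips < budget && i + anchor <= n &&
        all(chars[(i + 1L):(i + anchor)] == base)) {
      skips <- skips + 1L
      i <- i + 1L
      next
    }
    break
  }
  run
}
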