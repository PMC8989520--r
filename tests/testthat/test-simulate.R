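test_that("molecule simulation emits reverse complements of sampled slices", {
  syn <- syn_fixture()
  ref <- syn$ref
  cfg <- molecule_config(1, dist_point(syn$start5),
                         dist_point(ref$canonical_term_site), seed = 1)
  mol <- simulate_molecules(cfg, ref)
  slice <- substr(ref$sequence, ref$canonical_term_site, syn$start5)
  expect_equal(mol$sequence,
               chartr("ACGT", "TGCA",
                      paste(rev(strsplit(slice, "")[[1]]), collapse = "")))
  expect_equal(mol$length, nchar(slice))

  ## same seed twice -> byte-identical output
  cfg2 <- molecule_config(200, dist_point(syn$start5),
                          termination_preset(ref, "-rnaseH1"), seed = 33)
  expect_identical(simulate_molecules(cfg2, ref),
                   simulate_molecules(cfg2, ref))

  bad <- molecule_config(10, dist_point(nchar(ref$sequence) + 5),
                         dist_point(ref$canonical_term_site), seed = 1)
  expect_error(simulate_molecules(bad, ref),
               class = "retroterm_config_error")
})

test_that("sampled 3'-end histogram matches the specified mass function", {
  syn <- syn_fixture()
  end_dist <- termination_preset(syn$ref, "-rnaseH1", sd = 4)
  cfg <- molecule_config(10000, dist_point(syn$start5), end_dist, seed = 77)
  mols <- simulate_molecules(cfg, syn$ref)
  obs <- table(factor(mols$end3, levels = end_dist$positions))
  keep <- end_dist$probs * 10000 >= 5  # chi-square validity
  gof <- suppressWarnings(chisq.test(
    c(as.integer(obs[keep]), sum(obs[!keep])),
    p = c(end_dist$probs[keep], sum(end_dist$probs[!keep]))))
  expect_gt(gof$p.value, 0.01)
})

test_that("library reads follow the adapter/tail architecture", {
  mol <- data.frame(molecule_id = "m1", sequence = "CCGT", retron = "r",
                    start5 = NA, end3 = NA, length = 4)
  lib <- library_config(substitution_error_rate = 0,
                        tail_dist = dist_point(25),
                        orientation_mix = c(sense = 1, antisense = 0),
                        seed = 5)
  sim <- simulate_library(mol, lib)
  expect_equal(sim$reads$sequence,
               paste0(lib$adapter_a, "CCGT", strrep("A", 25), lib$adapter_b))
  expect_equal(sim$truth$tail_len, 25)
  expect_equal(nchar(sim$reads$quality), nchar(sim$reads$sequence))

  anti <- library_config(substitution_error_rate = 0,
                         tail_dist = dist_point(25),
                         orientation_mix = c(sense = 0, antisense = 1),
                         seed = 5)
  sim2 <- simulate_library(mol, anti)
  ## antisense image: reverse complement, poly-T run before the molecule
  ## complement
  expect_true(grepl(paste0(strrep("T", 25), "ACGG"), sim2$reads$sequence))
  expect_equal(sim2$reads$sequence,
               chartr("ACGT", "TGCA",
                      paste(rev(strsplit(sim$reads$sequence, "")[[1]]),
                            collapse = "")))
})

test_that("substitution errors occur at the configured rate", {
  syn <- syn_fixture()
  cfg <- molecule_config(10000, dist_point(syn$start5),
                         dist_point(syn$ref$canonical_term_site), seed = 3)
  mols <- simulate_molecules(cfg, syn$ref)
  clean <- simulate_library(mols, library_config(
    substitution_error_rate = 0, tail_dist = dist_point(25),
    orientation_mix = c(sense = 1, antisense = 0), seed = 9))
  noisy <- simulate_library(mols, library_config(
    substitution_error_rate = 0.01, tail_dist = dist_point(25),
    orientation_mix = c(sense = 1, antisense = 0), seed = 9))
  n_tot <- sum(nchar(clean$reads$sequence))
  n_mm <- sum(vapply(seq_len(nrow(mols)), function(i) {
    sum(utf8ToInt(clean$reads$sequence[i]) !=
          utf8ToInt(noisy$reads$sequence[i]))
  }, numeric(1)))
  sigma <- sqrt(n_tot * 0.01 * 0.99)
  expect_lt(abs(n_mm - 0.01 * n_tot), 3 * sigma)
})

test_that("oligo spike respects proportions and tailing bias", {
  oligos <- paste0("GATTACAGATTACAGGCCT", c("A", "C", "G", "T"))
  one <- simulate_oligo_spike(oligos, 200, proportions = c(1, 0, 0, 0),
                              seed = 4)
  expect_true(all(one$truth$terminal_base == "A"))

  eq <- simulate_oligo_spike(oligos, 4000, seed = 5)
  counts <- table(factor(eq$truth$terminal_base, levels = c("A", "C", "G", "T")))
  sigma <- sqrt(4000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 1000) < 3 * sigma))

  biased <- simulate_oligo_spike(oligos, 4000,
                                 bias = c(A = 2, C = 1, G = 1, T = 1),
                                 seed = 6)
  frac_a <- mean(biased$truth$terminal_base == "A")
  sigma_a <- sqrt(0.4 * 0.6 / 4000)
  expect_lt(abs(frac_a - 0.4), 3 * sigma_a)

  expect_error(simulate_oligo_spike(oligos, 10, proportions = c(1, 1, 0, 0)),
               class = "retroterm_config_error")
  expect_error(simulate_oligo_spike(c("AAAC", "AAAG", "AAAT", "CAAA"), 10),
               class = "retroterm_validation_error")
})

test_that("phenotype simulation recovers design means", {
  design <- data.frame(strain = "wt",
                       construct = c("full-operon", "full-operon",
                                     "accessory-only", "accessory-only"),
                       induced = c(TRUE, FALSE, TRUE, FALSE),
                       od600_mean = c(0.8, 1.0, 0.1, 1.0))
  exact <- simulate_phenotypes(design, noise_cv = 0, n_replicates = 2,
                               seed = 1)
  expect_equal(exact$od600, rep(design$od600_mean, each = 2))
  expect_identical(simulate_phenotypes(design, 0.2, 3, seed = 8),
                   simulate_phenotypes(design, 0.2, 3, seed = 8))

  many <- simulate_phenotypes(design[1, ], noise_cv = 0.2,
                              n_replicates = 200, seed = 9)
  se <- sd(many$od600) / sqrt(200)
  expect_lt(abs(mean(many$od600) - 0.8), 3 * se)

  counts <- simulate_phenotypes(
    data.frame(strain = "wt", construct = "full-operon", phage = "T5",
               pfu_mean = 50, lysate_volume_ul = 45, dilution_factor = 1e-6),
    n_replicates = 200, seed = 10)
  se_c <- sd(counts$plaque_count) / sqrt(200)
  expect_lt(abs(mean(counts$plaque_count) - 50), 3 * se_c)

  expect_error(simulate_phenotypes(transform(design, od600_mean = -1)),
               class = "retroterm_config_error")
})

test_that("FASTQ writing and reading round-trips", {
  syn <- syn_fixture()
  cfg <- molecule_config(20, dist_point(syn$start5),
                         dist_point(syn$ref$canonical_term_site), seed = 2)
  sim <- simulate_library(simulate_molecules(cfg, syn$ref),
                          library_config(seed = 2))
  path <- tempfile(fileext = ".fastq")
  suppressWarnings(write_fastq(sim$reads, path))
  back <- read_fastq(path)
  expect_equal(back$sequence, sim$reads$sequence)
  expect_equal(back$read_id, sim$reads$read_id)
})
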