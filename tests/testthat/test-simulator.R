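test_that("simulate_concatemer emits the stated unit structure", {
  a <- fixture_assay()
  # single wildtype unit: exactly one exact copy of the target seed
  s1 <- simulate_concatemer(a, 1)
  hits <- gregexpr(target_seed(a), s1$sequence, fixed = TRUE)[[1]]
  expect_length(hits[hits > 0], 1L)

  # four units: find_hits recovers each at identity 1 at the truth spans
  s4 <- simulate_concatemer(a, 4)
  h <- find_hits(s4$sequence, a)
  tgt <- h[h$label == "TARGET", ]
  expect_identical(nrow(tgt), 4L)
  expect_equal(tgt$start, s4$units$start)
  expect_equal(tgt$end, s4$units$end)
  expect_true(all(tgt$identity == 1))
  # alternating orientation
  expect_identical(s4$units$strand, c("+", "-", "+", "-"))

  # every mutant unit carries the mutant base at the hotspot
  sm <- simulate_concatemer(a, 3, "T")
  off <- a$hotspot_pos - a$target_span[1]
  for (k in seq_len(3)) {
    u <- sm$units[k, ]
    base <- if (u$strand == "+")
      substr(sm$sequence, u$start + off + 1, u$start + off + 1)
    else
      revcomp(substr(sm$sequence, u$end - off, u$end - off))
    expect_identical(base, "T")
  }
})

test_that("corrupt_seq honours its rates and coordinate map", {
  s <- random_dna(1000)
  clean <- corrupt_seq(s, c(sub = 0, ins = 0, del = 0))
  expect_identical(clean$sequence, s)
  expect_identical(clean$map, 0:1000)

  expect_error(corrupt_seq(s, c(sub = 0, ins = 0, del = 0.5)), "rates")

  # substitution count within 4 sigma of its binomial expectation
  set.seed(55)
  n_total <- 0L; n_sub <- 0L
  for (i in 1:20) {
    x <- random_dna(2500)
    y <- corrupt_seq(x, c(sub = 0.03, ins = 0, del = 0))
    n_total <- n_total + 2500L
    n_sub <- n_sub + sum(strsplit(x, "")[[1]] != strsplit(y$sequence, "")[[1]])
  }
  expected <- n_total * 0.03
  sigma <- sqrt(n_total * 0.03 * 0.97)
  expect_lt(abs(n_sub - expected), 4 * sigma)

  # map is monotone and ends at the emitted length
  z <- corrupt_seq(s, c(sub = 0.03, ins = 0.05, del = 0.05))
  expect_true(!is.unsorted(z$map))
  expect_identical(z$map[length(z$map)], nchar(z$sequence))
  # determinism under seed
  set.seed(9); z1 <- corrupt_seq(s)
  set.seed(9); z2 <- corrupt_seq(s)
  expect_identical(z1, z2)
})

test_that("simulate_run draws the mixture and is byte-deterministic", {
  a <- fixture_assay()
  short_cfg <- simulation_config(a, n_reads = 40L,
                                 mixture = c(SHORT = 1), rng_seed = 3L,
                                 background = fixture_background())
  sim <- simulate_run(short_cfg)
  expect_true(all(nchar(sim$sequence) < 60))
  expect_identical(nrow(sim), 40L)

  cfg <- simulation_config(a, n_reads = 60L, rng_seed = 8L,
                           background = fixture_background())
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  simulate_run(cfg, fastq = f1, truth = t1)
  simulate_run(cfg, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  truth <- read.table(t1, header = TRUE, sep = "\t")
  expect_identical(nrow(truth), 60L)
  expect_true(all(truth$class %in% c("TARGET", "FRAGMENT", "SPURIOUS",
                                     "BACKGROUND", "ONT", "SHORT",
                                     "UNKNOWN")))
})

test_that("arrival times are exponential inter-arrivals at the set rate", {
  a <- fixture_assay()
  cfg <- simulation_config(a, n_reads = 400L, mixture = c(SHORT = 1),
                           arrival_rate = 10, rng_seed = 12L,
                           background = "ACGT")
  sim <- simulate_run(cfg)
  gaps <- diff(c(0, sim$start_time))
  ks <- suppressWarnings(ks.test(gaps, "pexp", rate = 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth labels round-trip through the pipeline at zero error", {
  a <- fixture_assay()
  cfg <- simulation_config(a, n_reads = 150L, rng_seed = 6L,
                           error_rates = c(sub = 0, ins = 0, del = 0),
                           background = fixture_background())
  sim <- simulate_run(cfg)
  rep <- run_sim_pipeline(sim, a, cfg$background, cfg$adapter)
  cls <- diag_classes(rep)
  expect_gte(mean(cls == sim$class), 0.99)
  tgt <- sim$class == "TARGET"
  expect_true(all(diag_calls(rep)[tgt & cls == "TARGET"] ==
                    sim$allele[tgt & cls == "TARGET"]))
})
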