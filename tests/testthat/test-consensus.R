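test_that("align_subread reads the hotspot base off the edit path", {
  a <- fixture_assay()
  al <- align_subread(a$target_ref, a)
  expect_true(al$aligned)
  expect_identical(al$locus_call, a$wildtype_allele)

  # K27M-style substitution A>T
  mut <- a$target_ref
  substr(mut, a$hotspot_pos + 1, a$hotspot_pos + 1) <- "T"
  expect_identical(align_subread(mut, a)$locus_call, "T")

  # deletion spanning the hotspot
  del <- paste0(substr(a$target_ref, 1, a$hotspot_pos),
                substr(a$target_ref, a$hotspot_pos + 2,
                       nchar(a$target_ref)))
  expect_identical(align_subread(del, a)$locus_call, "DEL")

  # random sequences of the same length never pass the acceptance filter
  set.seed(11)
  for (i in 1:20)
    expect_false(align_subread(random_dna(nchar(a$target_ref)), a)$aligned)

  # a fragment not covering the hotspot aligns but gives NOCALL
  frag <- substr(a$target_ref, 1, a$hotspot_pos - 5)
  alf <- align_subread(frag, a)
  expect_true(alf$aligned)
  expect_identical(alf$locus_call, "NOCALL")
})

test_that("consensus_call applies plurality with seeded tie-breaking", {
  r <- consensus_call(c("T", "T", "A"))
  expect_identical(r$call, "T")
  expect_identical(r$support, 2L)
  expect_false(r$tie_broken)

  set.seed(1); t1 <- consensus_call(c("T", "A"))
  set.seed(1); t2 <- consensus_call(c("T", "A"))
  expect_true(t1$tie_broken)
  expect_true(t1$call %in% c("T", "A"))
  expect_identical(t1$call, t2$call)

  e <- consensus_call(character(0))
  expect_identical(e$call, "NOCALL")
  expect_identical(e$support, 0L)
  expect_identical(consensus_call(c("NOCALL", "NOCALL"))$call, "NOCALL")

  # permutation invariance for strict pluralities
  set.seed(3)
  for (i in 1:20) {
    calls <- c(rep("T", 3), sample(c("A", "C", "DEL"), 2, replace = TRUE))
    expect_identical(consensus_call(sample(calls))$call, "T")
  }
})

test_that("polish_stats counts overridden discordant calls", {
  cons <- consensus_call(c("T", "T", "A"))
  p <- polish_stats(c("T", "T", "A"), cons)
  expect_identical(p$n_overridden, 1L)
  expect_true(p$polished)
  p1 <- polish_stats("T", consensus_call("T"))
  expect_identical(p1$n_overridden, 0L)
  expect_false(p1$polished)
})

test_that("concatemer redundancy suppresses consensus miscalls", {
  a <- fixture_assay()
  g <- build_grammar(a)
  rates <- c(sub = 0.05, ins = 0, del = 0)
  set.seed(42)
  single_err <- 0L; cons_err <- 0L; n <- 120L
  for (i in seq_len(n)) {
    sim <- simulate_concatemer(a, 5, "T")
    noisy <- corrupt_seq(sim$sequence, rates)$sequence
    h <- find_hits(noisy, a)
    srs <- build_subreads(noisy, h, g)
    calls <- vapply(srs, function(sr)
      align_subread(sr$sequence, a)$locus_call, character(1))
    calls <- calls[calls != "NOCALL"]
    if (!length(calls)) next
    # paired comparison: first sub-read alone vs the pileup consensus
    single_err <- single_err + (calls[1] != "T")
    cons_err <- cons_err + (consensus_call(calls)$call != "T")
  }
  expect_gt(single_err, 0L)   # the error regime actually produces miscalls
  expect_lt(cons_err, single_err)
})

test_that("consensus error rate decreases with unit count", {
  a <- fixture_assay()
  g <- build_grammar(a)
  rates <- c(sub = 0.08, ins = 0.02, del = 0.02)
  err <- numeric(0)
  set.seed(7)
  for (n_units in c(1L, 3L, 6L)) {
    miscalls <- 0L; n <- 100L
    for (i in seq_len(n)) {
      sim <- simulate_concatemer(a, n_units, "T")
      noisy <- corrupt_seq(sim$sequence, rates)$sequence
      d <- classify_read(noisy, a, g)
      if (d$class != "TARGET" || d$consensus$call != "T")
        miscalls <- miscalls + 1L
    }
    err <- c(err, miscalls / n)
  }
  expect_true(all(diff(err) <= 0))
  expect_lt(err[3], err[1])
})
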