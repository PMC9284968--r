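test_that("lamp_assay validates its invariants", {
  a <- fixture_assay()
  expect_s3_class(a, "lamp_assay")
  expect_identical(substr(a$target_ref, a$hotspot_pos + 1, a$hotspot_pos + 1),
                   a$wildtype_allele)
  expect_identical(target_seed(a),
                   substr(a$target_ref, a$target_span[1] + 1, a$target_span[2]))
  # hotspot inside span, span inside ref
  expect_true(a$hotspot_pos >= a$target_span[1] &&
                a$hotspot_pos < a$target_span[2])
  expect_true(a$target_span[2] <= nchar(a$target_ref))

  # invariant violations raise validation errors naming the field
  expect_error(lamp_assay("x", a$target_ref, a$designs, hotspot_pos = 5L,
                          mutant_alleles = "T", target_span = a$target_span),
               "hotspot")
  expect_error(lamp_assay("x", a$target_ref, a$designs,
                          hotspot_pos = a$hotspot_pos, mutant_alleles = "T",
                          target_span = a$target_span,
                          wildtype_allele = "G"),
               "wildtype_allele")
  expect_error(lamp_assay("x", a$target_ref, a$designs[-2],
                          hotspot_pos = a$hotspot_pos, mutant_alleles = "T"),
               "missing label")
  expect_error(lamp_assay("x", "ACGTX", a$designs, 1L, "T", c(0L, 4L)),
               "target_ref")
  expect_error(lamp_assay("x", a$target_ref, a$designs, a$hotspot_pos, "A"),
               "mutant")
})

test_that("split_inner_primers partitions at a unique linker", {
  # published-style H3F3A inner primers, poly-T linker
  halves <- split_inner_primers(
    "GCGGGCAGTCTGCTTTGTATTTTATGCTGGTAGGTAAGTAAGGA",
    "CGACCGGTGGTAAAGCACCTTTTCACCCCTCCAGTAGAG")
  expect_identical(halves$fip,
                   c("GCGGGCAGTCTGCTTTGTA", "ATGCTGGTAGGTAAGTAAGGA"))
  expect_identical(halves$bip, c("CGACCGGTGGTAAAGCACC", "CACCCCTCCAGTAGAG"))
  # partition property: halves + linker reproduce the primer
  expect_identical(paste0(halves$fip[1], "TTTT", halves$fip[2]),
                   "GCGGGCAGTCTGCTTTGTATTTTATGCTGGTAGGTAAGTAAGGA")

  expect_identical(split_inner_primers("AAAATTTTCCCC", "GGGGTTTTAAAA")$fip,
                   c("AAAA", "CCCC"))
  # zero or multiple occurrences are ambiguous
  expect_error(split_inner_primers("TTTTAATTTT", "GGGGTTTTAAAA"), "2 times")
  expect_error(split_inner_primers("AAAACCCC", "GGGGTTTTAAAA"), "0 times")
})

test_that("assay files round-trip and the bundled file loads", {
  a <- fixture_assay()
  tmp <- withr::local_tempfile(fileext = ".assay")
  write_assay(a, tmp)
  expect_identical(unclass(load_assay(tmp)), unclass(a))

  bundled <- system.file("extdata", "h3f3a_k27m_synthetic.assay",
                         package = "lampcall")
  expect_identical(unclass(load_assay(bundled)), unclass(a))

  # target_ref via FASTA
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(amplicon = a$target_ref)), fa)
  lines <- readLines(tmp)
  lines <- lines[!startsWith(lines, "target_ref:")]
  writeLines(c(lines, "target_ref_fasta: ref.fa"), file.path(dir, "a.assay"))
  expect_identical(load_assay(file.path(dir, "a.assay"))$target_ref,
                   a$target_ref)

  expect_error(load_assay(file.path(dir, "nope.assay")), "not found")
})

test_that("default target span sits between F1 and B1 extended by 5", {
  a <- fixture_assay()
  f1_end <- regexpr(a$designs[["F1"]], a$target_ref, fixed = TRUE)[1] - 1L +
    nchar(a$designs[["F1"]])
  b1_start <- regexpr(a$designs[["B1"]], a$target_ref, fixed = TRUE)[1] - 1L
  expect_identical(a$target_span, c(f1_end - 5L, b1_start + 5L))
})
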