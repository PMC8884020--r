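test_that("design validation enforces CDR2 lengths and the CDR3 alphabet", {
  d <- default_design()
  expect_named(d$sublibraries, c("Upright6", "Upright12", "Roll12", "Roll15"))
  expect_equal(length(d$sublibraries$Upright6$cdr1), 150)
  expect_equal(length(d$sublibraries$Upright6$cdr2), 71)
  expect_equal(length(d$sublibraries$Roll15$cdr2), 69)
  expect_true(all(nchar(d$sublibraries$Upright12$cdr2) == 16))
  expect_true(all(nchar(d$sublibraries$Roll12$cdr2) == 17))

  scaff <- vhhkit:::default_scaffolds()$Upright
  # a 17-residue CDR2 inside an Upright spec is named in the error
  bad17 <- "AISGSGGSTYYADSVKG"
  err <- tryCatch(
    sublibrary_spec("Upright6", "Upright", scaff,
                    cdr1 = "GRTFSSYAMG", cdr2 = bad17, cdr3_length = 6),
    vhh_validation_error = function(e) e)
  expect_s3_class(err, "vhh_validation_error")
  expect_match(conditionMessage(err), bad17, fixed = TRUE)

  expect_error(
    sublibrary_spec("Upright6", "Upright", scaff, cdr1 = "GRTFSSYAMG",
                    cdr2 = "AISGSGGSTYYADSVK", cdr3_length = 6,
                    cdr3_alphabet = c(cdr3_alphabet17(), "C")),
    class = "vhh_validation_error")
  expect_error(
    sublibrary_spec("X", "Upright", scaff, cdr1 = "GRTFSSYAMG",
                    cdr2 = "AISGSGGSTYYADSVK", cdr3_length = 16),
    class = "vhh_validation_error")
  expect_equal(length(cdr3_alphabet17()), 17)
})

test_that("diversity is exact big-integer arithmetic", {
  # expected values frozen from an independent arbitrary-precision oracle
  d <- default_design()
  div <- diversity(d)
  expect_equal(div$per$diversity[div$per$name == "Upright6"],
               "257065109850")
  expect_equal(div$per$diversity[div$per$name == "Upright12"],
               "6204926826496954650")
  expect_equal(div$per$diversity[div$per$name == "Roll12"],
               "6030140155328026350")
  expect_equal(div$per$diversity[div$per$name == "Roll15"],
               "29626078583126593457550")
  expect_equal(div$total, "29638313650365483548400")

  # single CDR1/CDR2, length-1 CDR3 over 17 letters -> 17
  scaff <- vhhkit:::default_scaffolds()$Upright
  tiny <- structure(list(sublibraries = list(
    T1 = sublibrary_spec("T1", "Upright", scaff, cdr1 = "GRTFSSYAMG",
                         cdr2 = "AISGSGGSTYYADSVK", cdr3_length = 1))),
    class = "LibraryDesign")
  expect_equal(diversity(tiny)$per$diversity, "17")
})

test_that("diversity is monotone in repertoire sizes and CDR3 length", {
  base <- default_design()
  d6 <- diversity(base)$per
  v <- setNames(d6$diversity_num, d6$name)
  expect_lt(v[["Upright6"]], v[["Upright12"]])   # longer CDR3
  expect_lt(v[["Roll12"]], v[["Roll15"]])
  # trimming the CDR2 repertoire cannot increase diversity
  trim <- base
  trim$sublibraries$Upright6$cdr2 <- trim$sublibraries$Upright6$cdr2[1:10]
  expect_lt(diversity(trim)$per$diversity_num[1], v[["Upright6"]])
})

test_that("sampling is seed-deterministic and spec-conformant", {
  d <- default_design()
  a <- sample_protein(d, "Upright6", 1000, seed = 7)
  b <- sample_protein(d, "Upright6", 1000, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, sample_protein(d, "Upright6", 1000, seed = 8)))
  expect_error(sample_protein(d, "Nope", 10, seed = 1),
               class = "vhh_lookup_error")

  # no C/M/P in any sampled CDR3; sequences re-validate against the spec
  expect_false(any(grepl("[CMP]", a$cdr3)))
  s <- d$sublibraries$Upright6
  expect_true(all(nchar(a$sequence) ==
                    sum(nchar(s$fr)) + 10 + 16 + s$cdr3_length))
  expect_true(all(startsWith(a$sequence, s$fr["FR1"])))
  expect_true(all(endsWith(a$sequence, s$fr["FR4"])))
  expect_true(all(a$cdr3 == substr(a$sequence,
                                   nchar(a$sequence) - nchar(s$fr["FR4"]) -
                                     s$cdr3_length + 1,
                                   nchar(a$sequence) - nchar(s$fr["FR4"]))))
})

test_that("sampled CDR3 letter frequencies are near-uniform", {
  d <- default_design()
  n <- 20000
  sm <- sample_protein(d, "Roll12", n, seed = 13)
  qc <- composition_qc(sm$cdr3)
  expect_equal(qc$n_used, n)
  p <- 1 / 17
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(qc$freq - p) <= 5 * se))
})

test_that("reverse translation round-trips through the genetic code", {
  expect_equal(reverse_translate("M", c(M = "ATG")), "ATG")
  expect_error(reverse_translate("MX", c(M = "ATG")),
               class = "vhh_coding_error")

  d <- default_design()
  prot <- sample_protein(d, "Upright12", 1, seed = 2)$sequence
  dna <- reverse_translate(prot, d$codon_table)
  expect_equal(nchar(dna), 3 * nchar(prot))
  back <- as.character(Biostrings::translate(Biostrings::DNAString(dna)))
  expect_equal(back, prot)

  # stop codons rejected at table validation
  expect_error(validate_codon_table(c(M = "TAA")),
               class = "vhh_validation_error")
  expect_error(validate_codon_table(c(M = "ATG", K = "ATG")),
               class = "vhh_validation_error")
  expect_silent(validate_codon_table(default_codon_table()))
})

test_that("cassette assembly reports coordinates and closes under translation", {
  d <- default_design()
  d$cassette <- list(utr5 = "AAA", his_tag = "GGG", utr3 = "CCC")
  asm <- assemble_cassette("TTT", d)
  expect_equal(asm$sequence, "AAATTTGGGCCC")
  expect_equal(asm$elements$start, c(0, 3, 6, 9))
  expect_equal(asm$elements$end, c(3, 6, 9, 12))

  d$cassette$utr5 <- ""
  expect_error(assemble_cassette("TTT", d), class = "vhh_assembly_error")

  # real cassette: the VHH element translates back to the source protein
  d2 <- default_design()
  prot <- sample_protein(d2, "Roll15", 1, seed = 4)$sequence
  dna <- reverse_translate(prot, d2$codon_table)
  asm2 <- assemble_cassette(dna, d2)
  el <- asm2$elements
  vr <- substr(asm2$sequence, el$start[el$element == "vhh"] + 1,
               el$end[el$element == "vhh"])
  expect_equal(
    as.character(Biostrings::translate(Biostrings::DNAString(vr))), prot)
})

test_that("restriction audit finds sites on both strands at exact offsets", {
  hits <- restriction_audit("AACGTCTCAA")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$enzyme, "BsmBI")
  expect_equal(hits$strand, "+")
  expect_equal(hits$offset, 2L)

  expect_equal(nrow(restriction_audit("AAAAAAAAAA")), 0)

  # reverse-strand-only site: revcomp(CGTCTC) = GAGACG on the forward strand
  rev_hits <- restriction_audit("TTGAGACGTT")
  expect_equal(rev_hits$strand, "-")
  expect_equal(rev_hits$offset, 2L)

  expect_error(restriction_audit("ACGT", c(Bad = "")),
               class = "vhh_config_error")
})

test_that("restriction audit equals naive substring search on random DNA", {
  naive <- function(dna, pat) {
    hits <- integer(0)
    for (i in seq_len(nchar(dna) - nchar(pat) + 1))
      if (substr(dna, i, i + nchar(pat) - 1) == pat)
        hits <- c(hits, i - 1L)
    hits
  }
  revcomp <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  withr::with_seed(77, {
    for (rep in 1:10) {
      dna <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                   collapse = "")
      got <- restriction_audit(dna)
      for (enz in c("BsmBI", "BtgZI")) {
        pat <- vhhkit:::default_enzymes()[[enz]]
        expect_equal(sort(got$offset[got$enzyme == enz & got$strand == "+"]),
                     sort(naive(dna, pat)))
        expect_equal(sort(got$offset[got$enzyme == enz & got$strand == "-"]),
                     sort(naive(dna, revcomp(pat))))
      }
    }
  })
})

test_that("composition QC: TVD limits and violation handling", {
  # perfectly uniform count table -> TVD 0 everywhere
  counts <- matrix(10, nrow = 3, ncol = 17,
                   dimnames = list(NULL, cdr3_alphabet17()))
  qc <- composition_qc(counts)
  expect_equal(qc$tvd, rep(0, 3))
  expect_equal(qc$chisq$statistic, rep(0, 3))
  expect_equal(qc$chisq$df, rep(16, 3))

  # all mass on one letter -> TVD = 16/17
  one <- composition_qc(rep("AAA", 50))
  expect_equal(one$tvd, rep(16 / 17, 3), tolerance = 1e-12)

  # wrong-length and out-of-alphabet sequences are excluded but counted
  mixed <- c(rep("ADE", 30), "AD", "ACP")
  qc2 <- composition_qc(mixed, length_expected = 3)
  expect_equal(qc2$n_used, 30)
  expect_equal(qc2$n_excluded, 2)

  expect_error(composition_qc(character(0)), class = "vhh_empty_input")
})

test_that("designs round-trip through YAML config and FASTA repertoires", {
  dir <- withr::local_tempdir()
  reps <- make_repertoires(20, 10, 16, seed = 9, dir = dir,
                           alphabet = setdiff(AA20, c("C", "W")))
  reps_r <- make_repertoires(1, 8, 17, seed = 10,
                             alphabet = setdiff(AA20, c("C", "W")))
  cfg <- list(cdr1 = file.path(dir, "cdr1.fasta"),
              cdr2_upright = file.path(dir, "cdr2.fasta"),
              cdr2_roll = reps_r$cdr2,
              cdr3_lengths = list(Upright6 = 6, Roll15 = 15))
  yml <- file.path(dir, "design.yaml")
  yaml::write_yaml(cfg, yml)
  d <- build_design(yml)
  expect_named(d$sublibraries, c("Upright6", "Roll15"))
  expect_equal(sort(d$sublibraries$Upright6$cdr1), sort(reps$cdr1))
  expect_equal(length(d$sublibraries$Roll15$cdr2), 8)
})
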