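test_that("filters apply each rule and log every rejection", {
  recs <- rbind(
    make_record("1aaa", resolution = 2.5),                       # kept
    make_record("2bbb", resolution = 3.0),                       # resolution
    make_record("3ccc", resolution = 2.8),                       # boundary: strict <
    make_record("4ddd", method = "SOLUTION NMR"),                # method
    make_record("5eee", light_chain_id = "L"),                   # light chain
    make_record("6fff", resolution = NA_real_),                  # missing metadata
    make_record("7ggg", antigen_chain_ids = "",
                ligand_mw_max = 300))                            # hapten
  out <- filter_records(recs, curation_criteria())
  expect_equal(out$kept$entry_id, "1aaa")
  expect_equal(nrow(out$kept) + nrow(out$rejections), nrow(recs))
  got <- setNames(out$rejections$reason, out$rejections$entry_id)
  expect_equal(got[["2bbb"]], "resolution")
  expect_equal(got[["3ccc"]], "resolution")
  expect_equal(got[["4ddd"]], "method")
  expect_equal(got[["5eee"]], "light-chain-present")
  expect_equal(got[["6fff"]], "missing-metadata")
  expect_equal(got[["7ggg"]], "hapten")

  # a 300-Da ligand alongside a polymer antigen is NOT a hapten complex
  ok <- filter_records(make_record("8hhh", antigen_chain_ids = "B",
                                   ligand_mw_max = 300))
  expect_equal(nrow(ok$kept), 1)

  # paired-chain criteria (VH dataset): heavy-only entries rejected
  crit_vh <- curation_criteria(require_heavy_only = FALSE,
                               require_paired = TRUE,
                               species = "homo sapiens")
  paired <- make_record("9iii", light_chain_id = "L",
                        species_heavy = "homo sapiens",
                        species_light = "homo sapiens")
  unpaired <- make_record("10jjj", species_heavy = "homo sapiens")
  out2 <- filter_records(rbind(paired, unpaired), crit_vh)
  expect_equal(out2$kept$entry_id, "9iii")
  expect_equal(out2$rejections$reason, "light-chain-absent")
})

test_that("filtering is idempotent and conserves record counts", {
  withr::with_seed(3, {
    recs <- do.call(rbind, lapply(1:40, function(i)
      make_record(sprintf("%04d", i),
                  resolution = runif(1, 1.5, 3.5),
                  method = sample(c("X-RAY DIFFRACTION", "SOLUTION NMR"), 1),
                  light_chain_id = sample(c(NA, "L"), 1),
                  antigen_chain_ids = sample(c("B", ""), 1),
                  ligand_mw_max = sample(c(NA, 300, 5000), 1))))
  })
  out1 <- filter_records(recs)
  expect_equal(nrow(out1$kept) + nrow(out1$rejections), nrow(recs))
  expect_equal(sum(out1$log$n_rejected), nrow(out1$rejections))
  out2 <- filter_records(out1$kept)
  expect_equal(out2$kept, out1$kept)
  expect_equal(nrow(out2$rejections), 0)
})

test_that("exact dedup keeps best resolution, then smallest entry id", {
  r <- rbind(make_record("2xyz", resolution = 2.5,
                         variable_domain_sequence = "SEQA"),
             make_record("1abc", resolution = 2.0,
                         variable_domain_sequence = "SEQA"),
             make_record("3foo", resolution = 2.0,
                         variable_domain_sequence = "SEQB"))
  out <- dedup_exact(r)
  expect_equal(sort(out$entry_id), c("1abc", "3foo"))
  expect_equal(out$resolution[out$variable_domain_sequence == "SEQA"], 2.0)

  # tie on resolution -> lexicographically smallest entry id
  tie <- rbind(make_record("9zzz", resolution = 2.0,
                           variable_domain_sequence = "SEQC"),
               make_record("1aaa", resolution = 2.0,
                           variable_domain_sequence = "SEQC"))
  expect_equal(dedup_exact(tie)$entry_id, "1aaa")

  # all-unique input passes through; triple duplicate leaves one survivor
  uniq <- rbind(make_record("1", variable_domain_sequence = "A"),
                make_record("2", variable_domain_sequence = "B"))
  expect_equal(nrow(dedup_exact(uniq)), 2)
  trip <- do.call(rbind, lapply(1:3, function(i)
    make_record(as.character(i), variable_domain_sequence = "SAME")))
  expect_equal(nrow(dedup_exact(trip)), 1)
})

test_that("dedup matches a hash-set oracle on random tables", {
  withr::with_seed(19, {
    for (rep in 1:5) {
      seqs <- sample(replicate(15, paste(sample(AA <- LETTERS[1:20], 8,
                                                replace = TRUE),
                                         collapse = "")),
                     60, replace = TRUE)
      recs <- do.call(rbind, lapply(seq_along(seqs), function(i)
        make_record(sprintf("%03d", i), resolution = runif(1, 1, 3),
                    variable_domain_sequence = seqs[i])))
      out <- dedup_exact(recs)
      expect_equal(sort(unique(seqs)),
                   sort(out$variable_domain_sequence))
      expect_false(anyDuplicated(out$variable_domain_sequence) > 0)
    }
  })
})

test_that("class/length summary arithmetic on a hand-built table", {
  recs <- data.frame(
    class = c(rep("Roll", 10), rep("Upright", 4), NA),
    cdr2_length = c(rep(17, 9), 16, rep(16, 4), 16),
    cdr3_length = c(rep(14, 10), rep(6, 4), 7),
    cdr3_seq = c(rep("GRAYDYWAGDLRYE", 10), rep("GRAYDC", 4), "GRAYDYW"),
    stringsAsFactors = FALSE)
  s <- class_length_summary(recs)
  roll17 <- s$cdr2_contingency
  pct <- roll17$row_pct[roll17$class == "Roll" & roll17$cdr2_length == 17]
  expect_equal(pct, 90)
  expect_equal(s$n_unclassified, 1)
  # row percentages sum to 100 per class that has records
  for (cl in c("Roll", "Upright")) {
    rows <- s$cdr2_contingency[s$cdr2_contingency$class == cl, ]
    expect_equal(sum(rows$row_pct), 100, tolerance = 1e-9)
  }
  # empty class yields zero counts, no division error
  hr <- s$cdr2_contingency[s$cdr2_contingency$class == "Half-Roll", ]
  expect_true(all(hr$n == 0))
  # cysteine stratification: all short loops here
  cys <- s$cys_by_length
  expect_equal(cys$frac_with_cys[cys$stratum == "<16"],
               mean(grepl("C", recs$cdr3_seq[!is.na(recs$class)])))
})

test_that("seeded class-conditional simulation recovers generating percentages", {
  # generating model: P(cdr2 len 17 | Roll) = 0.87, P(len 16 | Upright) = 0.62
  n <- 1000
  withr::with_seed(2024, {
    cls <- sample(c("Roll", "Upright", "Half-Roll"), n, replace = TRUE,
                  prob = c(0.35, 0.35, 0.30))
    p17 <- ifelse(cls == "Roll", 0.87, ifelse(cls == "Upright", 0.38, 0.5))
    len2 <- ifelse(runif(n) < p17, 17, 16)
  })
  recs <- data.frame(class = cls, cdr2_length = len2,
                     cdr3_length = 10, cdr3_seq = "GRAYDYWAGD",
                     stringsAsFactors = FALSE)
  s <- class_length_summary(recs)
  ct <- s$cdr2_contingency
  check <- function(cl, len, p) {
    nn <- sum(cls == cl)
    obs <- ct$row_pct[ct$class == cl & ct$cdr2_length == len] / 100
    expect_lt(abs(obs - p), 1.96 * sqrt(p * (1 - p) / nn))
  }
  check("Roll", 17, 0.87)
  check("Upright", 16, 0.62)
})

test_that("hallmark profile reports the FR2 tetrad and counts missing as X", {
  s_u <- baseline_sequence()   # Upright scaffold: F37 / E44 / R45 / F47
  recs <- data.frame(entry_id = c("a", "b"), chain_id = "A",
                     sequence = c(s_u, "NOTAVALIDDOMAIN"),
                     stringsAsFactors = FALSE)
  hp <- hallmark_profile(recs)
  expect_equal(unlist(hp$per_record[1, c("H37", "H44", "H45", "H47")],
                      use.names = FALSE),
               c("F", "E", "R", "F"))
  expect_equal(unlist(hp$per_record[2, c("H37", "H44", "H45", "H47")],
                      use.names = FALSE),
               rep("X", 4))
  expect_equal(sum(hp$frequencies["H37", ]), 2)
  expect_equal(unname(hp$frequencies["H37", "F"]), 1)
  expect_equal(unname(hp$frequencies["H44", "X"]), 1)
})

test_that("aggregate hallmark frequencies equal a known mix", {
  s_u <- baseline_sequence()
  s_r <- paste0(substr(s_u, 1, 25), "GRTFSSYAMG",
                vhhkit:::default_scaffolds()$Roll["FR2"],
                substr(s_u, 50, nchar(s_u)))
  recs <- data.frame(entry_id = sprintf("e%02d", 1:10), chain_id = "A",
                     sequence = c(rep(s_u, 7), rep(s_r, 3)),
                     stringsAsFactors = FALSE)
  hp <- hallmark_profile(recs)
  expect_equal(unname(hp$frequencies["H47", "F"]), 7)  # Upright scaffold
  expect_equal(unname(hp$frequencies["H47", "W"]), 3)  # Roll scaffold (VH-like)
  expect_equal(unname(hp$frequencies["H45", "R"]), 7)
  expect_equal(unname(hp$frequencies["H45", "L"]), 3)
})
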