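test_that("quality filter removes reads with >75% of bases below Q25", {
  q30 <- intToUtf8(rep(30 + 33, 10))
  q20mix8 <- intToUtf8(c(rep(20 + 33, 8), rep(30 + 33, 2)))  # 80% low
  q20mix7 <- intToUtf8(c(rep(20 + 33, 7), rep(30 + 33, 3)))  # 70% low
  expect_true(qualityFilter(q30))
  expect_false(qualityFilter(q20mix8))
  expect_true(qualityFilter(q20mix7))          # 0.70 <= 0.75 boundary kept
  expect_message(res <- qualityFilter(NA_character_), "without quality")
  expect_true(res)
})

test_that("length filter is inclusive and mode-aware", {
  expect_true(lengthFilter(29, "mono"))
  expect_false(lengthFilter(29, "di"))
  expect_true(lengthFilter(45, "mono"))        # inclusive upper bound
  expect_true(lengthFilter(15, "mono"))
  expect_false(lengthFilter(14, "mono"))
  expect_true(all(lengthFilter(c(30, 70), "di")))
  expect_error(lengthFilter(20, minLen = 30, maxLen = 20), "exceed")
})

test_that("offset calibration recovers known offsets and ties take the smaller", {
  tx <- tinyTx(n = 5, seed = 3)
  cs <- cdsStart(tx)
  # reads whose P-site is exactly the start codon, true offset 12
  reads <- do.call(rbind, lapply(txIds(tx), function(id)
    data.frame(transcript_id = id,
               five_prime_pos = rep(cs[[id]] - 12L, 60),
               read_length = 29L, quality = NA_character_)))
  # plus in-frame CDS reads for periodicity
  body <- do.call(rbind, lapply(txIds(tx), function(id)
    data.frame(transcript_id = id,
               five_prime_pos = cs[[id]] + 3L * (1:20) - 12L,
               read_length = 29L, quality = NA_character_)))
  cal <- calibrateOffsets(rbind(reads, body), tx)
  expect_equal(unname(cal$offsets[["29"]]), 12)
  expect_equal(cal$report$f0, 1)
  expect_equal(cal$report$periodicity_score, 1)

  # tie between offsets 10 and 12: equal start hits, smaller offset wins
  tie <- rbind(
    data.frame(transcript_id = "tx1",
               five_prime_pos = rep(cs[["tx1"]] - 10L, 100),
               read_length = 29L, quality = NA_character_),
    data.frame(transcript_id = "tx2",
               five_prime_pos = rep(cs[["tx2"]] - 12L, 100),
               read_length = 29L, quality = NA_character_))
  calTie <- calibrateOffsets(tie, tx, minReads = 1)
  expect_equal(unname(calTie$offsets[["29"]]), 10)
})

test_that("frame-uniform reads are rejected by the periodicity screen", {
  tx <- tinyTx(n = 4, seed = 5)
  cs <- cdsStart(tx)
  set.seed(8)
  reads <- do.call(rbind, lapply(txIds(tx), function(id) {
    psite <- cs[[id]] + sample(0:80, 120, replace = TRUE)  # all frames
    data.frame(transcript_id = id, five_prime_pos = psite - 12L,
               read_length = 29L, quality = NA_character_)
  }))
  anchor <- data.frame(transcript_id = "tx1",
                       five_prime_pos = cs[["tx1"]] - 12L,
                       read_length = 29L, quality = NA_character_)
  expect_error(calibrateOffsets(rbind(anchor, reads), tx),
               "no read length passed")
})

test_that("track building conserves kept reads and drops rejected lengths", {
  tx <- tinyTx()
  reads <- data.frame(transcript_id = "tx1",
                      five_prime_pos = c(12L, 12L, 30L),
                      read_length = c(29L, 35L, 29L),
                      quality = NA_character_)
  lib <- buildTracks(reads, c("29" = 12L), tx, "s1")
  expect_equal(librarySize(lib), 2)            # the 35-mer is rejected
  expect_equal(track(lib, "tx1")[24 + 1], 1)   # 12 + 12
  expect_equal(track(lib, "tx1")[42 + 1], 1)

  set.seed(11)
  many <- data.frame(transcript_id = sample(txIds(tx), 1e4, replace = TRUE),
                     five_prime_pos = sample(0:80, 1e4, replace = TRUE),
                     read_length = 29L, quality = NA_character_)
  lib2 <- buildTracks(many, c("29" = 12L), tx, "s2")
  expect_equal(librarySize(lib2), 1e4)         # conservation, exact
})

test_that("RPKM follows the formula and is scale invariant", {
  counts <- integer(1200)
  tx <- Transcriptome(
    c(tx1 = strrep("ACGTT", 240)),
    data.frame(transcript_id = "tx1", gene_id = "g1",
               cds_start = 99L, cds_end = 1098L))    # 999 nt CDS
  counts[101:200] <- 1L                              # 100 counts in CDS
  filler <- SampleLibrary("s1", list(tx1 = counts))
  r <- rpkm(filler, tx, "cds")
  expect_equal(unname(r),
               100 / (999 / 1e3) / (sum(counts) / 1e6))
  lib2 <- SampleLibrary("s2", list(tx1 = counts * 5L))
  expect_equal(unname(rpkm(lib2, tx, "cds")), unname(r))  # scale invariant
  expect_equal(rpmScale(filler), 1e6 / sum(counts))
})
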