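cfgS <- simConfig(seed = 21, nGenes = 60, depth = 1e5)
simS <- simulateTranscriptome(cfgS)

test_that("the generator is deterministic given a seed", {
  sim2 <- simulateTranscriptome(simConfig(seed = 21, nGenes = 60,
                                          depth = 1e5))
  expect_identical(as.character(txSequences(simS$transcriptome)),
                   as.character(txSequences(sim2$transcriptome)))
  expect_identical(simS$truth$anchors, sim2$truth$anchors)
  r1 <- simulateFootprints(simS, "control", "s", cfgS, seed = 4,
                           materializeReads = TRUE)
  r2 <- simulateFootprints(simS, "control", "s", cfgS, seed = 4,
                           materializeReads = TRUE)
  expect_identical(r1$reads, r2$reads)
  i1 <- simulateIclip(simS, cfgS, nReads = 500, seed = 8)
  i2 <- simulateIclip(simS, cfgS, nReads = 500, seed = 8)
  expect_identical(i1, i2)
})

test_that("gene classes carry the advertised sequence architecture", {
  g <- simS$truth$genes
  an <- simS$truth$anchors
  erg <- g$transcript_id[g$class == "ERG"]
  irg <- g$transcript_id[g$class == "IRG"]
  # every ERG-like gene has an AG run of length >= 4 within codons 5-50
  # and a short TISU-like 5'UTR
  for (id in erg) {
    a <- an[an$transcript_id == id & an$class == "AG" &
              an$region == "cds", ]
    expect_true(any(a$codon <= 50 & a$length >= 4))
  }
  expect_true(all(utr5Length(simS$transcriptome)[erg] <= 15))
  expect_true(all(utr5Length(simS$transcriptome)[irg] >= 130))
  # IRG-like genes carry 5'UTR anchors
  expect_true(all(irg %in% an$transcript_id[an$region == "utr5"]))
  # planted anchors are real motifs in the sequence (scan recovers them)
  scan <- findMotifs(simS$transcriptome, "cds", 4, "AG")
  planted <- an[an$region == "cds" & an$class == "AG", ]
  key <- function(d) paste(d$transcript_id, d$start)
  expect_true(all(key(planted) %in% key(scan)))
  # and the scan finds nothing else: planted anchors are the only AG motifs
  expect_setequal(key(scan), key(planted))
})

test_that("CDSs are ATG-initiated with a single terminal stop", {
  seqs <- as.character(txSequences(simS$transcriptome))
  cs <- cdsStart(simS$transcriptome); ce <- cdsEnd(simS$transcriptome)
  for (id in sample(names(seqs), 10)) {
    cds <- substr(seqs[[id]], cs[[id]] + 1, ce[[id]])
    expect_equal(substr(cds, 1, 3), "ATG")
    cods <- substring(cds, seq(1, nchar(cds) - 2, 3),
                      seq(3, nchar(cds), 3))
    expect_true(cods[length(cods)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("materialized reads conserve counts and stay on the transcript", {
  fp <- simulateFootprints(simS, "control", "s", cfgS, seed = 31,
                           materializeReads = TRUE)
  expect_equal(nrow(fp$reads), librarySize(fp$library))
  txlen <- txLengths(simS$transcriptome)
  expect_true(all(fp$reads$five_prime_pos >= 0))
  expect_true(all(fp$reads$five_prime_pos + fp$reads$read_length <=
                    txlen[fp$reads$transcript_id]))
})

test_that("regimes shift body counts in the expected directions", {
  cfg <- simConfig(seed = 42, nGenes = 300, depth = 1e6)
  sim <- simulateTranscriptome(cfg)
  lc <- simulateFootprints(sim, "control", "c", cfg, seed = 1)$library
  lt <- simulateFootprints(sim, c("elongation_stall", "initiation_block"),
                           "t", cfg, seed = 2)$library
  cm <- buildCountMatrix(list(lc, lt), sim$transcriptome)
  sf <- medianRatioSizeFactors(cm)
  norm <- sweep(cm, 2, sf, "/")
  lfc <- log2((norm[, 2] + 0.5) / (norm[, 1] + 0.5))
  cls <- sim$truth$genes$class
  expect_gt(median(lfc[cls == "ERG"]), 0.5)
  expect_lt(median(lfc[cls == "IRG"]), -0.5)
  expect_lt(abs(median(lfc[cls == "background"])), 0.15)
  # initiation block leaves polarity essentially unchanged for IRGs,
  # the stall shifts ERG polarity negative
  dp <- deltaPolarity(list(treatment = "t", control = "c"),
                      list(c = lc, t = lt), sim$transcriptome)
  expect_lt(median(dp[cls == "ERG"], na.rm = TRUE), -0.02)
  expect_lt(abs(median(dp[cls == "IRG"], na.rm = TRUE)), 0.02)
})

test_that("disome reads are 55-65 nt and concentrate in stalled early CDS", {
  cfg <- simConfig(seed = 14, nGenes = 150, depth = 5e5)
  sim <- simulateTranscriptome(cfg)
  dt <- simulateDisomes(sim, "elongation_stall", "dt", cfg, seed = 3)
  dc <- simulateDisomes(sim, "control", "dc", cfg, seed = 4)
  expect_true(all(dt$reads$read_length >= 55 & dt$reads$read_length <= 65))
  expect_equal(nrow(dt$reads), librarySize(dt$library))
  erg <- sim$truth$genes$transcript_id[sim$truth$genes$class == "ERG"]
  cs <- cdsStart(sim$transcriptome)
  dens50 <- function(lib) {
    sc <- rpmScale(lib)
    mean(vapply(erg, function(id)
      sum(track(lib, id)[(cs[[id]] + 1):(cs[[id]] + 150)]) * sc,
      numeric(1)))
  }
  expect_gt(dens50(dt$library), 2 * dens50(dc$library))
})

test_that("written transcriptome files round-trip through the readers", {
  dir <- tempfile()
  writeSimulatedTranscriptome(simS, dir, cfgS)
  tx <- readTranscriptome(file.path(dir, "transcriptome.fa"),
                          file.path(dir, "cds_annotation.tsv"))
  expect_equal(sort(txIds(tx)), sort(txIds(simS$transcriptome)))
  expect_equal(cdsStart(tx)[txIds(tx)],
               cdsStart(simS$transcriptome)[txIds(tx)])
})
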