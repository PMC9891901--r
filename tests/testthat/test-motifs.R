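# brute-force motif oracle: check every substring for class membership and
# maximality
motifOracle <- function(s, k, letters) {
  hits <- integer(0)
  chars <- strsplit(s, "")[[1]]
  inClass <- chars %in% letters
  n <- nchar(s)
  for (i in seq_len(n)) {
    if (!inClass[i]) next
    if (i > 1 && inClass[i - 1]) next          # not a run start
    j <- i
    while (j < n && inClass[j + 1]) j <- j + 1
    if (j - i + 1 >= k) hits <- c(hits, i - 1) # 0-based
  }
  hits
}

mkTx <- function(seqs, cds_start, cds_end) {
  ids <- paste0("t", seq_along(seqs))
  Transcriptome(stats::setNames(seqs, ids),
                data.frame(transcript_id = ids,
                           gene_id = paste0("g", seq_along(seqs)),
                           cds_start = cds_start, cds_end = cds_end))
}

test_that("motif scan anchors maximal runs and handles both alphabets", {
  tx <- mkTx("TTAGAGATTCGG", 0L, 12L)
  m45 <- findMotifs(tx, "cds", kSet = 4:5, alphabet = "AG")
  expect_equal(m45$start, c(2, 2))             # run AGAGA at 0-based 2
  expect_equal(sort(m45$k), c(4, 5))
  expect_equal(nrow(findMotifs(mkTx("TTTTTTTTT", 0L, 9L), "cds",
                               kSet = 4, alphabet = "AG")), 0)
  # AAAA matches under both alphabet classes
  txA <- mkTx("TTAAAATTT", 0L, 9L)
  expect_equal(nrow(findMotifs(txA, "cds", 4, "AG")), 1)
  expect_equal(nrow(findMotifs(txA, "cds", 4, "AC")), 1)
  # N breaks a run
  txN <- mkTx("TTAGNGATT", 0L, 9L)
  expect_equal(nrow(findMotifs(txN, "cds", 4, "AG")), 0)
})

test_that("motif scan agrees with a brute-force substring check", {
  set.seed(404)
  for (i in 1:100) {
    n <- sample(30:120, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    len <- n - (n %% 3)
    tx <- mkTx(substr(s, 1, len), 0L, as.integer(len))
    for (al in c("AG", "AC")) {
      k <- sample(4:6, 1)
      got <- findMotifs(tx, "cds", k, al)$start
      want <- motifOracle(substr(s, 1, len), k, strsplit(al, "")[[1]])
      expect_equal(sort(got), sort(want))
    }
  }
})

test_that("window enrichment is 1 for identical libraries and filters work", {
  set.seed(55)
  cfg <- simConfig(seed = 55, nGenes = 40, depth = 1e5)
  sim <- simulateTranscriptome(cfg)
  lib <- simulateFootprints(sim, "control", "x", cfg, seed = 1)$library
  erg <- sim$truth$genes$transcript_id[sim$truth$genes$class == "ERG"]
  an <- sim$truth$anchors
  ag <- an[an$region == "cds" & an$class == "AG" &
             an$transcript_id %in% erg, ]
  res <- motifWindowEnrichment(ag, list(lib), list(lib),
                               sim$transcriptome, w = 50)
  expect_true(all(abs(res$enrichment_ratio - 1) < 1e-12, na.rm = TRUE))
  expect_equal(res$p_value, 1, tolerance = 1e-9)

  # a window with fewer than 10 pooled counts is excluded
  expect_error(
    motifWindowEnrichment(ag, list(lib), list(lib), sim$transcriptome,
                          w = 50, minCounts = .Machine$integer.max),
    "survive")
})

test_that("edge exclusion removes anchors near region boundaries", {
  chars <- rep("T", 300)
  chars[61:64] <- c("A", "G", "A", "G")   # anchor at 0-based 60
  chars[151:154] <- c("G", "A", "G", "A") # anchor at 0-based 150
  chars[21:24] <- c("A", "G", "G", "A")   # anchor at 20: inside the edge
  tx <- mkTx(paste(chars, collapse = ""), 0L, 300L)
  m <- findMotifs(tx, "cds", 4, "AG")
  expect_setequal(m$start, c(20, 60, 150))
  set.seed(77)
  lib <- SampleLibrary("s", list(t1 = as.integer(rpois(300, 3)) + 1L))
  res <- motifWindowEnrichment(rbind(m, m), list(lib), list(lib),
                               tx, w = 50, edgeExcl = 50)
  expect_equal(res$n_motifs, 2)           # duplicates collapse, edge anchor out
  expect_error(motifWindowEnrichment(m, list(lib), list(lib), tx,
                                     w = 50, edgeExcl = 120),
               "survive")                 # tighter edges exclude everything
})

test_that("welch test matches the textbook formula and known cases", {
  expect_equal(unname(welchT(c(1, 2, 3), c(1, 2, 3))[c("t", "p")]),
               c(0, 1))
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  got <- welchT(x, y)
  # independent evaluation of the Welch statistic
  se <- sqrt(var(x) / 4 + var(y) / 4)
  tt <- (mean(x) - mean(y)) / se
  df <- (var(x) / 4 + var(y) / 4)^2 /
    ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  p <- 2 * pt(-abs(tt), df)
  expect_equal(unname(got["t"]), tt, tolerance = 1e-10)
  expect_equal(unname(got["p"]), p, tolerance = 1e-10)
  set.seed(9)
  for (i in 1:100) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.4)
    g <- welchT(a, b)
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    tt <- (mean(a) - mean(b)) / se
    df <- se^4 / ((var(a) / length(a))^2 / (length(a) - 1) +
                    (var(b) / length(b))^2 / (length(b) - 1))
    expect_equal(unname(g["t"]), tt, tolerance = 1e-10)
    expect_equal(unname(g["p"]), 2 * pt(-abs(tt), df), tolerance = 1e-10)
  }
  expect_equal(unname(welchT(x * 3, y * 3)["t"]), tt <- unname(got["t"]))
  expect_error(welchT(1, c(1, 2)), "at least 2")
})

test_that("kmer enrichment is 1 for identical libraries and honors retention", {
  set.seed(202)
  targets <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""),
    character(1))
  reads <- vapply(1:300, function(i) {
    t <- sample(5, 1); s <- sample(171, 1)
    substr(targets[t], s, s + 29)
  }, character(1))
  res <- iclipKmerEnrichment(reads, reads, targets, kSet = 4)
  ok <- !is.na(res$table$ratio)
  expect_true(all(abs(res$table$ratio[ok] - 1) < 1e-12))
  expect_equal(unname(res$retained), c(300L, 300L))

  # a read absent from all targets contributes to neither library
  alien <- strrep("T", 30)
  res2 <- iclipKmerEnrichment(c(reads, alien), c(reads, alien), targets,
                              kSet = 4)
  expect_equal(unname(res2$retained), c(300L, 300L))
  expect_error(iclipKmerEnrichment(alien, reads, targets), "zero retained")
})

test_that("constructed AG oversampling is detected by the kmer ratio test", {
  set.seed(303)
  cfg <- simConfig(seed = 303, nGenes = 120, depth = 1e5)
  sim <- simulateTranscriptome(cfg)
  ic <- simulateIclip(sim, cfg, nReads = 4000, oversample = 3, seed = 5)
  erg <- sim$truth$genes$transcript_id[sim$truth$genes$class == "ERG"]
  cs <- cdsStart(sim$transcriptome); ce <- cdsEnd(sim$transcriptome)
  seqs <- as.character(txSequences(sim$transcriptome))
  targets <- substr(seqs[erg], cs[erg] + 1, ce[erg])
  res <- iclipKmerEnrichment(ic$treatment, ic$control, targets)
  tab <- res$table[!is.na(res$table$ratio), ]
  expect_gt(mean(tab$ratio[tab$is_class]), mean(tab$ratio[!tab$is_class]))
  expect_lt(res$p_value, 0.05)
  # the null (oversample 1) shows no enrichment signal
  ic0 <- simulateIclip(sim, cfg, nReads = 4000, oversample = 1, seed = 6)
  res0 <- iclipKmerEnrichment(ic0$treatment, ic0$control, targets)
  tab0 <- res0$table[!is.na(res0$table$ratio), ]
  expect_lt(abs(mean(tab0$ratio[tab0$is_class]) - 1), 0.25)
})
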