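# independent step-up BH oracle
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

test_that("body counts exclude the first 15 and last 5 codons", {
  tx <- Transcriptome(
    c(tx1 = strrep("ACGTT", 66)),               # 330 nt
    data.frame(transcript_id = "tx1", gene_id = "g1",
               cds_start = 12L, cds_end = 312L)) # 100 codons
  uni <- rep(0L, 330); uni[13:312] <- 1L         # 3 per codon
  lib <- SampleLibrary("s1", list(tx1 = uni))
  cm <- buildCountMatrix(list(lib), tx)
  expect_equal(unname(cm[1, 1]), 80 * 3)         # 100 - 15 - 5 codons

  onlyStart <- rep(0L, 330); onlyStart[13:(12 + 45)] <- 2L  # codons 1-15
  cm2 <- buildCountMatrix(list(SampleLibrary("s", list(tx1 = onlyStart))),
                          tx)
  expect_equal(unname(cm2[1, 1]), 0)
})

test_that("degenerate short CDS genes are flagged and excluded", {
  tx <- Transcriptome(
    c(tx1 = strrep("ACGTT", 24)),                # 120 nt
    data.frame(transcript_id = "tx1", gene_id = "g1",
               cds_start = 12L, cds_end = 72L))  # 20 codons
  lib <- SampleLibrary("s1", list(tx1 = rep(1L, 120)))
  cm <- buildCountMatrix(list(lib), tx)
  expect_equal(unname(cm[1, 1]), 0)
  expect_equal(attr(cm, "flagged"), "g1")
})

test_that("median-of-ratios size factors match the hand-computed example", {
  m <- cbind(s1 = c(1, 2, 4), s2 = c(2, 4, 8))
  expect_equal(unname(medianRatioSizeFactors(m)),
               c(1 / sqrt(2), sqrt(2)))
  ident <- cbind(a = c(5, 9, 2), b = c(5, 9, 2))
  expect_equal(unname(medianRatioSizeFactors(ident)), c(1, 1))
  # a gene with a zero is excluded from the median
  withZero <- cbind(a = c(1, 2, 0), b = c(2, 4, 10))
  expect_equal(unname(medianRatioSizeFactors(withZero)),
               unname(medianRatioSizeFactors(withZero[1:2, ])))
  expect_warning(medianRatioSizeFactors(cbind(a = c(0, 1), b = c(1, 0))),
                 "falling back")
})

test_that("identical conditions give log2FC 0 and p 1; large means match arithmetic", {
  set.seed(2)
  base <- matrix(rpois(50 * 3, 100), 50, 3)
  m <- cbind(base, base)
  rownames(m) <- paste0("g", 1:50)
  res <- nbTest(m, rep(c("T", "C"), each = 3), "T", "C")
  expect_equal(res$log2FC, rep(0, 50))
  expect_equal(res$p_value, rep(1, 50))

  m2 <- cbind(t1 = rep(8000L, 30), t2 = rep(8000L, 30),
              c1 = rep(2000L, 30), c2 = rep(2000L, 30))
  rownames(m2) <- paste0("g", 1:30)
  res2 <- nbTest(m2, c("T", "T", "C", "C"), "T", "C",
                 sizeFactors = rep(1, 4))
  expect_true(all(abs(res2$log2FC - 2) < 1e-3))  # pseudocount negligible
})

test_that("the NB test is calibrated near alpha = 0.05 on a Poisson null", {
  set.seed(510)
  lam <- 10^runif(2000, 1.5, 3)
  m <- matrix(rpois(2000 * 6, rep(lam, 6)), ncol = 6)
  rownames(m) <- paste0("g", 1:2000)
  res <- nbTest(m, rep(c("T", "C"), each = 3), "T", "C")
  typeI <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_gte(typeI, 0.03)
  expect_lte(typeI, 0.07)
})

test_that("swapping condition labels negates log2FC exactly", {
  set.seed(77)
  m <- matrix(rnbinom(200 * 6, mu = 150, size = 10), 200, 6)
  rownames(m) <- paste0("g", 1:200)
  cond <- rep(c("T", "C"), each = 3)
  a <- nbTest(m, cond, "T", "C")
  b <- nbTest(m, cond, "C", "T")
  expect_equal(a$log2FC, -b$log2FC)
  expect_equal(a$p_value, b$p_value)
})

test_that("all-zero genes are reported as NA", {
  m <- rbind(g1 = rep(0L, 4), g2 = c(10L, 12L, 9L, 11L))
  res <- nbTest(m, c("T", "T", "C", "C"), "T", "C",
                sizeFactors = rep(1, 4))
  expect_true(is.na(res$log2FC[1]) && is.na(res$p_value[1]))
  expect_false(is.na(res$p_value[2]))
})

test_that("BH adjustment matches the worked example and a brute-force oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.33), 0.33)
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  set.seed(66)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
  }
  # permutation invariance up to reordering
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
})

test_that("classification applies the inclusive lfc and q cutoffs", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   baseMean = 100,
                   log2FC = c(1.2, -1.2, 2, 0.5),
                   p_value = c(1e-6, 1e-6, 0.5, 1e-6))
  res <- classifyGenes(de)
  expect_equal(res$class, c("ERG", "IRG", "NS", "NS"))
  expect_equal(attr(res, "erg"), "a")
  expect_equal(attr(res, "irg"), "b")
  expect_true(all(res$q_value >= res$p_value, na.rm = TRUE))
})
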