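#' Body-of-CDS count matrix
#'
#' Per gene and sample, the total P-site count over CDS codons 16..(L-5),
#' i.e. excluding the first 15 and the last 5 codons, so that start/stop
#' proximal piling does not drive the differential test.  Genes whose CDS
#' has 20 codons or fewer get a count of 0 and are listed in the
#' \code{"flagged"} attribute (they carry no body region and are excluded
#' from testing).
#'
#' @param libraries named list of \linkS4class{SampleLibrary} objects (the
#'   columns, in order).
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param excludeStart,excludeEnd codons trimmed from the CDS ends
#'   (defaults 15 and 5).
#' @return integer matrix genes x samples (rownames = gene ids), with
#'   attribute \code{flagged} naming degenerate genes.
#' @export
buildCountMatrix <- function(libraries, transcriptome,
                             excludeStart = 15, excludeEnd = 5) {
  ids <- txIds(transcriptome)
  genes <- geneIds(transcriptome)
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  Lc <- (ce - cs) %/% 3L
  flagged <- genes[Lc <= excludeStart + excludeEnd]
  mat <- vapply(libraries, function(lib) {
    vapply(ids, function(id) {
      L <- Lc[[id]]
      if (L <= excludeStart + excludeEnd) return(0L)
      from <- cs[[id]] + 3L * excludeStart + 1L
      to <- cs[[id]] + 3L * (L - excludeEnd)
      as.integer(sum(track(lib, id)[from:to]))
    }, integer(1))
  }, integer(length(ids)))
  mat <- matrix(mat, ncol = length(libraries),
                dimnames = list(unname(genes[ids]),
                                vapply(libraries, sampleId, character(1))))
  attr(mat, "flagged") <- unname(flagged)
  mat
}

#' Median-of-ratios size factors
#'
#' For genes with non-zero counts in every sample, the per-sample median of
#' count / geometric-mean-across-samples.  When no gene is non-zero
#' everywhere, falls back to total-count ratios (normalized to geometric
#' mean 1) with a warning.
#'
#' @param counts genes x samples count matrix.
#' @return numeric vector of per-sample size factors.
#' @examples
#' medianRatioSizeFactors(cbind(a = c(1, 2, 4), b = c(2, 4, 8)))
#' @export
medianRatioSizeFactors <- function(counts) {
  ok <- rowSums(counts == 0) == 0
  if (!any(ok)) {
    warning("no gene with non-zero counts in all samples; ",
            "falling back to total-count size factors")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  logc <- log(counts[ok, , drop = FALSE])
  geo <- rowMeans(logc)
  apply(exp(logc - geo), 2, median)
}

#' Negative-binomial Wald test for differential footprint counts
#'
#' A self-contained count-based test: counts are normalized by
#' median-of-ratios size factors; group means get a pseudocount
#' (default 0.5) for fold-change stability; per-gene NB dispersion is
#' estimated by method of moments on the normalized counts (pooled
#' within-group variance) and shrunk toward a local trend - the mean of the
#' raw (untruncated) moment estimates of the \code{nNeighbors} genes
#' closest in mean count - before flooring at zero; the null of equal
#' means is assessed by a Wald test on log(m_t / m_c) with delta-method
#' variance \code{(1/m + alpha)/n} per group, two-sided normal p.  With a
#' single replicate per condition the within-group variance is replaced by
#' the squared between-condition half-difference, so the trend (driven by
#' the mostly-null genes) supplies the dispersion.
#'
#' Genes with all-zero counts are reported as NA.
#'
#' @param counts genes x samples integer matrix.
#' @param condition character/factor per column.
#' @param treatment,control the two condition levels compared
#'   (treatment over control).
#' @param sizeFactors optional per-sample factors; computed from
#'   \code{counts} by \code{\link{medianRatioSizeFactors}} when NULL.
#' @param pseudocount added to normalized group means for the fold change.
#' @param nNeighbors window size of the dispersion trend.
#' @param shrinkWeight weight of the per-gene moment estimate relative to
#'   the trend (default 0.3).
#' @return data.frame: \code{gene_id}, \code{baseMean}, \code{log2FC},
#'   \code{p_value}.
#' @export
nbTest <- function(counts, condition, treatment, control,
                   sizeFactors = NULL, pseudocount = 0.5,
                   nNeighbors = 50, shrinkWeight = 0.3) {
  stopifnot(length(condition) == ncol(counts))
  tcols <- which(condition == treatment)
  ccols <- which(condition == control)
  if (!length(tcols) || !length(ccols))
    stop("both condition levels need at least one sample")
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)
  norm <- sweep(counts, 2, sizeFactors, "/")
  nt <- length(tcols); nc <- length(ccols)
  mt <- rowMeans(norm[, tcols, drop = FALSE])
  mc <- rowMeans(norm[, ccols, drop = FALSE])
  mu <- (nt * mt + nc * mc) / (nt + nc)

  if (nt + nc > 2) {
    vt <- if (nt > 1) apply(norm[, tcols, drop = FALSE], 1, var) else 0
    vc <- if (nc > 1) apply(norm[, ccols, drop = FALSE], 1, var) else 0
    s2 <- ((nt - 1) * vt + (nc - 1) * vc) / (nt + nc - 2)
  } else {
    s2 <- (norm[, tcols] - norm[, ccols])^2 / 2
  }
  rawAlpha <- ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)

  ord <- order(mu)
  trend <- rep(NA_real_, length(mu))
  okIdx <- ord[!is.na(rawAlpha[ord]) & mu[ord] > 0]
  if (length(okIdx)) {
    v <- rawAlpha[okIdx]
    w <- min(nNeighbors, length(v))
    cums <- c(0, cumsum(v))
    half <- w %/% 2
    nOk <- length(v)
    lo <- pmax(1, pmin(seq_len(nOk) - half, nOk - w + 1))
    hi <- pmin(nOk, lo + w - 1)
    trend[okIdx] <- (cums[hi + 1] - cums[lo]) / (hi - lo + 1)
  }
  alpha <- pmax(0, shrinkWeight * rawAlpha + (1 - shrinkWeight) * trend)
  alpha[is.na(alpha)] <- 0

  log2FC <- log2((mt + pseudocount) / (mc + pseudocount))
  seLog <- sqrt((1 / (mt + pseudocount) + alpha) / nt +
                (1 / (mc + pseudocount) + alpha) / nc)
  z <- log((mt + pseudocount) / (mc + pseudocount)) / seLog
  p <- 2 * pnorm(-abs(z))
  allZero <- rowSums(counts) == 0
  log2FC[allZero] <- NA_real_
  p[allZero] <- NA_real_
  data.frame(gene_id = rownames(counts), baseMean = mu, log2FC = log2FC,
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotonicity enforced,
#' order-preserving); backed by \code{stats::p.adjust}.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return q-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify genes as elongation- or initiation-repressed
#'
#' Adds BH q-values and the three-way class to a differential test result:
#' ERG (elongation-repressed, footprint counts up) when log2FC >= lfcCutoff
#' and q <= qCutoff; IRG (initiation-repressed, counts down) when
#' log2FC <= -lfcCutoff and q <= qCutoff; NS otherwise.
#'
#' @param de data.frame from \code{\link{nbTest}}.
#' @param lfcCutoff absolute log2 fold-change cutoff (inclusive,
#'   default 1).
#' @param qCutoff q-value cutoff (inclusive, default 0.05).
#' @return the input with \code{q_value} and \code{class} columns; gene-id
#'   sets in attributes \code{erg} and \code{irg}.
#' @export
classifyGenes <- function(de, lfcCutoff = 1, qCutoff = 0.05) {
  de$q_value <- bhAdjust(de$p_value)
  cls <- rep("NS", nrow(de))
  cls[!is.na(de$q_value) & de$q_value <= qCutoff &
        de$log2FC >= lfcCutoff] <- "ERG"
  cls[!is.na(de$q_value) & de$q_value <= qCutoff &
        de$log2FC <= -lfcCutoff] <- "IRG"
  de$class <- cls
  attr(de, "erg") <- de$gene_id[cls == "ERG"]
  attr(de, "irg") <- de$gene_id[cls == "IRG"]
  de
}
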