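#' Polarity score of ribosome density along a CDS
#'
#' Summarizes where along the CDS ribosome density sits: for codon-level
#' densities d_1..d_L the score is sum(d_i * w_i) / sum(d_i) with weights
#' w_i = (2i - (L + 1)) / (L - 1), i = 1..L, so a transcript with all
#' density on the first codon scores -1, on the last codon +1, and a
#' uniform transcript 0.  Codon density is the sum of the three nucleotide
#' P-site counts of the codon.  The score is undefined (NA) when the CDS
#' carries no counts, and is invariant under scaling of the densities.
#'
#' @param counts per-nucleotide P-site counts for one transcript.
#' @param cds_start,cds_end CDS coordinates, 0-based half-open.
#' @return polarity in [-1, 1], or NA when the CDS has zero counts.
#'   Errors when the CDS has fewer than 2 codons.
#' @examples
#' polarityScore(c(1, 0, 0, 0, 0, 0, 3, 0, 0), 0, 9)  # L=3, d=(1,0,3): 0.5
#' @export
polarityScore <- function(counts, cds_start, cds_end) {
  d <- codonDensities(counts, cds_start, cds_end)
  L <- length(d)
  if (L < 2) stop("polarity needs a CDS of at least 2 codons")
  tot <- sum(d)
  if (tot == 0) return(NA_real_)
  i <- seq_len(L)
  w <- (2 * i - (L + 1)) / (L - 1)
  sum(d * w) / tot
}

codonDensities <- function(counts, cds_start, cds_end) {
  cds <- counts[(cds_start + 1L):cds_end]
  colSums(matrix(cds, nrow = 3L))
}

#' Per-transcript polarity for a whole library
#'
#' @param library A \linkS4class{SampleLibrary}.
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @return named numeric vector of polarity scores (NA where undefined).
#' @export
polarity <- function(library, transcriptome) {
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  ids <- txIds(transcriptome)
  vapply(setNames(ids, ids), function(id) {
    x <- track(library, id)
    if (is.null(x)) return(NA_real_)
    polarityScore(x, cs[[id]], ce[[id]])
  }, numeric(1))
}

#' Polarity change between a treatment and its control
#'
#' Replicates are averaged within each group before differencing, so one
#' delta is reported per condition pair; transcripts with no defined
#' polarity in either group are omitted (NA).
#'
#' @param pair list with elements \code{pair_id}, \code{treatment} and
#'   \code{control} (character vectors of sample ids) and optionally
#'   \code{label}.
#' @param libraries named list of \linkS4class{SampleLibrary} objects.
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @return named numeric vector: treatment minus control mean polarity per
#'   transcript (NA where undefined in either group).
#' @export
deltaPolarity <- function(pair, libraries, transcriptome) {
  groupMean <- function(sampleIds) {
    m <- vapply(sampleIds, function(s)
      polarity(libraries[[s]], transcriptome),
      numeric(length(txIds(transcriptome))))
    m <- matrix(m, ncol = length(sampleIds),
                dimnames = list(txIds(transcriptome), sampleIds))
    out <- rowMeans(m, na.rm = TRUE)
    out[rowSums(!is.na(m)) == 0] <- NA_real_
    out
  }
  groupMean(pair$treatment) - groupMean(pair$control)
}

#' Transcript filter for condition clustering
#'
#' Keeps transcripts with CDS RPKM above \code{minRpkm} in every sample of
#' every condition pair and with mean coverage (fraction of CDS codons
#' carrying at least one P-site count, averaged over all samples) strictly
#' greater than the grand mean of that quantity over all transcripts.
#'
#' @param pairs list of condition-pair lists (see
#'   \code{\link{deltaPolarity}}).
#' @param libraries named list of \linkS4class{SampleLibrary} objects.
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param minRpkm RPKM threshold (strict; default 1).
#' @return character vector of surviving transcript ids; hard error when
#'   empty.
#' @export
filterTranscriptsForClustering <- function(pairs, libraries, transcriptome,
                                           minRpkm = 1) {
  stopifnot(length(pairs) >= 1)
  samples <- unique(unlist(lapply(pairs, function(p)
    c(p$treatment, p$control))))
  ids <- txIds(transcriptome)
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  rpkmMat <- vapply(samples, function(s)
    rpkm(libraries[[s]], transcriptome, "cds"), numeric(length(ids)))
  rpkmMat <- matrix(rpkmMat, ncol = length(samples),
                    dimnames = list(ids, samples))
  covMat <- vapply(samples, function(s) {
    vapply(ids, function(id) {
      d <- codonDensities(track(libraries[[s]], id), cs[[id]], ce[[id]])
      mean(d >= 1)
    }, numeric(1))
  }, numeric(length(ids)))
  covMat <- matrix(covMat, ncol = length(samples),
                   dimnames = list(ids, samples))
  meanCov <- rowMeans(covMat)
  keep <- apply(rpkmMat > minRpkm, 1, all) & meanCov > mean(meanCov)
  if (!any(keep))
    stop("no transcript survives the RPKM/coverage filter")
  ids[keep]
}

#' Hierarchical clustering of perturbation conditions
#'
#' Agglomerative clustering of condition pairs (columns of the delta-
#' polarity matrix) with Ward linkage on the euclidean metric
#' (\code{hclust} method \code{"ward.D2"}, the Ward criterion on euclidean
#' distances).  Transcripts with any missing delta are dropped listwise
#' beforehand, since Ward/euclidean requires complete vectors.
#'
#' @param deltaMatrix numeric matrix, transcripts x condition pairs.
#' @param k number of flat clusters to cut (default 2).
#' @return list with \code{hclust} (the merge tree), \code{labels} (named
#'   integer vector over pairs), \code{transcripts} (rows used),
#'   \code{method}, \code{metric}.
#' @export
clusterConditions <- function(deltaMatrix, k = 2) {
  complete <- stats::complete.cases(deltaMatrix)
  m <- deltaMatrix[complete, , drop = FALSE]
  if (ncol(m) < 2) stop("need at least 2 condition pairs")
  if (ncol(m) < k) stop("fewer condition pairs than clusters requested")
  hc <- hclust(dist(t(m), method = "euclidean"), method = "ward.D2")
  labels <- cutree(hc, k = k)
  list(hclust = hc, labels = labels,
       transcripts = rownames(deltaMatrix)[complete],
       method = "ward.D2", metric = "euclidean")
}
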