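#' Start/stop-anchored metagene profile
#'
#' Average positional ribosome density over many transcripts aligned at the
#' start or stop codon, at codon resolution.  Eligible transcripts (CDS
#' longer than \code{minLen} codons, CDS RPKM above \code{minRpkm}, at
#' least \code{minCount} raw CDS counts) are first scaled to RPM, then each
#' transcript's codon-density vector is divided by its own mean CDS codon
#' density, so the profile of a uniform transcript is identically 1 and the
#' result is invariant to library-size rescaling.  The profile value at a
#' position is the mean over the transcripts that extend to that position;
#' \code{n_transcripts} records how many do.
#'
#' Codons upstream of the start (or downstream of the stop) are taken from
#' the UTRs on the reading-frame grid anchored at the CDS.
#'
#' @param library A \linkS4class{SampleLibrary}.
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param anchor \code{"start"} or \code{"stop"}.
#' @param u,d codons upstream/downstream of the start codon retained
#'   (positions -u..+d around the start; -d..+u around the stop).
#' @param minLen eligibility: CDS length must exceed this many codons.
#' @param minRpkm eligibility: CDS RPKM must exceed this (strict).
#' @param minCount eligibility: minimum raw CDS P-site count.
#' @return data.frame with \code{position} (codons relative to the anchor),
#'   \code{mean_density}, \code{n_transcripts}.  Errors when no transcript
#'   is eligible.
#' @export
metageneProfile <- function(library, transcriptome,
                            anchor = c("start", "stop"),
                            u = 100, d = 400, minLen = 100, minRpkm = 10,
                            minCount = 1) {
  anchor <- match.arg(anchor)
  ids <- txIds(transcriptome)
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  txlen <- txLengths(transcriptome)
  rp <- rpkm(library, transcriptome, "cds")
  scale <- rpmScale(library)

  axis <- if (anchor == "start") (-u):d else (-d):u
  acc <- numeric(length(axis))
  n <- integer(length(axis))
  used <- 0L
  for (id in ids) {
    Lc <- (ce[[id]] - cs[[id]]) %/% 3L
    if (Lc <= minLen || rp[[id]] <= minRpkm) next
    x <- track(library, id)
    cdsCounts <- sum(x[(cs[[id]] + 1L):ce[[id]]])
    if (cdsCounts < minCount) next
    dens <- x * scale
    cdsCodons <- codonDensities(dens, cs[[id]], ce[[id]])
    m <- mean(cdsCodons)
    if (m == 0) next
    nUp <- cs[[id]] %/% 3L
    upstream <- if (nUp > 0) {
      upSpan <- dens[(cs[[id]] - 3L * nUp + 1L):cs[[id]]]
      colSums(matrix(upSpan, nrow = 3L))
    } else numeric(0)
    nDown <- (txlen[[id]] - ce[[id]]) %/% 3L
    downstream <- if (nDown > 0) {
      dnSpan <- dens[(ce[[id]] + 1L):(ce[[id]] + 3L * nDown)]
      colSums(matrix(dnSpan, nrow = 3L))
    } else numeric(0)
    full <- c(upstream, cdsCodons, downstream) / m
    # position of each entry relative to the anchor codon
    pos <- if (anchor == "start") {
      seq_along(full) - nUp - 1L
    } else {
      seq_along(full) - (nUp + Lc)
    }
    sel <- pos >= axis[1] & pos <= axis[length(axis)]
    idx <- pos[sel] - axis[1] + 1L
    acc[idx] <- acc[idx] + full[sel]
    n[idx] <- n[idx] + 1L
    used <- used + 1L
  }
  if (used == 0L) stop("no transcript eligible for the metagene profile")
  mean_density <- ifelse(n > 0, acc / n, NA_real_)
  data.frame(position = axis, mean_density = mean_density,
             n_transcripts = n)
}

#' Ratio of density in the first 75 codons over the whole CDS
#'
#' \code{(counts on codons 1-75 / 75) / (counts on the CDS / L)}; 1 for a
#' uniform transcript, larger when density piles up early.  Undefined (NA)
#' for transcripts with a CDS shorter than 75 codons or with zero CDS
#' counts.
#'
#' @param counts per-nucleotide P-site counts of one transcript.
#' @param cds_start,cds_end CDS coordinates, 0-based half-open.
#' @param nCodons width of the early window in codons (default 75).
#' @return the ratio, or NA when undefined.
#' @export
first75Ratio <- function(counts, cds_start, cds_end, nCodons = 75) {
  d <- codonDensities(counts, cds_start, cds_end)
  L <- length(d)
  if (L < nCodons) return(NA_real_)
  tot <- sum(d)
  if (tot == 0) return(NA_real_)
  (sum(d[seq_len(nCodons)]) / nCodons) / (tot / L)
}

#' Per-transcript first-75-codon ratios for a library
#'
#' @param library A \linkS4class{SampleLibrary}.
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param nCodons early-window width in codons.
#' @return named numeric vector (NA where undefined).
#' @export
first75Ratios <- function(library, transcriptome, nCodons = 75) {
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  ids <- txIds(transcriptome)
  vapply(setNames(ids, ids), function(id)
    first75Ratio(track(library, id), cs[[id]], ce[[id]], nCodons),
    numeric(1))
}
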