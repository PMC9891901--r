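#' Base-quality filter for footprint reads
#'
#' A read is discarded when strictly more than \code{fracCutoff} of its
#' bases have Phred quality below \code{phredCutoff} (defaults: Phred 25,
#' 75\% of bases).  Reads without quality information pass with a one-time
#' notice, since simulated inputs and some BAMs carry no qualities.
#'
#' @param qualities character vector of Phred+33 quality strings (or a
#'   single numeric vector of Phred scores for one read).  \code{NA} or
#'   empty strings mean "no quality available".
#' @param phredCutoff Phred score below which a base counts as low quality.
#' @param fracCutoff fraction of low-quality bases above which the read is
#'   removed (strict inequality).
#' @return logical vector, \code{TRUE} = keep.
#' @examples
#' qualityFilter(rep(30, 10))                   # kept
#' qualityFilter(c(rep(20, 8), rep(30, 2)))     # 80% < 25: removed
#' @export
qualityFilter <- function(qualities, phredCutoff = 25, fracCutoff = 0.75) {
  if (is.numeric(qualities)) {
    return(mean(qualities < phredCutoff) <= fracCutoff)
  }
  noQual <- is.na(qualities) | !nzchar(qualities)
  if (any(noQual))
    message(sum(noQual), " read(s) without quality strings pass unfiltered")
  out <- rep(TRUE, length(qualities))
  if (any(!noQual)) {
    fracLow <- vapply(qualities[!noQual], function(q) {
      mean((utf8ToInt(q) - 33L) < phredCutoff)
    }, numeric(1), USE.NAMES = FALSE)
    out[!noQual] <- fracLow <= fracCutoff
  }
  out
}

#' Footprint length filter
#'
#' Inclusive length window: 15-45 nt for monosome footprints, 30-70 nt for
#' disome footprints.
#'
#' @param readLength integer vector of read lengths.
#' @param minLen,maxLen inclusive bounds; defaults taken from \code{mode}.
#' @param mode \code{"mono"} (15-45) or \code{"di"} (30-70).
#' @return logical vector, \code{TRUE} = keep.
#' @export
lengthFilter <- function(readLength, mode = c("mono", "di"),
                         minLen = NULL, maxLen = NULL) {
  mode <- match.arg(mode)
  bounds <- if (mode == "mono") c(15L, 45L) else c(30L, 70L)
  if (is.null(minLen)) minLen <- bounds[1]
  if (is.null(maxLen)) maxLen <- bounds[2]
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  readLength >= minLen & readLength <= maxLen
}

#' Calibrate P-site offsets and screen 3-nt periodicity
#'
#' For each read length L the P-site offset is the o in
#' \code{searchRange} (capped at L-1) maximizing the number of reads whose
#' 5' end plus o lands exactly on an annotated CDS start; ties take the
#' smaller offset.  Periodicity is then scored from the reading-frame
#' fractions of \code{(five_prime_pos + offset - cds_start) mod 3} over
#' reads with P-site inside the CDS; a length is kept when the dominant
#' frame fraction is at least \code{minScore} and at least \code{minReads}
#' reads were scored.
#'
#' @param reads read-record data.frame (see \code{\link{readAlignments}}).
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param searchRange candidate offsets in nt from the 5' end; default
#'   8..18 brackets the canonical ~12 nt 5'-to-P-site distance.
#' @param minScore minimum dominant-frame fraction (default 0.5).
#' @param minReads minimum reads needed to score a length (default 100).
#' @return list with \code{offsets} (named integer vector over kept
#'   lengths) and \code{report} (data.frame: \code{read_length},
#'   \code{offset}, \code{f0}, \code{f1}, \code{f2},
#'   \code{periodicity_score}, \code{n_reads}, \code{kept}).  Errors,
#'   printing the per-length report, when no length passes.
#' @export
calibrateOffsets <- function(reads, transcriptome, searchRange = 8:18,
                             minScore = 0.5, minReads = 100) {
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  readCs <- cs[reads$transcript_id]
  readCe <- ce[reads$transcript_id]
  lens <- sort(unique(reads$read_length))
  rows <- lapply(lens, function(L) {
    sel <- reads$read_length == L
    fp <- reads$five_prime_pos[sel]
    rcs <- readCs[sel]
    rce <- readCe[sel]
    cand <- searchRange[searchRange < L]
    if (!length(cand))
      return(data.frame(read_length = L, offset = NA_integer_, f0 = NA,
                        f1 = NA, f2 = NA, periodicity_score = NA,
                        n_reads = 0L, kept = FALSE))
    hits <- vapply(cand, function(o) sum(fp + o == rcs), integer(1))
    off <- cand[which.max(hits)]  # which.max takes the first = smallest
    psite <- fp + off
    inCds <- psite >= rcs & psite < rce
    n <- sum(inCds)
    if (n > 0) {
      fr <- (psite[inCds] - rcs[inCds]) %% 3
      f <- tabulate(fr + 1L, 3L) / n
    } else f <- rep(NA_real_, 3)
    data.frame(read_length = L, offset = off, f0 = f[1], f1 = f[2],
               f2 = f[3], periodicity_score = max(f), n_reads = n,
               kept = !is.na(max(f)) && max(f) >= minScore && n >= minReads)
  })
  report <- do.call(rbind, rows)
  if (!any(report$kept)) {
    print(report)
    stop("no read length passed periodicity screening (scores above)")
  }
  kept <- report[report$kept, , drop = FALSE]
  list(offsets = setNames(as.integer(kept$offset),
                          as.character(kept$read_length)),
       report = report)
}

#' Build per-sample P-site tracks
#'
#' Each read of a calibrated length increments the count at
#' \code{five_prime_pos + offset(read_length)} on its transcript.  Reads of
#' lengths absent from \code{offsets} (those failing periodicity) are not
#' counted; P-sites beyond the transcript end are skipped and counted in
#' the \code{"skipped_out_of_range"} attribute.
#'
#' @param reads read-record data.frame.
#' @param offsets named integer vector, read length -> offset (kept
#'   lengths only), e.g. from \code{\link{calibrateOffsets}}.
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param sampleId sample identifier for the resulting library.
#' @return A \linkS4class{SampleLibrary} covering every transcript of the
#'   transcriptome (zero tracks included).
#' @export
buildTracks <- function(reads, offsets, transcriptome, sampleId) {
  txlen <- txLengths(transcriptome)
  off <- offsets[as.character(reads$read_length)]
  keep <- !is.na(off)
  psite <- reads$five_prime_pos[keep] + off[keep]
  txid <- reads$transcript_id[keep]
  inRange <- psite < txlen[txid] & psite >= 0
  nskip <- sum(!inRange)
  psite <- psite[inRange]
  txid <- txid[inRange]
  ids <- txIds(transcriptome)
  trk <- lapply(setNames(ids, ids), function(id) integer(txlen[[id]]))
  if (length(psite)) {
    sp <- split(psite, txid)
    for (id in names(sp))
      trk[[id]] <- tabulate(sp[[id]] + 1L, nbins = txlen[[id]])
  }
  lib <- SampleLibrary(sampleId, trk)
  attr(lib, "skipped_out_of_range") <- nskip
  lib
}

#' Library-size normalization
#'
#' \code{rpmScale} returns the reads-per-million factor
#' \code{1e6 / librarySize}; \code{rpkm} computes reads per kilobase per
#' million mapped P-sites over the CDS or the full transcript.
#'
#' @param library A \linkS4class{SampleLibrary} with non-zero size.
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param region \code{"cds"} or \code{"full"}.
#' @return \code{rpm_scale}: a single number. \code{rpkm}: named numeric
#'   vector over transcripts.
#' @examples
#' # 100 counts on a 1000-nt CDS in a 1e6-read library -> RPKM 100
#' @export
rpmScale <- function(library) {
  if (librarySize(library) <= 0) stop("library size must be positive")
  1e6 / librarySize(library)
}

#' @rdname rpmScale
#' @export
rpkm <- function(library, transcriptome, region = c("cds", "full")) {
  region <- match.arg(region)
  if (librarySize(library) <= 0) stop("library size must be positive")
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  ids <- txIds(transcriptome)
  counts <- vapply(ids, function(id) {
    x <- track(library, id)
    if (is.null(x)) return(0)
    if (region == "cds") sum(x[(cs[[id]] + 1L):ce[[id]]]) else sum(x)
  }, numeric(1))
  len <- if (region == "cds") ce - cs else txLengths(transcriptome)
  if (any(len == 0)) stop("zero-length region")
  setNames(counts / (len / 1e3) / (librarySize(library) / 1e6), ids)
}
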