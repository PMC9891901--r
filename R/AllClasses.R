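#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   width subseq oligonucleotideFrequency PDict vwhichPDict translate
#' @importFrom stats rnbinom rpois rnorm runif rlnorm median quantile sd var
#'   hclust dist cutree t.test p.adjust pnorm setNames aggregate
#' @importFrom utils read.delim write.table head tail
NULL

#' Transcriptome: transcript sequences with CDS annotation
#'
#' Container for a set of transcript models: one nucleotide sequence per
#' transcript together with 0-based half-open CDS coordinates and the gene
#' each transcript represents.  All downstream statistics (P-site tracks,
#' polarity, metagene profiles, motif scans) operate on this object in
#' transcript coordinates.  A \code{Transcriptome} holds exactly one
#' representative transcript per gene (the longest; ties broken
#' lexicographically by transcript id).
#'
#' Invariants, enforced by the validity method: \code{0 <= cds_start <
#' cds_end <= length(sequence)}; CDS length divisible by 3; the 5'UTR
#' \code{[0, cds_start)}, CDS \code{[cds_start, cds_end)} and 3'UTR
#' \code{[cds_end, length)} partition each sequence.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet}, named by transcript id.
#' @slot txInfo A data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{cds_start}, \code{cds_end} (0-based half-open),
#'   one row per transcript, in the same order as \code{sequences}.
#'
#' @seealso \code{\link{readTranscriptome}}, \code{\link{Transcriptome}}
#' @export
setClass("Transcriptome",
  representation(sequences = "DNAStringSet", txInfo = "data.frame"))

setValidity("Transcriptome", function(object) {
  info <- object@txInfo
  need <- c("transcript_id", "gene_id", "cds_start", "cds_end")
  if (!all(need %in% names(info)))
    return(paste("txInfo must have columns", paste(need, collapse = ", ")))
  if (length(object@sequences) != nrow(info))
    return("sequences and txInfo length mismatch")
  if (!identical(names(object@sequences), info$transcript_id))
    return("sequence names must equal txInfo$transcript_id")
  if (anyDuplicated(info$transcript_id))
    return("duplicated transcript ids")
  if (anyDuplicated(info$gene_id))
    return("a gene may have only one representative transcript")
  len <- Biostrings::width(object@sequences)
  bad <- info$cds_start < 0 | info$cds_start >= info$cds_end |
    info$cds_end > len
  if (any(bad))
    return(paste("invalid CDS coordinates for",
                 paste(info$transcript_id[bad], collapse = ", ")))
  if (any((info$cds_end - info$cds_start) %% 3L != 0L))
    return("CDS length must be divisible by 3")
  TRUE
})

#' Construct a Transcriptome
#'
#' @param sequences A named \code{DNAStringSet} or named character vector of
#'   transcript sequences.
#' @param txInfo data.frame with \code{transcript_id}, \code{gene_id},
#'   \code{cds_start}, \code{cds_end} (0-based half-open).
#' @return A \linkS4class{Transcriptome}.
#' @examples
#' tx <- Transcriptome(
#'   c(tx1 = paste(rep("ACGT", 30), collapse = "")),
#'   data.frame(transcript_id = "tx1", gene_id = "g1",
#'              cds_start = 12, cds_end = 102))
#' cdsLength(tx)
#' @export
Transcriptome <- function(sequences, txInfo) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  txInfo <- as.data.frame(txInfo, stringsAsFactors = FALSE)
  txInfo$transcript_id <- as.character(txInfo$transcript_id)
  txInfo$gene_id <- as.character(txInfo$gene_id)
  txInfo$cds_start <- as.integer(txInfo$cds_start)
  txInfo$cds_end <- as.integer(txInfo$cds_end)
  sequences <- sequences[txInfo$transcript_id]
  rownames(txInfo) <- txInfo$transcript_id
  new("Transcriptome", sequences = sequences, txInfo = txInfo)
}

#' @describeIn Transcriptome-accessors transcript identifiers
#' @export
txIds <- function(object) object@txInfo$transcript_id

#' Accessors for Transcriptome objects
#'
#' @param object A \linkS4class{Transcriptome}.
#' @name Transcriptome-accessors
#' @return \code{txIds}, \code{geneIds}: character vectors. \code{cdsStart},
#'   \code{cdsEnd}, \code{txLengths}, \code{cdsLength}, \code{utr5Length},
#'   \code{utr3Length}: named integer vectors (coordinates 0-based
#'   half-open, lengths in nt).  \code{txSequences}: the
#'   \code{DNAStringSet}.
NULL

#' @describeIn Transcriptome-accessors gene identifiers
#' @export
geneIds <- function(object) {
  setNames(object@txInfo$gene_id, object@txInfo$transcript_id)
}

#' @describeIn Transcriptome-accessors CDS start (0-based inclusive)
#' @export
cdsStart <- function(object) {
  setNames(object@txInfo$cds_start, object@txInfo$transcript_id)
}

#' @describeIn Transcriptome-accessors CDS end (0-based exclusive)
#' @export
cdsEnd <- function(object) {
  setNames(object@txInfo$cds_end, object@txInfo$transcript_id)
}

#' @describeIn Transcriptome-accessors transcript lengths in nt
#' @export
txLengths <- function(object) {
  setNames(Biostrings::width(object@sequences),
           object@txInfo$transcript_id)
}

#' @describeIn Transcriptome-accessors CDS length in nt
#' @export
cdsLength <- function(object) cdsEnd(object) - cdsStart(object)

#' @describeIn Transcriptome-accessors 5'UTR length in nt
#' @export
utr5Length <- function(object) cdsStart(object)

#' @describeIn Transcriptome-accessors 3'UTR length in nt
#' @export
utr3Length <- function(object) txLengths(object) - cdsEnd(object)

#' @describeIn Transcriptome-accessors transcript sequences
#' @export
txSequences <- function(object) object@sequences

setMethod("show", "Transcriptome", function(object) {
  n <- length(object@sequences)
  cat("Transcriptome with", n, "transcripts (one per gene)\n")
  if (n) {
    cat("  transcript length: ",
        paste(range(Biostrings::width(object@sequences)), collapse = "-"),
        " nt; CDS length: ",
        paste(range(cdsLength(object)), collapse = "-"), " nt\n", sep = "")
  }
})

#' @export
setMethod("length", "Transcriptome", function(x) length(x@sequences))

#' SampleLibrary: per-sample P-site count tracks
#'
#' One sequencing library reduced to per-nucleotide P-site counts: a named
#' list with one non-negative integer vector per transcript (length equal to
#' the transcript length) plus the total number of mapped P-sites.  The
#' reads-per-million scale factor is \code{1e6 / librarySize}.
#'
#' @slot sampleId Sample identifier.
#' @slot tracks Named list of integer count vectors.
#' @slot librarySize Total mapped P-sites; must equal the sum over tracks.
#' @seealso \code{\link{buildTracks}}, \code{\link{rpmScale}}
#' @export
setClass("SampleLibrary",
  representation(sampleId = "character", tracks = "list",
                 librarySize = "numeric"))

setValidity("SampleLibrary", function(object) {
  if (length(object@sampleId) != 1L) return("sampleId must be length 1")
  tot <- sum(vapply(object@tracks, sum, numeric(1)))
  if (length(object@tracks) && abs(tot - object@librarySize) > 0.5)
    return("librarySize must equal the total of all track counts")
  if (any(vapply(object@tracks, function(x) any(x < 0), logical(1))))
    return("negative counts")
  TRUE
})

#' Construct a SampleLibrary
#'
#' @param sampleId sample identifier.
#' @param tracks named list of per-transcript integer count vectors.
#' @return A \linkS4class{SampleLibrary}.
#' @export
SampleLibrary <- function(sampleId, tracks) {
  new("SampleLibrary", sampleId = as.character(sampleId), tracks = tracks,
      librarySize = sum(vapply(tracks, sum, numeric(1))))
}

#' @describeIn SampleLibrary-accessors total mapped P-sites
#' @export
librarySize <- function(object) object@librarySize

#' Accessors for SampleLibrary objects
#' @param object A \linkS4class{SampleLibrary}.
#' @name SampleLibrary-accessors
NULL

#' @describeIn SampleLibrary-accessors sample identifier
#' @export
sampleId <- function(object) object@sampleId

#' @describeIn SampleLibrary-accessors count vector for one transcript
#' @param transcriptId transcript to extract.
#' @export
track <- function(object, transcriptId) object@tracks[[transcriptId]]

#' @describeIn SampleLibrary-accessors all tracks as a named list
#' @export
tracks <- function(object) object@tracks

setMethod("show", "SampleLibrary", function(object) {
  cat("SampleLibrary '", object@sampleId, "': ",
      length(object@tracks), " transcripts, ",
      format(object@librarySize, big.mark = ","), " mapped P-sites\n",
      sep = "")
})
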