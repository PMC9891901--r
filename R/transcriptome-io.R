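#' Read a transcriptome from FASTA plus CDS annotation
#'
#' Loads transcript sequences and CDS coordinates and selects one
#' representative transcript per gene: the longest, with length ties broken
#' lexicographically by transcript id.  Transcripts violating the CDS
#' invariants (coordinates out of range, CDS length not divisible by 3) and
#' FASTA records without annotation are dropped with a warning.
#'
#' @param fastaPath FASTA file of transcript sequences.
#' @param annotationPath Either a tab-separated table with columns
#'   \code{transcript_id}, \code{gene_id}, \code{cds_start}, \code{cds_end}
#'   (0-based half-open, header optional) or a GTF file in transcript
#'   coordinates (seqnames are transcript ids; CDS features 1-based; needs
#'   the rtracklayer package).
#' @return A \linkS4class{Transcriptome}.  Errors if no valid transcript
#'   remains.
#' @export
readTranscriptome <- function(fastaPath, annotationPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- readCdsAnnotation(annotationPath)

  missing <- setdiff(names(seqs), ann$transcript_id)
  if (length(missing))
    warning(length(missing), " FASTA record(s) without annotation skipped: ",
            paste(head(missing, 5), collapse = ", "))
  ann <- ann[ann$transcript_id %in% names(seqs), , drop = FALSE]

  len <- Biostrings::width(seqs)[match(ann$transcript_id, names(seqs))]
  bad <- ann$cds_start < 0 | ann$cds_start >= ann$cds_end |
    ann$cds_end > len | (ann$cds_end - ann$cds_start) %% 3L != 0L
  if (any(bad)) {
    warning(sum(bad), " transcript(s) dropped for invalid CDS: ",
            paste(head(ann$transcript_id[bad], 5), collapse = ", "))
    ann <- ann[!bad, , drop = FALSE]
    len <- len[!bad]
  }
  if (nrow(ann) == 0L)
    stop("no valid transcript remains after filtering")

  # longest transcript per gene, ties lexicographic by transcript_id
  ord <- order(ann$gene_id, -len, ann$transcript_id)
  ann <- ann[ord, , drop = FALSE]
  ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  ann <- ann[order(ann$transcript_id), , drop = FALSE]
  Transcriptome(seqs[ann$transcript_id], ann)
}

readCdsAnnotation <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GTF input requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "CDS"]
    ids <- as.character(GenomicRanges::seqnames(gr))
    df <- data.frame(
      transcript_id = ids,
      gene_id = if (!is.null(gr$gene_id)) gr$gene_id else ids,
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
    agg <- do.call(rbind, lapply(split(df, df$transcript_id), function(d)
      data.frame(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
                 cds_start = min(d$start), cds_end = max(d$end))))
    rownames(agg) <- NULL
    return(agg)
  }
  first <- readLines(path, n = 10L)
  first <- first[!grepl("^#", first)][1]
  hasHeader <- grepl("transcript_id", first)
  ann <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (!hasHeader) {
    if (ncol(ann) < 4) stop("annotation TSV needs 4 columns")
    names(ann)[1:4] <- c("transcript_id", "gene_id", "cds_start", "cds_end")
  }
  ann$transcript_id <- as.character(ann$transcript_id)
  ann$gene_id <- as.character(ann$gene_id)
  ann$cds_start <- as.integer(ann$cds_start)
  ann$cds_end <- as.integer(ann$cds_end)
  ann[, c("transcript_id", "gene_id", "cds_start", "cds_end")]
}

#' Read footprint alignments in transcript coordinates
#'
#' Reads SAM/BAM alignments (forward strand, transcript space) or a
#' simplified TSV (\code{transcript_id<TAB>five_prime_pos<TAB>read_length}
#' with optional fourth quality column) into a read-record table.  SAM
#' 1-based \code{POS} is converted to a 0-based 5' position
#' (\code{five_prime_pos = POS - 1}).  Reads on transcripts absent from the
#' transcriptome, reverse-strand or malformed records are skipped and
#' counted in the \code{"skipped"} attribute.
#'
#' @param path alignment file.
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param format \code{"auto"} (by extension), \code{"sam"}, \code{"bam"}
#'   or \code{"tsv"}.
#' @return data.frame with columns \code{transcript_id},
#'   \code{five_prime_pos} (0-based), \code{read_length}, \code{quality}
#'   (Phred+33 string or \code{NA}); attribute \code{skipped} is a named
#'   integer vector (\code{unknown_transcript}, \code{reverse_strand},
#'   \code{malformed}).
#' @export
readAlignments <- function(path, transcriptome,
                           format = c("auto", "sam", "bam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path)) "bam"
      else if (grepl("\\.sam$", path)) "sam" else "tsv"
  }
  if (format %in% c("sam", "bam")) {
    bam <- if (format == "sam")
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE) else path
    res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "qwidth", "qual")))[[1]]
    df <- data.frame(transcript_id = as.character(res$rname),
                     five_prime_pos = res$pos - 1L,
                     read_length = res$qwidth,
                     quality = as.character(res$qual),
                     stringsAsFactors = FALSE)
    rev <- !is.na(res$strand) & res$strand == "-"
    mal <- is.na(df$five_prime_pos) | is.na(df$read_length)
    skippedRev <- sum(rev)
    df <- df[!rev & !mal, , drop = FALSE]
    skippedMal <- sum(mal & !rev)
  } else {
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#")
    if (ncol(raw) < 3) stop("TSV alignments need >= 3 columns")
    df <- data.frame(transcript_id = as.character(raw[[1]]),
                     five_prime_pos = suppressWarnings(as.integer(raw[[2]])),
                     read_length = suppressWarnings(as.integer(raw[[3]])),
                     quality = if (ncol(raw) >= 4) as.character(raw[[4]])
                       else NA_character_,
                     stringsAsFactors = FALSE)
    mal <- is.na(df$five_prime_pos) | is.na(df$read_length) |
      df$read_length <= 0 | df$five_prime_pos < 0
    skippedMal <- sum(mal)
    skippedRev <- 0L
    df <- df[!mal, , drop = FALSE]
  }
  known <- df$transcript_id %in% txIds(transcriptome)
  skippedUnknown <- sum(!known)
  df <- df[known, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "skipped") <- c(unknown_transcript = skippedUnknown,
                           reverse_strand = as.integer(skippedRev),
                           malformed = as.integer(skippedMal))
  df
}

#' Write and read P-site tracks
#'
#' \code{writeTrack} dumps one per-nucleotide count vector either as
#' bedGraph (0-based half-open intervals, merged over runs of equal
#' non-zero count) or as a two-column position/count TSV.  A header comment
#' records transcript, sample and track length so that
#' \code{readTrack} restores the exact vector (round-trip safe).
#'
#' @param counts integer count vector (one entry per nucleotide).
#' @param path output file.
#' @param transcriptId,sampleId identifiers recorded in the header.
#' @param format \code{"bedgraph"} or \code{"tsv"}.
#' @return \code{writeTrack}: the path, invisibly. \code{readTrack}: a list
#'   with \code{counts}, \code{transcript_id}, \code{sample_id}.
#' @examples
#' f <- tempfile(fileext = ".bedgraph")
#' writeTrack(c(0L, 0L, 3L, 3L, 1L), f, "tx1", "s1")
#' readTrack(f)$counts
#' @export
writeTrack <- function(counts, path, transcriptId, sampleId,
                       format = c("bedgraph", "tsv")) {
  format <- match.arg(format)
  stopifnot(all(counts >= 0))
  header <- sprintf("# riboStall track format=%s transcript=%s sample=%s length=%d",
                    format, transcriptId, sampleId, length(counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (format == "bedgraph") {
    r <- rle(as.integer(counts))
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0L
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%d", transcriptId, start[keep],
                         end[keep], r$values[keep]), con)
  } else {
    keep <- which(counts != 0L)
    if (length(keep))
      writeLines(sprintf("%s\t%d\t%d", transcriptId, keep - 1L,
                         as.integer(counts[keep])), con)
  }
  invisible(path)
}

#' @rdname writeTrack
#' @export
readTrack <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!grepl("^# riboStall track", hdr)) stop("not a riboStall track file")
  field <- function(k) sub(paste0(".*", k, "=([^ ]+).*"), "\\1", hdr)
  fmt <- field("format")
  len <- as.integer(field("length"))
  counts <- integer(len)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (fmt == "bedgraph") {
      for (p in parts) {
        s <- as.integer(p[2]); e <- as.integer(p[3])
        counts[(s + 1L):e] <- as.integer(p[4])
      }
    } else {
      pos <- vapply(parts, function(p) as.integer(p[2]), integer(1))
      val <- vapply(parts, function(p) as.integer(p[3]), integer(1))
      counts[pos + 1L] <- val
    }
  }
  list(counts = counts, transcript_id = field("transcript"),
       sample_id = field("sample"))
}
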