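#' Scan transcript regions for poly-purine (or poly-AC) motifs
#'
#' Finds maximal runs of the two alphabet letters (A/G for poly-purine,
#' A/C for the negative-control class) in the CDS or 5'UTR of each
#' transcript and emits one occurrence per run per requested k with
#' k <= run length, anchored at the run start.  Anchoring at maximal-run
#' starts (rather than every overlapping k-mer) prevents a single long run
#' from dominating downstream averages.  Runs containing N never match.
#'
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param region \code{"cds"} or \code{"utr5"}.
#' @param kSet motif lengths of interest (default 4, 5, 6).
#' @param alphabet \code{"AG"} or \code{"AC"}.
#' @param transcripts optional subset of transcript ids to scan.
#' @return data.frame: \code{transcript_id}, \code{region}, \code{start}
#'   (0-based offset within the region), \code{k}, \code{run_length},
#'   \code{alphabet_class}.
#' @examples
#' tx <- Transcriptome(c(t1 = "TTAGAGATTCGG"),
#'   data.frame(transcript_id = "t1", gene_id = "g1",
#'              cds_start = 0, cds_end = 12))
#' findMotifs(tx, "cds", kSet = 4:5)  # run AGAGA at 2: k=4 and k=5
#' @export
findMotifs <- function(transcriptome, region = c("cds", "utr5"),
                       kSet = c(4, 5, 6), alphabet = c("AG", "AC"),
                       transcripts = NULL) {
  region <- match.arg(region)
  alphabet <- match.arg(alphabet)
  pat <- if (alphabet == "AG") "[AG]+" else "[AC]+"
  ids <- if (is.null(transcripts)) txIds(transcriptome) else transcripts
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  seqs <- as.character(txSequences(transcriptome))
  out <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    sub <- if (region == "cds")
      substr(seqs[[id]], cs[[id]] + 1L, ce[[id]])
    else substr(seqs[[id]], 1L, cs[[id]])
    if (nchar(sub) < min(kSet)) next
    m <- gregexpr(pat, sub)[[1]]
    if (m[1] == -1) next
    runStart <- as.integer(m) - 1L
    runLen <- attr(m, "match.length")
    keep <- runLen >= min(kSet)
    if (!any(keep)) next
    runStart <- runStart[keep]; runLen <- runLen[keep]
    rows <- lapply(seq_along(runStart), function(i) {
      ks <- kSet[kSet <= runLen[i]]
      if (!length(ks)) return(NULL)
      data.frame(transcript_id = id, region = region,
                 start = runStart[i], k = as.integer(ks),
                 run_length = runLen[i], alphabet_class = alphabet,
                 stringsAsFactors = FALSE)
    })
    out[[j]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(transcript_id = character(), region = character(),
                      start = integer(), k = integer(),
                      run_length = integer(), alphabet_class = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Motif-anchored footprint density enrichment
#'
#' Compares ribosome (or disome) density in windows around motif anchors
#' between a treatment and a control group.  Motifs are discarded when the
#' anchor lies within the first or last \code{edgeExcl} nt of its region,
#' when the (2w+1)-nt window does not fit inside the region, or when the
#' pooled raw P-site count of both groups in the window is below
#' \code{minCounts}.  Densities are RPM-scaled per library and averaged
#' within groups; the per-offset enrichment ratio is the across-motif mean
#' treatment density over the mean control density.  Significance is a
#' two-sided Welch t-test comparing, across motifs, the mean upstream
#' (-w..-1) density between the groups (motifs are the replicates).
#'
#' @param motifs data.frame from \code{\link{findMotifs}} (rows define the
#'   anchors used; duplicated anchors, e.g. the same run at several k, are
#'   collapsed).
#' @param treatmentLibs,controlLibs lists of \linkS4class{SampleLibrary}.
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param w window half-width in nt: 50 for monosome, 100 for disome data.
#' @param minCounts minimum pooled raw counts per window (default 10).
#' @param edgeExcl nt excluded at each region end (default 50).
#' @return list: \code{offsets} (-w..w), \code{enrichment_ratio},
#'   \code{mean_treatment}, \code{mean_control} (per offset),
#'   \code{per_motif} (anchor table with upstream means),
#'   \code{welch} (htest), \code{p_value}, \code{n_motifs}.
#' @export
motifWindowEnrichment <- function(motifs, treatmentLibs, controlLibs,
                                  transcriptome, w = 50, minCounts = 10,
                                  edgeExcl = 50) {
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  anchors <- unique(motifs[, c("transcript_id", "region", "start")])
  regLen <- ifelse(anchors$region == "cds",
                   (ce - cs)[anchors$transcript_id],
                   cs[anchors$transcript_id])
  ok <- anchors$start >= edgeExcl & anchors$start < regLen - edgeExcl &
    anchors$start - w >= 0 & anchors$start + w < regLen
  anchors <- anchors[ok, , drop = FALSE]
  if (nrow(anchors) < 2) stop("fewer than 2 motifs survive the filters")

  regStart <- ifelse(anchors$region == "cds",
                     cs[anchors$transcript_id], 0L)
  absAnchor <- regStart + anchors$start
  offsets <- (-w):w
  nm <- nrow(anchors)
  grab <- function(libs) {
    mats <- lapply(libs, function(lib) {
      sc <- rpmScale(lib)
      m <- matrix(0, nm, length(offsets))
      for (i in seq_len(nm)) {
        x <- track(lib, anchors$transcript_id[i])
        m[i, ] <- x[(absAnchor[i] - w + 1L):(absAnchor[i] + w + 1L)] * sc
      }
      m
    })
    Reduce(`+`, mats) / length(mats)
  }
  rawWindow <- function(libs) {
    tot <- numeric(nm)
    for (lib in libs)
      for (i in seq_len(nm)) {
        x <- track(lib, anchors$transcript_id[i])
        tot[i] <- tot[i] +
          sum(x[(absAnchor[i] - w + 1L):(absAnchor[i] + w + 1L)])
      }
    tot
  }
  pooledRaw <- rawWindow(treatmentLibs) + rawWindow(controlLibs)
  keep <- pooledRaw >= minCounts
  anchors <- anchors[keep, , drop = FALSE]
  absAnchor <- absAnchor[keep]
  nm <- nrow(anchors)
  if (nm < 2) stop("fewer than 2 motifs survive the count filter")

  treatMat <- grab(treatmentLibs)
  ctrlMat <- grab(controlLibs)
  meanT <- colMeans(treatMat)
  meanC <- colMeans(ctrlMat)
  upIdx <- which(offsets < 0)
  upT <- rowMeans(treatMat[, upIdx, drop = FALSE])
  upC <- rowMeans(ctrlMat[, upIdx, drop = FALSE])
  wt <- t.test(upT, upC, var.equal = FALSE)
  anchors$upstream_treatment <- upT
  anchors$upstream_control <- upC
  list(offsets = offsets,
       enrichment_ratio = ifelse(meanC > 0, meanT / meanC, NA_real_),
       mean_treatment = meanT, mean_control = meanC,
       per_motif = anchors, welch = wt, p_value = wt$p.value,
       n_motifs = nm)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t statistic with Welch-Satterthwaite degrees
#' of freedom (wraps \code{stats::t.test}).
#'
#' @param x,y numeric vectors of length >= 2; at least one must have
#'   non-zero variance.
#' @return named vector with \code{t}, \code{df}, \code{p}.
#' @export
welchT <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need at least 2 observations")
  if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y))
    return(c(t = 0, df = length(x) + length(y) - 2, p = 1))
  res <- t.test(x, y, var.equal = FALSE)
  c(t = unname(res$statistic), df = unname(res$parameter),
    p = res$p.value)
}

#' k-mer enrichment between two CLIP read libraries
#'
#' A read is retained when it occurs as an exact substring of any target
#' region sequence (exact, no-mismatch matching); for every k-mer of the
#' requested class-alphabet lengths, its frequency is the number of
#' occurrences within retained reads per million retained reads, and the
#' enrichment ratio is treatment frequency over control frequency (defined
#' only where the control frequency is positive).  Group significance per k
#' is a Welch test of the class k-mer ratios (k-mers drawn solely from the
#' two alphabet letters) against the ratios of all remaining k-mers of the
#' same k; an overall test pools the k values.
#'
#' @param readsTreatment,readsControl character vectors or
#'   \code{DNAStringSet} of read sequences.
#' @param targetRegions character vector or \code{DNAStringSet} of target
#'   region sequences (e.g. ERG CDSs or IRG 5'UTRs).
#' @param kSet k-mer lengths (default 4:6).
#' @param alphabet \code{"AG"} or \code{"AC"}.
#' @return list: \code{table} (kmer, k, is_class, freq_treatment,
#'   freq_control, ratio), \code{tests} (per-k Welch results),
#'   \code{p_value} (pooled), \code{retained} (per-library retained read
#'   counts).
#' @export
iclipKmerEnrichment <- function(readsTreatment, readsControl, targetRegions,
                                kSet = 4:6, alphabet = c("AG", "AC")) {
  alphabet <- match.arg(alphabet)
  toSet <- function(x) if (is(x, "DNAStringSet")) x
    else Biostrings::DNAStringSet(as.character(x))
  targets <- toSet(targetRegions)
  retain <- function(reads) {
    reads <- toSet(reads)
    if (!length(reads)) return(reads)
    hit <- logical(length(reads))
    for (wdt in unique(Biostrings::width(reads))) {
      idx <- which(Biostrings::width(reads) == wdt)
      pd <- Biostrings::PDict(reads[idx])
      found <- unique(unlist(Biostrings::vwhichPDict(pd, targets)))
      hit[idx[found]] <- TRUE
    }
    reads[hit]
  }
  keptT <- retain(readsTreatment)
  keptC <- retain(readsControl)
  if (!length(keptT) || !length(keptC))
    stop("zero retained reads in one of the libraries")

  freqs <- function(reads, k) {
    counts <- colSums(Biostrings::oligonucleotideFrequency(reads, width = k))
    counts / length(reads) * 1e6
  }
  letters2 <- strsplit(alphabet, "")[[1]]
  tabs <- lapply(kSet, function(k) {
    fT <- freqs(keptT, k)
    fC <- freqs(keptC, k)
    kmers <- names(fT)
    isClass <- !grepl(paste0("[^", alphabet, "]"), kmers)
    data.frame(kmer = kmers, k = k, is_class = isClass,
               freq_treatment = unname(fT), freq_control = unname(fC),
               ratio = ifelse(fC > 0, fT / fC, NA_real_),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  testOne <- function(d) {
    rc <- d$ratio[d$is_class & !is.na(d$ratio)]
    rn <- d$ratio[!d$is_class & !is.na(d$ratio)]
    if (length(rc) < 2 || length(rn) < 2) return(NULL)
    welchT(rc, rn)
  }
  tests <- lapply(split(tab, tab$k), testOne)
  overall <- testOne(tab)
  list(table = tab, tests = tests,
       p_value = if (!is.null(overall)) unname(overall["p"]) else NA_real_,
       retained = c(treatment = length(keptT), control = length(keptC)))
}
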