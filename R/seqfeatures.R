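#' Codon weight tables for tAI/cAI
#'
#' \code{readCodonWeights} reads a two-column TSV (codon, weight) into a
#' named numeric vector, checking that all weights lie in (0, 1].
#' \code{caiWeights} derives codon-adaptation relative adaptiveness from a
#' reference codon-frequency table: within each synonymous family the most
#' frequent codon gets weight 1 and the others their frequency relative to
#' it (zero frequencies are floored at 0.5 counts so weights stay
#' positive).
#'
#' A synthetic illustrative tAI table ships at
#' \code{system.file("extdata", "codon_weights_tai_synthetic.tsv",
#' package = "riboStall")}; real tables derived from tRNA copy numbers are
#' expected as user input.
#'
#' @param path TSV file, two columns codon/weight, '#' comments allowed.
#' @param freq named numeric vector of codon frequencies (61 sense codons
#'   or all 64).
#' @return named numeric vector of weights in (0, 1].
#' @export
readCodonWeights <- function(path) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  w <- setNames(as.numeric(tab[[2]]), toupper(tab[[1]]))
  if (any(w <= 0 | w > 1)) stop("weights must lie in (0, 1]")
  w
}

#' @rdname readCodonWeights
#' @export
caiWeights <- function(freq) {
  codons <- toupper(names(freq))
  aa <- vapply(codons, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd))),
    character(1))
  freq <- pmax(freq, 0.5)
  w <- numeric(length(freq))
  for (a in unique(aa)) {
    idx <- aa == a
    w[idx] <- freq[idx] / max(freq[idx])
  }
  setNames(w, codons)
}

#' Local codon-optimality profile (windowed geometric mean)
#'
#' The value at codon i is the geometric mean of the weights of codons
#' i..i+window-1; positions within one window of the CDS end are omitted.
#' Windows containing codons absent from the table (e.g. stop codons in a
#' tAI table) are reported as NA with a notice.
#'
#' @param cdsSeq CDS nucleotide sequence (character or DNAString); length a
#'   multiple of 3.
#' @param weights named numeric codon weight vector in (0, 1] (tAI or cAI).
#' @param window window length in codons (default 10).
#' @return numeric vector of length L - window + 1 (L = CDS codons), NA
#'   where a window hit a missing codon; empty when window > L.
#' @export
localIndex <- function(cdsSeq, weights, window = 10) {
  s <- toupper(as.character(cdsSeq))
  L <- nchar(s) %/% 3L
  if (window > L) return(numeric(0))
  codons <- substring(s, 3 * seq_len(L) - 2, 3 * seq_len(L))
  lw <- log(weights[codons])
  if (anyNA(lw))
    message(sum(is.na(lw)), " codon(s) absent from the weight table; ",
            "affected windows reported as NA")
  cums <- c(0, cumsum(ifelse(is.na(lw), 0, lw)))
  nmiss <- c(0, cumsum(is.na(lw)))
  i <- seq_len(L - window + 1)
  out <- exp((cums[i + window] - cums[i]) / window)
  out[(nmiss[i + window] - nmiss[i]) > 0] <- NA_real_
  unname(out)
}

kyteDoolittle <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
residueCharge <- c(K = 1, R = 1, D = -1, E = -1)

#' Sliding-window residue feature profile
#'
#' Arithmetic mean over a sliding window of per-residue scores: charge
#' (K, R = +1; D, E = -1; others including H = 0, the common convention at
#' cytosolic pH) or Kyte-Doolittle hydrophobicity.  Unknown residues score
#' 0 (charge) or the scale mean (hydrophobicity) with a notice.
#'
#' @param proteinSeq amino-acid sequence (stop excluded), character or
#'   AAString.
#' @param feature \code{"charge"} or \code{"hydrophobicity"}.
#' @param window window length in residues (default 10).
#' @return numeric vector of length N - window + 1.
#' @examples
#' residueFeature("KRDE", "charge", window = 4)       # 0
#' residueFeature("AI", "hydrophobicity", window = 2) # 3.15
#' @export
residueFeature <- function(proteinSeq,
                           feature = c("charge", "hydrophobicity"),
                           window = 10) {
  feature <- match.arg(feature)
  s <- strsplit(toupper(as.character(proteinSeq)), "")[[1]]
  N <- length(s)
  if (window > N) return(numeric(0))
  vals <- if (feature == "charge") {
    v <- residueCharge[s]
    v[is.na(v)] <- 0
    known <- s %in% c(names(kyteDoolittle))
    if (!all(known))
      message(sum(!known), " non-standard residue(s) scored as 0")
    unname(v)
  } else {
    v <- kyteDoolittle[s]
    if (anyNA(v)) {
      message(sum(is.na(v)), " non-standard residue(s) scored as scale mean")
      v[is.na(v)] <- mean(kyteDoolittle)
    }
    unname(v)
  }
  cums <- c(0, cumsum(vals))
  i <- seq_len(N - window + 1)
  (cums[i + window] - cums[i]) / window
}

#' Feature metagene over a gene set
#'
#' Positional mean of per-gene local feature profiles (tAI, cAI, charge or
#' hydrophobicity) aligned at the start codon, with the number of
#' contributing genes tracked per position.  The stop codon is excluded
#' before computing codon/residue profiles.
#'
#' @param geneSet character vector of gene ids (resolved through the
#'   transcriptome's gene-to-transcript map).
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param feature one of \code{"tai"}, \code{"cai"}, \code{"charge"},
#'   \code{"hydrophobicity"}.
#' @param weights codon weight vector, required for tai/cai.
#' @param window window length (codons or residues, default 10).
#' @param maxPos profile truncated at this position (default 100).
#' @return data.frame: \code{position} (1-based codon/residue from the
#'   start), \code{mean_value}, \code{n_genes}.
#' @export
featureMetagene <- function(geneSet, transcriptome,
                            feature = c("tai", "cai", "charge",
                                        "hydrophobicity"),
                            weights = NULL, window = 10, maxPos = 100) {
  feature <- match.arg(feature)
  g2t <- setNames(txIds(transcriptome), geneIds(transcriptome))
  ids <- unname(g2t[intersect(geneSet, names(g2t))])
  if (!length(ids)) stop("gene set resolves to no transcript")
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  seqs <- txSequences(transcriptome)
  acc <- numeric(maxPos); n <- integer(maxPos)
  for (id in ids) {
    cds <- subseq(seqs[[id]], cs[[id]] + 1L, ce[[id]])
    cds <- subseq(cds, 1L, length(cds) - 3L)  # drop stop codon
    prof <- if (feature %in% c("tai", "cai")) {
      if (is.null(weights)) stop("tai/cai need a codon weight table")
      localIndex(cds, weights, window)
    } else {
      prot <- as.character(suppressWarnings(Biostrings::translate(
        cds, if.fuzzy.codon = "solve")))
      residueFeature(prot, feature, window)
    }
    if (!length(prof)) next
    take <- seq_len(min(maxPos, length(prof)))
    ok <- take[!is.na(prof[take])]
    acc[ok] <- acc[ok] + prof[ok]
    n[ok] <- n[ok] + 1L
  }
  data.frame(position = seq_len(maxPos),
             mean_value = ifelse(n > 0, acc / n, NA_real_),
             n_genes = n)
}

#' Ribosome-enriched and -depleted positions in the early CDS
#'
#' Per-codon density ratio (treatment over control, both RPM-scaled)
#' within the first \code{firstN} CDS codons: positions with ratio >= 1.5
#' are labelled \code{enriched}, ratio <= 0.67 \code{depleted} (both
#' inclusive), the rest \code{neither}; codons with zero control density
#' are excluded.
#'
#' @param treatmentLib,controlLib \linkS4class{SampleLibrary} objects.
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param transcripts transcripts to classify (default: all).
#' @param firstN number of early CDS codons examined (default 50).
#' @param enrichedCutoff,depletedCutoff inclusive ratio cutoffs.
#' @return data.frame: \code{transcript_id}, \code{codon_index} (1-based),
#'   \code{ratio}, \code{label}.
#' @export
classifyPositions <- function(treatmentLib, controlLib, transcriptome,
                              transcripts = NULL, firstN = 50,
                              enrichedCutoff = 1.5, depletedCutoff = 0.67) {
  ids <- if (is.null(transcripts)) txIds(transcriptome) else transcripts
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  st <- rpmScale(treatmentLib); sc <- rpmScale(controlLib)
  out <- lapply(ids, function(id) {
    dt <- codonDensities(track(treatmentLib, id), cs[[id]], ce[[id]]) * st
    dc <- codonDensities(track(controlLib, id), cs[[id]], ce[[id]]) * sc
    nn <- min(firstN, length(dc))
    idx <- which(dc[seq_len(nn)] > 0)
    if (!length(idx)) return(NULL)
    ratio <- dt[idx] / dc[idx]
    lab <- ifelse(ratio >= enrichedCutoff, "enriched",
                  ifelse(ratio <= depletedCutoff, "depleted", "neither"))
    data.frame(transcript_id = id, codon_index = idx, ratio = ratio,
               label = lab, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(transcript_id = character(), codon_index = integer(),
                      ratio = numeric(), label = character())
  rownames(res) <- NULL
  res
}

#' Compare sequence features between enriched and depleted positions
#'
#' For each classified position the local feature value at its codon is
#' looked up (windowed profile starting at that codon) and the enriched and
#' depleted sets are compared with a Welch two-sided t-test.  Used to ask
#' whether codon optimality, charge, or hydrophobicity explains where
#' footprints accumulate.
#'
#' @param positions data.frame from \code{\link{classifyPositions}}.
#' @param transcriptome A \linkS4class{Transcriptome}.
#' @param feature,weights,window as in \code{\link{featureMetagene}}.
#' @return list with \code{welch} (named vector t/df/p), \code{p_value},
#'   \code{n} (positions per label actually scored).
#' @export
comparePositionFeatures <- function(positions, transcriptome,
                                    feature = c("tai", "cai", "charge",
                                                "hydrophobicity"),
                                    weights = NULL, window = 10) {
  feature <- match.arg(feature)
  cs <- cdsStart(transcriptome)
  ce <- cdsEnd(transcriptome)
  seqs <- txSequences(transcriptome)
  profiles <- new.env()
  getProf <- function(id) {
    hit <- get0(id, envir = profiles, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    cds <- subseq(seqs[[id]], cs[[id]] + 1L, ce[[id]])
    cds <- subseq(cds, 1L, length(cds) - 3L)
    p <- if (feature %in% c("tai", "cai")) {
      if (is.null(weights)) stop("tai/cai need a codon weight table")
      localIndex(cds, weights, window)
    } else {
      residueFeature(as.character(suppressWarnings(
        Biostrings::translate(cds, if.fuzzy.codon = "solve"))),
        feature, window)
    }
    assign(id, p, envir = profiles)
    p
  }
  val <- vapply(seq_len(nrow(positions)), function(i) {
    p <- getProf(positions$transcript_id[i])
    j <- positions$codon_index[i]
    if (j <= length(p)) p[j] else NA_real_
  }, numeric(1))
  enr <- val[positions$label == "enriched" & !is.na(val)]
  dep <- val[positions$label == "depleted" & !is.na(val)]
  if (length(enr) < 2 || length(dep) < 2)
    stop("need at least 2 scored positions per label")
  wt <- welchT(enr, dep)
  list(welch = wt, p_value = unname(wt["p"]),
       n = c(enriched = length(enr), depleted = length(dep)))
}
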