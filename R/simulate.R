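#' Configuration for the synthetic ribosome-profiling generator
#'
#' Bundles every tunable of the simulator with defaults describing the
#' reference cohort used throughout the package's validation: 2000 genes of
#' which 10\% are ERG-like (elongation-stall targets: short TISU-like
#' 5'UTRs, AG anchors planted in the early CDS) and 10\% IRG-like
#' (initiation-block targets: long 5'UTRs carrying AG anchors), sequencing
#' depth 2e6 P-sites per library, per-codon negative-binomial noise with
#' dispersion 0.1, dwell-time stall factor 5 over the 15 nt upstream of AG
#' anchors within the first 50 codons, ribosome-loading fold 2 for
#' ERG-like genes under the stall regime and initiation factor 0.5 for
#' IRG-like genes under the block regime.
#'
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @param nGenes number of genes (one transcript each).
#' @param ergFraction,irgFraction fractions of ERG-like / IRG-like genes.
#' @param utr5Short,utr5Long candidate 5'UTR lengths (nt) for short
#'   (TISU-like) and long UTR classes.
#' @param utr3Len 3'UTR length in nt.
#' @param cdsCodons inclusive range of CDS lengths in codons.
#' @param ergAnchors AG anchors planted per ERG-like gene (codons 5-50).
#' @param acAnchors AC control anchors planted per ERG-like gene
#'   (codons 70-95, outside any stall window).
#' @param irgUtrAnchors AG anchors planted per IRG-like 5'UTR.
#' @param bgAnchors AG/AC anchor pairs planted per background gene at
#'   random CDS codons.
#' @param runLengths candidate motif run lengths in nt.
#' @param stallFactor dwell-time multiplier on stalled positions (>= 1).
#' @param stallWindow stalled stretch upstream of an anchor, in nt.
#' @param stallFirstCodons anchors at codons up to this bound stall.
#' @param stallAt \code{"motif"}: stall windows sit upstream of planted AG
#'   anchors; \code{"random"}: at random early-CDS codons, independent of
#'   sequence.
#' @param ergFlux ribosome-loading multiplier of ERG-like genes under the
#'   stall regime (net body-count fold is this times the dwell excess).
#' @param initiationFactor flux multiplier of IRG-like genes under the
#'   initiation-block regime.
#' @param blockUtrLoad expected per-position 5'UTR density (in units of
#'   gene flux) added at IRG UTR anchors under the block regime.
#' @param dispersion negative-binomial dispersion of per-codon counts
#'   (0 = Poisson).
#' @param depth target library size (expected total P-sites).
#' @param tauSd,fluxSd log-normal sdlog of per-codon dwell times and of
#'   per-gene flux.
#' @param startBoost dwell multiplier of the initiation codon, emulating
#'   the start-codon occupancy peak of real footprint libraries (and
#'   anchoring P-site offset calibration).
#' @param readLengths,readLengthProbs footprint length distribution.
#' @param psiteOffsets named vector, read length -> 5'-to-P-site offset.
#' @param framePurity probability that a materialized read keeps its exact
#'   P-site frame (the rest shift by +-1 nt).
#' @param disomeLengths,disomeOffset,disomeTopFrac disome read lengths,
#'   5'-end offset upstream of the stalled P-site, and the top dwell-time
#'   quantile fraction emitting disomes.
#' @param iclipReadLen,iclipOversample CLIP read length and the
#'   oversampling factor of anchor-overlapping windows in the treatment
#'   library.
#' @return a list of class \code{simConfig}.
#' @export
simConfig <- function(seed = 1L, nGenes = 2000, ergFraction = 0.1,
                      irgFraction = 0.1, utr5Short = 11:15,
                      utr5Long = 130:170, utr3Len = 50,
                      cdsCodons = c(150, 400), ergAnchors = 2,
                      acAnchors = 2, irgUtrAnchors = 2, bgAnchors = 1,
                      runLengths = 4:8, stallFactor = 5, stallWindow = 15,
                      stallFirstCodons = 50, stallAt = c("motif", "random"),
                      ergFlux = 2, initiationFactor = 0.5,
                      blockUtrLoad = 2, dispersion = 0.1, depth = 2e6,
                      tauSd = 0.25, fluxSd = 0.5, startBoost = 3,
                      readLengths = c(28L, 29L, 30L),
                      readLengthProbs = c(1, 1, 1) / 3,
                      psiteOffsets = c("28" = 11L, "29" = 12L, "30" = 13L),
                      framePurity = 1, disomeLengths = 55:65,
                      disomeOffset = 30, disomeTopFrac = 0.1,
                      iclipReadLen = 30, iclipOversample = 3) {
  cfg <- as.list(environment())
  cfg$stallAt <- match.arg(stallAt)
  stopifnot(cfg$stallFactor >= 1, cfg$depth > 0,
            all(names(psiteOffsets) == as.character(readLengths)))
  class(cfg) <- "simConfig"
  cfg
}

# background sequence without AG- or AC-class runs of 4+ nt: iid draws,
# then every offending run is broken by a T every 4th position (T belongs
# to neither class, so repairs cannot create new runs)
randomSeqNoRuns <- function(n) {
  v <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  repeat {
    s <- paste(v, collapse = "")
    m <- gregexpr("[AG]{4,}|[AC]{4,}", s)[[1]]
    if (m[1] == -1) return(v)
    for (j in seq_along(m)) {
      st <- m[j]
      len <- attr(m, "match.length")[j]
      v[seq(st + 3L, st + len - 1L, by = 4L)] <- "T"
    }
  }
}

fixInternalStops <- function(v, cds_start, cds_end) {
  # substitute the middle base with C/ last base: stops never survive and
  # the C cannot seed an AG-class run
  Lc <- (cds_end - cds_start) %/% 3L
  if (Lc <= 2) return(v)
  for (cod in 2:(Lc - 1)) {
    i <- cds_start + 3L * (cod - 1L) + 1L
    codon <- paste(v[i:(i + 2L)], collapse = "")
    if (codon == "TAA") v[i + 1L] <- "C"
    else if (codon == "TAG") v[i + 1L] <- "C"
    else if (codon == "TGA") v[i + 2L] <- "C"
  }
  v
}

plantRun <- function(v, pos0, len, letters, needed) {
  # pos0: 0-based start within v.  T flanks keep the run maximal in both
  # motif alphabets (T belongs to neither); a stop codon accidentally
  # formed by a right flank is repaired afterwards by fixInternalStops.
  # A is shared between the AG and AC alphabets, so runs avoid 4+
  # consecutive A to keep each planted anchor in exactly one class.
  for (try in 1:25) {
    run <- sample(letters, len, replace = TRUE)
    run[sample(len, 1)] <- needed
    if (!grepl("AAAA", paste(run, collapse = ""), fixed = TRUE)) break
    if (try == 25) run <- rep_len(c(needed, "A"), len)
  }
  v[(pos0 + 1L):(pos0 + len)] <- run
  if (pos0 >= 1L) v[pos0] <- "T"
  if (pos0 + len < length(v)) v[pos0 + len + 1L] <- "T"
  v
}

#' Simulate a transcriptome with planted motifs and known ground truth
#'
#' Generates one transcript per gene: ERG-like genes get short TISU-like
#' 5'UTRs and AG runs planted at early CDS codons (5-50) plus AC control
#' runs at codons 70-95; IRG-like genes get long 5'UTRs carrying AG runs;
#' background genes get one AG and one AC run at random CDS codons.  The
#' background sequence suppresses spontaneous AG/AC runs of 4+ nt so the
#' planted anchors are the only poly-purine motifs, every CDS is
#' ATG-initiated with a single in-frame stop at its end, and per-codon
#' dwell times and per-gene fluxes are drawn once and recorded in the
#' truth object.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{transcriptome} (a
#'   \linkS4class{Transcriptome}) and \code{truth}: \code{genes}
#'   (transcript_id, gene_id, class, flux, cds_codons), \code{anchors}
#'   (transcript_id, region, start 0-based within region, length, class),
#'   \code{dwell} (per-transcript dwell-time vectors),
#'   \code{stallCodons} (per-transcript stalled codon indices, 1-based).
#' @export
simulateTranscriptome <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  n <- cfg$nGenes
  nErg <- round(n * cfg$ergFraction)
  nIrg <- round(n * cfg$irgFraction)
  cls <- c(rep("ERG", nErg), rep("IRG", nIrg),
           rep("background", n - nErg - nIrg))
  ids <- sprintf("tx%04d", seq_len(n))
  gids <- sprintf("g%04d", seq_len(n))
  seqs <- character(n)
  info <- data.frame(transcript_id = ids, gene_id = gids,
                     cds_start = 0L, cds_end = 0L,
                     stringsAsFactors = FALSE)
  anchorRows <- vector("list", n)
  dwell <- vector("list", n)
  stallCodons <- vector("list", n)
  flux <- rlnorm(n, 0, cfg$fluxSd)
  for (i in seq_len(n)) {
    Lc <- sample(cfg$cdsCodons[1]:cfg$cdsCodons[2], 1)
    utr5 <- if (cls[i] == "ERG") sample(cfg$utr5Short, 1)
      else if (cls[i] == "IRG") sample(cfg$utr5Long, 1)
      else sample(c(cfg$utr5Short, cfg$utr5Long), 1)
    total <- utr5 + 3L * Lc + cfg$utr3Len
    v <- randomSeqNoRuns(total)
    cs <- utr5
    ce <- utr5 + 3L * Lc
    v[(cs + 1L):(cs + 3L)] <- c("A", "T", "G")
    v[(ce - 2L):ce] <- c("T", "A", "A")
    # C breakers around the inserted start/stop so their A/G letters cannot
    # seed purine runs with the adjacent background (C never forms a stop)
    if (cs >= 1L) v[cs] <- "C"
    v[cs + 4L] <- "C"
    if (ce < total) v[ce + 1L] <- "C"

    anch <- list()
    plantCds <- function(codon, class) {
      len <- sample(cfg$runLengths, 1)
      pos0 <- cs + 3L * (codon - 1L)
      lets <- if (class == "AG") c("A", "G") else c("A", "C")
      need <- if (class == "AG") "G" else "C"
      v <<- plantRun(v, pos0, len, lets, need)
      list(region = "cds", start = 3L * (codon - 1L), length = len,
           class = class, codon = codon)
    }
    if (cls[i] == "ERG") {
      # anchors at least 24 codons apart: one anchor's +-50 nt window can
      # then never overlap the neighbour's 15-nt stall stretch
      agCodons <- if (cfg$ergAnchors == 1) {
        sample(seq(5L, 50L, by = 5L), 1)
      } else if (cfg$ergAnchors == 2) {
        a <- sample(seq(5L, 25L, by = 5L), 1)
        gap <- seq(25L, 50L - a, by = 5L)
        b <- a + gap[sample.int(length(gap), 1)]
        c(a, b)
      } else sample(seq(5L, 50L, by = 5L), cfg$ergAnchors)
      acCodons <- sample(seq(70L, 95L, by = 5L), cfg$acAnchors)
      anch <- c(lapply(agCodons, plantCds, class = "AG"),
                lapply(acCodons, plantCds, class = "AC"))
    } else if (cls[i] == "IRG") {
      slots <- seq(55L, min(90L, utr5 - 12L), by = 12L)
      upos <- sample(slots, min(cfg$irgUtrAnchors, length(slots)))
      for (p in upos) {
        len <- sample(cfg$runLengths, 1)
        v <- plantRun(v, p, len, c("A", "G"), "G")
        anch <- c(anch, list(list(region = "utr5", start = p,
                                  length = len, class = "AG",
                                  codon = NA_integer_)))
      }
    } else if (cfg$bgAnchors > 0) {
      slots <- seq(5L, Lc - 20L, by = 5L)
      pick <- sample(slots, 2 * cfg$bgAnchors)
      anch <- c(lapply(pick[seq_len(cfg$bgAnchors)], plantCds,
                       class = "AG"),
                lapply(pick[cfg$bgAnchors + seq_len(cfg$bgAnchors)],
                       plantCds, class = "AC"))
    }
    v <- fixInternalStops(v, cs, ce)
    seqs[i] <- paste(v, collapse = "")
    info$cds_start[i] <- cs
    info$cds_end[i] <- ce
    if (length(anch))
      anchorRows[[i]] <- data.frame(
        transcript_id = ids[i],
        region = vapply(anch, `[[`, character(1), "region"),
        start = vapply(anch, `[[`, integer(1), "start"),
        length = vapply(anch, function(a) as.integer(a$length), integer(1)),
        class = vapply(anch, `[[`, character(1), "class"),
        codon = vapply(anch, function(a) as.integer(a$codon), integer(1)),
        stringsAsFactors = FALSE)
    dwell[[i]] <- rlnorm(Lc, 0, cfg$tauSd)

    stallAnchorCodons <- if (cfg$stallAt == "motif") {
      cands <- Filter(function(a) a$region == "cds" && a$class == "AG" &&
                        !is.na(a$codon) &&
                        a$codon <= cfg$stallFirstCodons, anch)
      vapply(cands, function(a) as.integer(a$codon), integer(1))
    } else if (cls[i] == "ERG") {
      sample(10:cfg$stallFirstCodons, cfg$ergAnchors)
    } else integer(0)
    sc <- integer(0)
    for (cod in stallAnchorCodons) {
      anchorNt <- 3L * (cod - 1L)            # CDS-relative, 0-based
      nt <- max(0L, anchorNt - cfg$stallWindow):(anchorNt - 1L)
      nt <- nt[nt >= 0]
      sc <- union(sc, unique(nt %/% 3L) + 1L)
    }
    stallCodons[[i]] <- sort(sc)
  }
  names(dwell) <- ids
  names(stallCodons) <- ids
  genes <- data.frame(transcript_id = ids, gene_id = gids, class = cls,
                      flux = flux,
                      cds_codons = (info$cds_end - info$cds_start) %/% 3L,
                      stringsAsFactors = FALSE)
  list(transcriptome = Transcriptome(setNames(seqs, ids), info),
       truth = list(genes = genes,
                    anchors = do.call(rbind, anchorRows),
                    dwell = dwell, stallCodons = stallCodons))
}

regimeEffects <- function(sim, cfg, regime) {
  # per-transcript flux multiplier, stalled-codon dwell multiplier and
  # extra 5'UTR load under a (possibly combined) regime
  g <- sim$truth$genes
  fluxMult <- rep(1, nrow(g))
  stallMult <- 1
  utrLoad <- rep(0, nrow(g))
  if ("elongation_stall" %in% regime) {
    stallMult <- cfg$stallFactor
    fluxMult[g$class == "ERG"] <- fluxMult[g$class == "ERG"] * cfg$ergFlux
  }
  if ("initiation_block" %in% regime) {
    fluxMult[g$class == "IRG"] <- fluxMult[g$class == "IRG"] *
      cfg$initiationFactor
    utrLoad[g$class == "IRG"] <- cfg$blockUtrLoad
  }
  # "control" and "no_stall_mutant" leave everything at baseline
  list(fluxMult = setNames(fluxMult, g$transcript_id),
       stallMult = stallMult,
       utrLoad = setNames(utrLoad, g$transcript_id))
}

#' Simulate a footprint library under a perturbation regime
#'
#' Steady-state expected density per codon is flux x dwell time
#' (\code{mu_i = J tau_i}), the minimal model in which an elongation stall
#' (dwell multiplier on the 15 nt upstream of early AG anchors) piles
#' footprints up locally and raises a gene's total count, while an
#' initiation block (flux multiplier) scales a gene's CDS density down
#' uniformly and adds uORF-like density at the planted 5'UTR anchors of
#' IRG-like genes.  Counts are negative-binomial per codon at the
#' configured dispersion, scaled so the expected library size equals
#' \code{depth}; each count sits at the first nucleotide of its codon.
#'
#' @param sim output of \code{\link{simulateTranscriptome}}.
#' @param regime one or more of \code{"control"},
#'   \code{"elongation_stall"}, \code{"initiation_block"},
#'   \code{"no_stall_mutant"} (combined regimes apply both effects).
#' @param sampleId library identifier.
#' @param cfg the \code{\link{simConfig}} used to build \code{sim}.
#' @param depth expected library size (default \code{cfg$depth}).
#' @param seed RNG seed for this library (default \code{cfg$seed}; give
#'   each replicate its own).
#' @param materializeReads also emit a read-record table (5' end =
#'   P-site - offset(read length), lengths from the configured
#'   distribution, frame jitter per \code{framePurity}).
#' @return list: \code{library} (a \linkS4class{SampleLibrary} of
#'   ground-truth P-site tracks) and \code{reads} (data.frame or NULL).
#' @export
simulateFootprints <- function(sim, regime = "control", sampleId,
                               cfg = simConfig(), depth = cfg$depth,
                               seed = cfg$seed, materializeReads = FALSE) {
  set.seed(seed)
  eff <- regimeEffects(sim, cfg, regime)
  g <- sim$truth$genes
  ids <- g$transcript_id
  cs <- cdsStart(sim$transcriptome)
  txlen <- txLengths(sim$transcriptome)
  anchors <- sim$truth$anchors

  mus <- vector("list", length(ids))
  pos <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    tau <- sim$truth$dwell[[id]]
    stall <- sim$truth$stallCodons[[id]]
    tauEff <- tau
    tauEff[1] <- tauEff[1] * cfg$startBoost
    if (length(stall) && eff$stallMult != 1)
      tauEff[stall] <- tauEff[stall] * eff$stallMult
    mu <- g$flux[i] * eff$fluxMult[[id]] * tauEff
    p <- cs[[id]] + 3L * (seq_along(tau) - 1L)
    if (eff$utrLoad[[id]] > 0 && !is.null(anchors)) {
      ua <- anchors[anchors$transcript_id == id &
                      anchors$region == "utr5", , drop = FALSE]
      if (nrow(ua)) {
        upos <- unlist(lapply(ua$start, function(a)
          seq(a - cfg$stallWindow, a - 3L, by = 3L)))
        upos <- upos[upos >= 0]
        mu <- c(mu, rep(g$flux[i] * eff$utrLoad[[id]], length(upos)))
        p <- c(p, upos)
      }
    }
    mus[[i]] <- mu
    pos[[i]] <- p
  }
  allMu <- unlist(mus)
  scale <- depth / sum(allMu)
  counts <- if (cfg$dispersion > 0) {
    rnbinom(length(allMu), mu = scale * allMu, size = 1 / cfg$dispersion)
  } else rpois(length(allMu), scale * allMu)
  idxSplit <- rep(seq_along(ids), lengths(mus))
  trk <- vector("list", length(ids))
  names(trk) <- ids
  countsBy <- split(counts, idxSplit)
  for (i in seq_along(ids)) {
    v <- integer(txlen[[ids[i]]])
    ci <- countsBy[[as.character(i)]]
    agg <- rowsum(ci, pos[[i]])           # UTR windows may share positions
    v[as.integer(rownames(agg)) + 1L] <- as.integer(agg[, 1])
    trk[[ids[i]]] <- v
  }
  lib <- SampleLibrary(sampleId, trk)

  reads <- NULL
  if (materializeReads) {
    nTot <- sum(counts)
    txv <- rep(rep(ids, lengths(mus)), counts)
    pv <- rep(unlist(pos), counts)
    if (cfg$framePurity < 1) {
      shift <- sample(c(-1L, 0L, 1L), nTot, replace = TRUE,
                      prob = c((1 - cfg$framePurity) / 2, cfg$framePurity,
                               (1 - cfg$framePurity) / 2))
      pv <- pv + shift
    }
    len <- sample(cfg$readLengths, nTot, replace = TRUE,
                  prob = cfg$readLengthProbs)
    off <- cfg$psiteOffsets[as.character(len)]
    fp <- pv - off
    fp[fp < 0] <- 0L        # rare jittered codon-1 reads on minimal UTRs
    reads <- data.frame(transcript_id = txv,
                        five_prime_pos = as.integer(fp),
                        read_length = as.integer(len),
                        quality = NA_character_,
                        stringsAsFactors = FALSE)
  }
  list(library = lib, reads = reads)
}

#' Simulate a disome library
#'
#' Disomes (collided ribosome pairs) are emitted at codons whose effective
#' dwell time lies in the top decile of the transcript, at a rate
#' proportional to the dwell time; under the stall regime the stalled
#' early codons of ERG-like genes dominate that decile.  Reads are 55-65
#' nt with the 5' end 30 nt upstream of the stalled P-site (clipped at the
#' transcript start).
#'
#' @inheritParams simulateFootprints
#' @param depth expected disome library size.
#' @return list: \code{library} (P-site track of the stalled ribosome
#'   positions) and \code{reads} (data.frame).
#' @export
simulateDisomes <- function(sim, regime = "control", sampleId,
                            cfg = simConfig(), depth = cfg$depth / 10,
                            seed = cfg$seed) {
  set.seed(seed)
  eff <- regimeEffects(sim, cfg, regime)
  g <- sim$truth$genes
  ids <- g$transcript_id
  cs <- cdsStart(sim$transcriptome)
  txlen <- txLengths(sim$transcriptome)
  mus <- vector("list", length(ids))
  pos <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    tau <- sim$truth$dwell[[id]]
    stall <- sim$truth$stallCodons[[id]]
    tauEff <- tau
    if (length(stall) && eff$stallMult != 1)
      tauEff[stall] <- tauEff[stall] * eff$stallMult
    gate <- tauEff >= quantile(tauEff, 1 - cfg$disomeTopFrac)
    mus[[i]] <- g$flux[i] * eff$fluxMult[[id]] * tauEff * gate
    pos[[i]] <- cs[[id]] + 3L * (seq_along(tau) - 1L)
  }
  allMu <- unlist(mus)
  scale <- depth / sum(allMu)
  counts <- if (cfg$dispersion > 0) {
    rnbinom(length(allMu), mu = scale * allMu, size = 1 / cfg$dispersion)
  } else rpois(length(allMu), scale * allMu)
  idxSplit <- rep(seq_along(ids), lengths(mus))
  trk <- vector("list", length(ids))
  names(trk) <- ids
  countsBy <- split(counts, idxSplit)
  for (i in seq_along(ids)) {
    v <- integer(txlen[[ids[i]]])
    v[pos[[i]] + 1L] <- as.integer(countsBy[[as.character(i)]])
    trk[[ids[i]]] <- v
  }
  nTot <- sum(counts)
  txv <- rep(rep(ids, lengths(mus)), counts)
  pv <- rep(unlist(pos), counts)
  len <- sample(cfg$disomeLengths, nTot, replace = TRUE)
  fp <- pmax(0L, pv - cfg$disomeOffset)
  fp <- pmin(fp, txlen[txv] - len)
  list(library = SampleLibrary(sampleId, trk),
       reads = data.frame(transcript_id = txv,
                          five_prime_pos = as.integer(fp),
                          read_length = as.integer(len),
                          quality = NA_character_,
                          stringsAsFactors = FALSE))
}

#' Simulate an eIF4A CLIP read pair (treatment and control libraries)
#'
#' The control library samples fixed-length windows uniformly from the
#' transcriptome; the treatment library oversamples windows overlapping
#' planted AG anchors by the configured factor (rejection sampling:
#' non-overlapping windows are kept with probability 1/factor).
#'
#' @inheritParams simulateFootprints
#' @param nReads reads per library.
#' @param oversample enrichment factor for anchor-overlapping windows
#'   (default \code{cfg$iclipOversample}; 1 = null).
#' @return list of two character vectors, \code{treatment} and
#'   \code{control}.
#' @export
simulateIclip <- function(sim, cfg = simConfig(), nReads = 1e4,
                          oversample = cfg$iclipOversample,
                          seed = cfg$seed) {
  set.seed(seed)
  rl <- cfg$iclipReadLen
  seqs <- as.character(txSequences(sim$transcriptome))
  txlen <- nchar(seqs)
  ids <- names(seqs)
  nWin <- pmax(0L, txlen - rl + 1L)
  anchors <- sim$truth$anchors
  anchors <- anchors[anchors$class == "AG", , drop = FALSE]
  cs <- cdsStart(sim$transcriptome)
  anchAbs <- split(
    ifelse(anchors$region == "cds", cs[anchors$transcript_id], 0L) +
      anchors$start,
    anchors$transcript_id)
  anchLen <- split(anchors$length, anchors$transcript_id)

  drawBatch <- function(nDraw) {
    txIdx <- sample(seq_along(ids), nDraw, replace = TRUE,
                    prob = nWin / sum(nWin))
    st <- floor(runif(nDraw) * nWin[txIdx])      # 0-based window start
    overlap <- logical(nDraw)
    for (j in seq_len(nDraw)) {
      a <- anchAbs[[ids[txIdx[j]]]]
      if (is.null(a)) next
      l <- anchLen[[ids[txIdx[j]]]]
      overlap[j] <- any(st[j] < a + l & a < st[j] + rl)
    }
    list(tx = txIdx, st = st, overlap = overlap)
  }
  sampleLib <- function(enrich) {
    got <- character(0)
    while (length(got) < nReads) {
      b <- drawBatch(2L * nReads)
      keep <- b$overlap | runif(length(b$st)) < 1 / enrich
      tx <- b$tx[keep]; st <- b$st[keep]
      got <- c(got, substring(seqs[tx], st + 1L, st + rl))
    }
    got[seq_len(nReads)]
  }
  list(treatment = sampleLib(oversample), control = sampleLib(1))
}

#' Write simulated objects as plain-text files
#'
#' Convenience writers: FASTA + annotation TSV for a simulated
#' transcriptome, TSV read tables, and FASTQ for CLIP reads (constant
#' quality).  Every file carries the generator seed in a header comment.
#'
#' @param sim output of \code{\link{simulateTranscriptome}}.
#' @param dir output directory (created if needed).
#' @param cfg the generating \code{\link{simConfig}}.
#' @return invisibly, the written file paths.
#' @export
writeSimulatedTranscriptome <- function(sim, dir, cfg = simConfig()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "transcriptome.fa")
  Biostrings::writeXStringSet(txSequences(sim$transcriptome), fa)
  ann <- file.path(dir, "cds_annotation.tsv")
  con <- file(ann, "w")
  writeLines(sprintf("# riboStall simulated annotation seed=%d", cfg$seed),
             con)
  writeLines("transcript_id\tgene_id\tcds_start\tcds_end", con)
  info <- sim$transcriptome@txInfo
  writeLines(sprintf("%s\t%s\t%d\t%d", info$transcript_id, info$gene_id,
                     info$cds_start, info$cds_end), con)
  close(con)
  invisible(c(fa, ann))
}
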