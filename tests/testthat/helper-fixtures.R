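# small in-code fixtures shared across the suite

# a transcriptome with hand-picked coordinates: utr5 12 nt, CDS 90 nt
# (30 codons), utr3 18 nt
tinyTx <- function(n = 3, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
          collapse = ""), character(1))
  ids <- paste0("tx", seq_len(n))
  Transcriptome(stats::setNames(seqs, ids),
                data.frame(transcript_id = ids,
                           gene_id = paste0("g", seq_len(n)),
                           cds_start = 12L, cds_end = 102L))
}

# library with explicit counts on tx1 and zeros elsewhere
libWithTrack <- function(tx, counts, sampleId = "s1", transcript = "tx1") {
  trk <- lapply(stats::setNames(nm = txIds(tx)),
                function(id) integer(txLengths(tx)[[id]]))
  trk[[transcript]] <- as.integer(counts)
  SampleLibrary(sampleId, trk)
}

# uniform m counts per nucleotide across all transcripts
uniformLib <- function(tx, m = 1L, sampleId = "s1") {
  trk <- lapply(stats::setNames(nm = txIds(tx)), function(id)
    rep(as.integer(m), txLengths(tx)[[id]]))
  SampleLibrary(sampleId, trk)
}

writeTempFasta <- function(seqs) {
  f <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), f)
  f
}

writeTempAnnotation <- function(df) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_id\tcds_start\tcds_end",
               sprintf("%s\t%s\t%d\t%d", df$transcript_id, df$gene_id,
                       df$cds_start, df$cds_end)), f)
  f
}
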