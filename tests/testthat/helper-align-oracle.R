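# Independent all-offsets bisulfite alignment oracle.
#
# Scores a C-to-T reduced read against EVERY offset of the reduced forward
# text and the reduced reverse-complement text of every contig. The
# exhaustive <= k-mismatch scan is delegated to Biostrings::matchPattern
# (a C implementation of naive full-text matching with mismatches) so the
# oracle shares no algorithm or code path with the package's seeded
# aligner; the best-stratum/uniqueness rule is re-stated here from first
# principles.

brute_texts <- function(genome) {
  lapply(names(genome), function(nm) {
    rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", genome[[nm]]), "",
                             fixed = TRUE)[[1]]), collapse = "")
    list(contig = nm, L = nchar(genome[[nm]]),
         fwd = Biostrings::DNAString(gsub("C", "T", genome[[nm]],
                                          fixed = TRUE)),
         rev = Biostrings::DNAString(gsub("C", "T", rc, fixed = TRUE)))
  })
}

brute_align_one <- function(seq, texts, max_mismatch = 2L) {
  pat <- Biostrings::DNAString(gsub("C", "T", seq, fixed = TRUE))
  m <- length(pat)
  hits <- list()
  for (tx in texts) {
    if (m > tx$L) next
    for (space in c("OT", "OB")) {
      tv <- if (space == "OT") tx$fwd else tx$rev
      mp <- Biostrings::matchPattern(pat, tv, max.mismatch = max_mismatch,
                                     with.indels = FALSE, fixed = TRUE)
      if (length(mp) == 0L) next
      p0 <- Biostrings::start(mp) - 1L
      p0 <- p0[p0 >= 0L & p0 + m <= tx$L]  # fully contained placements only
      if (length(p0) == 0L) next
      mm <- Biostrings::neditStartingAt(pat, tv, starting.at = p0 + 1L,
                                        with.indels = FALSE, fixed = TRUE)
      start <- if (space == "OT") p0 else tx$L - p0 - m
      hits[[length(hits) + 1L]] <-
        data.frame(contig = tx$contig, start = start, strand = space,
                   mm = mm, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(list(status = "unaligned"))
  h <- do.call(rbind, hits)
  best <- min(h$mm)
  stratum <- h[h$mm == best, , drop = FALSE]
  if (nrow(stratum) > 1L) return(list(status = "ambiguous"))
  list(status = "unique", contig = stratum$contig, start = stratum$start,
       end = stratum$start + m, strand = stratum$strand,
       mismatches = stratum$mm)
}

brute_align <- function(reads, genome, max_mismatch = 2L) {
  texts <- brute_texts(genome)
  lapply(reads$sequence, brute_align_one, texts = texts,
         max_mismatch = max_mismatch)
}

# Agreement checker shared by the unit and acceptance suites: returns the
# fraction of reads where status (and placement, for uniques) matches.
oracle_agreement <- function(aligned, oracle) {
  ok <- vapply(seq_len(nrow(aligned)), function(i) {
    o <- oracle[[i]]
    if (aligned$status[i] != o$status) return(FALSE)
    if (o$status != "unique") return(TRUE)
    aligned$contig[i] == o$contig && aligned$start[i] == o$start &&
      aligned$strand[i] == o$strand && aligned$mismatches[i] == o$mismatches
  }, logical(1))
  mean(ok)
}
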