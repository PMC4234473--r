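#' Build a directional three-letter bisulfite index
#'
#' C-to-T reduces the forward strand of every contig and the reverse
#' complement of every contig, and hashes all seed-length k-mers of both
#' reduced texts. A directional library is searched only in these two
#' spaces: a read from the original top strand matches the reduced forward
#' text, a read from the original bottom strand matches the reduced
#' reverse-complement text.
#'
#' @param genome a [ref_genome()].
#' @param seed_length k-mer length (>= 8; default 16). Only a read's first
#'   `seed_length` bases are used for seeding, so a read whose entire seed
#'   carries errors can be missed; the brute-force oracle in the test suite
#'   bounds this loss.
#' @return object of class `bisulfite_index`.
#' @export
build_index <- function(genome, seed_length = 16L) {
  stopifnot(inherits(genome, "ref_genome"))
  if (seed_length < 8L) stop("seed_length must be >= 8")
  lens <- nchar(genome)
  if (any(lens < seed_length))
    stop("contig(s) shorter than seed_length")
  nms <- names(genome)
  off <- stats::setNames(cumsum(c(0L, unname(lens[-length(lens)]))), nms)
  fwd_red <- chartr("C", "T", unclass(genome))
  rev_red <- chartr("C", "T", revcomp(unclass(genome)))
  names(rev_red) <- nms
  hash_space <- function(texts) {
    kms <- character(0); gps <- integer(0)
    for (nm in nms) {
      L <- lens[[nm]]
      km <- substring(texts[[nm]], 1:(L - seed_length + 1L), seed_length:L)
      kms <- c(kms, km)
      gps <- c(gps, off[[nm]] + 0:(L - seed_length))
    }
    sp <- split(gps, kms)
    list2env(sp, envir = new.env(hash = TRUE, size = max(2L * length(sp), 29L)))
  }
  structure(list(contigs = nms, lens = lens, off = off,
                 fwd_red = fwd_red, rev_red = rev_red,
                 env_f = hash_space(fwd_red), env_r = hash_space(rev_red),
                 seed_length = as.integer(seed_length)),
            class = "bisulfite_index")
}

#' Align reads with best-unique placement
#'
#' Seeds each C-to-T reduced read in both reduced spaces of the index and
#' scores candidate placements by mismatch count in reduced space: a read
#' T over a genomic C is not a mismatch (it is a conversion event), while
#' C-vs-genomic-T and T-vs-genomic-C are. Within the best (minimal
#' mismatch) stratum, a read is `unique` iff exactly one placement exists
#' and has at most `max_mismatch` mismatches; more than one placement
#' (including equal-score hits on opposite strands) is `ambiguous`; no
#' placement within the bound is `unaligned`. Ties are discarded, never
#' broken arbitrarily. No indels: RRBS 50-mers anchored at MspI ends are
#' aligned substitution-only.
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param index a [build_index()] result.
#' @param max_mismatch maximum mismatches for a unique call (default 2).
#' @return data.frame with one row per read: `read_id`, `status`
#'   (`unique`/`ambiguous`/`unaligned`), `contig`, `start`, `end` (0-based
#'   half-open forward-strand placement), `strand` (`OT`/`OB`),
#'   `mismatches`, plus the input `sequence` and `quality`. Placement
#'   columns are `NA` for non-unique reads.
#' @export
align_reads <- function(reads, index, max_mismatch = 2L) {
  stopifnot(inherits(index, "bisulfite_index"))
  n <- nrow(reads)
  k <- index$seed_length
  off <- index$off; lens <- index$lens; nms <- index$contigs
  status <- rep("unaligned", n)
  contig <- rep(NA_character_, n)
  start <- rep(NA_integer_, n); end <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  score_space <- function(gpos, texts, rraw, m) {
    if (is.null(gpos)) return(NULL)
    ci <- findInterval(gpos, off)
    local <- gpos - off[ci]
    ok <- local + m <= lens[ci]
    if (!any(ok)) return(NULL)
    ci <- ci[ok]; local <- local[ok]
    mm <- vapply(seq_along(ci), function(j) {
      ref <- substr(texts[[nms[ci[j]]]], local[j] + 1L, local[j] + m)
      sum(charToRaw(ref) != rraw)
    }, integer(1))
    data.frame(ci = ci, local = local, mm = mm)
  }
  for (i in seq_len(n)) {
    s <- reads$sequence[i]
    m <- nchar(s)
    if (m < k) next
    rred <- chartr("C", "T", s)
    rraw <- charToRaw(rred)
    seed <- substr(rred, 1L, k)
    hf <- score_space(index$env_f[[seed]], index$fwd_red, rraw, m)
    hr <- score_space(index$env_r[[seed]], index$rev_red, rraw, m)
    nf <- if (is.null(hf)) 0L else nrow(hf)
    if (is.null(hf) && is.null(hr)) next
    all_mm <- c(if (nf) hf$mm, if (!is.null(hr)) hr$mm)
    best <- min(all_mm)
    if (best > max_mismatch) next
    idx <- which(all_mm == best)
    if (length(idx) > 1L) { status[i] <- "ambiguous"; next }
    status[i] <- "unique"
    mism[i] <- best
    if (idx <= nf) {
      ci <- hf$ci[idx]; local <- hf$local[idx]
      contig[i] <- nms[ci]
      start[i] <- local
      strand[i] <- "OT"
    } else {
      j <- idx - nf
      ci <- hr$ci[j]; local <- hr$local[j]
      contig[i] <- nms[ci]
      start[i] <- lens[[ci]] - local - m
      strand[i] <- "OB"
    }
    end[i] <- start[i] + m
  }
  data.frame(read_id = reads$read_id, status = status, contig = contig,
             start = start, end = end, strand = strand, mismatches = mism,
             sequence = reads$sequence, quality = reads$quality,
             stringsAsFactors = FALSE)
}

# Per-contig cytosine position/context tables used by the caller.
cytosine_tables <- function(genome) {
  lapply(stats::setNames(names(genome), names(genome)), function(nm) {
    seq <- genome[[nm]]
    cpos <- match_positions(seq, "C")
    gpos <- match_positions(seq, "G")
    list(cpos = cpos, ctx_f = context_vec(seq, cpos, "+"),
         gpos = gpos, ctx_r = context_vec(seq, gpos, "-"))
  })
}

#' Extract per-cytosine methylation calls
#'
#' For every genomic cytosine on a uniquely-placed read's strand of origin:
#' a read C is a methylated call, a read T a converted call, and any other
#' base (a sequencing error) yields no call. Contexts come from the
#' genome; reverse-strand CpG calls are re-attributed to the forward C
#' position of the CpG, so both strands of one CpG share a site key.
#'
#' @param aligned data.frame from [align_reads()]; all rows must have
#'   `status == "unique"`.
#' @param genome a [ref_genome()].
#' @return data.frame with columns `read_id`, `contig`, `site` (forward C
#'   position of the call's site), `base_pos` (forward position of the
#'   covered base), `offset` (base_pos - start), `strand` (`OT`/`OB`),
#'   `context` (`CpG`/`CHG`/`CHH`) and `state`
#'   (`methylated`/`converted`).
#' @export
extract_calls <- function(aligned, genome) {
  stopifnot(inherits(genome, "ref_genome"))
  if (any(aligned$status != "unique"))
    stop("extract_calls requires unique-status alignments only")
  tabs <- cytosine_tables(genome)
  n <- nrow(aligned)
  rc_all <- strsplit(aligned$sequence, "", fixed = TRUE)
  acc_row <- vector("list", n)   # per read: list(site, pos, ctx, base)
  in_window <- function(v, s, e) {
    if (length(v) == 0L) return(integer(0))
    lo <- findInterval(s - 0.5, v) + 1L
    hi <- findInterval(e - 0.5, v)
    if (lo > hi) integer(0) else lo:hi
  }
  nrows <- integer(n)
  for (i in seq_len(n)) {
    tb <- tabs[[aligned$contig[i]]]
    s <- aligned$start[i]; e <- aligned$end[i]
    rc <- rc_all[[i]]
    if (aligned$strand[i] == "OT") {
      j <- in_window(tb$cpos, s, e)
      p <- tb$cpos[j]
      ctx <- tb$ctx_f[j]
      base <- rc[p - s + 1L]
      site <- p
    } else {
      j <- in_window(tb$gpos, s, e)
      p <- tb$gpos[j]
      ctx <- tb$ctx_r[j]
      base <- rc[e - p]          # read index of forward pos p, 1-based
      site <- p - (ctx == "CpG") # reverse CpG re-attributed to forward C
    }
    keep <- !is.na(ctx) & (base == "C" | base == "T")
    nrows[i] <- sum(keep)
    if (nrows[i] > 0L)
      acc_row[[i]] <- list(site = site[keep], pos = p[keep],
                           ctx = ctx[keep], base = base[keep])
  }
  has <- nrows > 0L
  if (!any(has))
    return(data.frame(read_id = character(0), contig = character(0),
                      site = integer(0), base_pos = integer(0),
                      offset = integer(0), strand = character(0),
                      context = character(0), state = character(0)))
  pos <- unlist(lapply(acc_row[has], `[[`, "pos"), use.names = FALSE)
  base <- unlist(lapply(acc_row[has], `[[`, "base"), use.names = FALSE)
  out <- data.frame(
    read_id = rep(aligned$read_id[has], nrows[has]),
    contig = rep(aligned$contig[has], nrows[has]),
    site = unlist(lapply(acc_row[has], `[[`, "site"), use.names = FALSE),
    base_pos = pos,
    offset = pos - rep(aligned$start[has], nrows[has]),
    strand = rep(aligned$strand[has], nrows[has]),
    context = unlist(lapply(acc_row[has], `[[`, "ctx"), use.names = FALSE),
    state = ifelse(base == "C", "methylated", "converted"),
    stringsAsFactors = FALSE)
  out
}

#' Export alignments as SAM
#'
#' Writes spec-conformant SAM text: `@HD`/`@SQ` headers from the genome,
#' 1-based POS, FLAG 16 (with reverse-complemented SEQ and reversed QUAL)
#' for original-bottom placements, fixed MAPQ 255, all-match CIGAR, `NM`
#' mismatch tag, an `XM` per-base methylation string (Z/z methylated and
#' converted CpG, X/x CHG, H/h CHH, `.` otherwise, in SEQ orientation) and
#' an `XG` strand-of-origin tag. Suitable for loading into a genome
#' viewer after conversion to BAM.
#'
#' @param aligned data.frame from [align_reads()].
#' @param genome a [ref_genome()].
#' @param path optional output path.
#' @param include_unaligned also emit non-unique reads as unmapped records
#'   (FLAG 4).
#' @return character vector of SAM lines (invisibly when `path` is given).
#' @export
to_sam <- function(aligned, genome, path = NULL, include_unaligned = FALSE) {
  stopifnot(inherits(genome, "ref_genome"))
  miss <- setdiff(unique(stats::na.omit(aligned$contig)), names(genome))
  if (length(miss) > 0L)
    stop("contig(s) absent from genome: ", paste(miss, collapse = ", "))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  uniq <- aligned[aligned$status == "unique", , drop = FALSE]
  recs <- character(0)
  if (nrow(uniq) > 0L) {
    calls <- extract_calls(uniq, genome)
    code <- c(CpG = "Z", CHG = "X", CHH = "H")[calls$context]
    code <- ifelse(calls$state == "methylated", code, tolower(code))
    xm_by_read <- split(data.frame(off = calls$offset, code = code,
                                   stringsAsFactors = FALSE),
                       factor(calls$read_id, uniq$read_id))
    m <- nchar(uniq$sequence)
    xm <- vapply(seq_len(nrow(uniq)), function(i) {
      v <- rep(".", m[i])
      cl <- xm_by_read[[uniq$read_id[i]]]
      if (!is.null(cl) && nrow(cl) > 0L) v[cl$off + 1L] <- cl$code
      paste(v, collapse = "")
    }, character(1))
    is_ob <- uniq$strand == "OB"
    seq_out <- uniq$sequence
    qual_out <- uniq$quality
    if (any(is_ob)) {
      seq_out[is_ob] <- revcomp(seq_out[is_ob])
      qual_out[is_ob] <- vapply(qual_out[is_ob], function(q)
        intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
    }
    recs <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tXM:Z:%s\tXG:Z:%s",
                    uniq$read_id, ifelse(is_ob, 16L, 0L), uniq$contig,
                    uniq$start + 1L, m, seq_out, qual_out,
                    uniq$mismatches, xm, uniq$strand)
  }
  if (include_unaligned) {
    rest <- aligned[aligned$status != "unique", , drop = FALSE]
    if (nrow(rest) > 0L)
      recs <- c(recs, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                              rest$read_id, rest$sequence, rest$quality))
  }
  out <- c(header, recs)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read alignments back from SAM
#'
#' Parses mapped records produced by [to_sam()] (or any single-end,
#' ungapped SAM with an `XG` strand tag; records without `XG` are assumed
#' forward = OT, FLAG 16 = OB). Sequences are returned in as-sequenced
#' orientation so downstream call extraction matches [align_reads()]
#' output.
#'
#' @param path SAM path.
#' @return data.frame in the layout of [align_reads()].
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0L)
    return(data.frame(read_id = character(0), status = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), sequence = character(0),
                      quality = character(0)))
  f <- strsplit(ln, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  f <- f[mapped]; flag <- flag[mapped]
  get_tag <- function(x, tag) {
    hit <- grep(paste0("^", tag, ":"), x[-(1:11)], value = TRUE)
    if (length(hit) == 0L) NA_character_ else sub("^[^:]+:[^:]+:", "", hit[1])
  }
  is_ob <- bitwAnd(flag, 16L) == 16L
  seqs <- vapply(f, `[`, character(1), 10L)
  quals <- vapply(f, `[`, character(1), 11L)
  xg <- vapply(f, get_tag, character(1), "XG")
  strand <- ifelse(!is.na(xg), xg, ifelse(is_ob, "OB", "OT"))
  if (any(is_ob)) {
    seqs[is_ob] <- revcomp(seqs[is_ob])
    quals[is_ob] <- vapply(quals[is_ob], function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  }
  nm <- vapply(f, get_tag, character(1), "NM")
  start <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L
  data.frame(read_id = vapply(f, `[`, character(1), 1L),
             status = "unique",
             contig = vapply(f, `[`, character(1), 3L),
             start = start, end = start + nchar(seqs), strand = strand,
             mismatches = as.integer(nm), sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}
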