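#' Per-position base composition
#'
#' Tallies each base at each read position (1-based). Column sums at
#' position p equal the number of reads of length >= p. In a directional
#' RRBS library cytosine content is expected to be very low at almost all
#' positions (bisulfite conversion) with obligate G at positions 2-3.
#'
#' @param reads data.frame with a `sequence` column, or a character vector.
#' @return object of class `composition_matrix`: list with `counts`
#'   (5 x max-length integer matrix, rows A,C,G,T,N) and `n_reads`.
#' @export
base_composition <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  if (length(seqs) == 0L) stop("reads must be non-empty")
  lens <- nchar(seqs)
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  posi <- sequence(lens)
  counts <- table(factor(chars, levels = c("A", "C", "G", "T", "N")),
                  factor(posi, levels = seq_len(max(lens))))
  counts <- matrix(as.integer(counts), nrow = 5L,
                   dimnames = list(base = c("A", "C", "G", "T", "N"),
                                   pos = seq_len(max(lens))))
  structure(list(counts = counts, n_reads = length(seqs)),
            class = "composition_matrix")
}

#' Head/tail cytosine ratio
#'
#' Ratio of total C counts in a head window of read positions to a tail
#' window. In a well-converted library the ratio is approximately 1; an
#' excess of tail cytosines suggests incomplete conversion or sequencing
#' error. The windows default to positions 1-10 vs 41-50 (equal widths;
#' the traditional "bases 1-10 and 40-50" phrasing spans unequal windows,
#' so both are exposed as arguments).
#'
#' @param composition a [base_composition()] result.
#' @param head_range,tail_range 1-based position vectors.
#' @return the head/tail C-count ratio; `NaN` with a warning when the tail
#'   window contains no cytosines.
#' @export
c_ratio <- function(composition, head_range = 1:10, tail_range = 41:50) {
  stopifnot(inherits(composition, "composition_matrix"))
  npos <- ncol(composition$counts)
  if (max(head_range) > npos || max(tail_range) > npos)
    stop("window exceeds read length (", npos, " positions)")
  head_c <- sum(composition$counts["C", head_range])
  tail_c <- sum(composition$counts["C", tail_range])
  if (tail_c == 0L) {
    warning("no cytosines in tail window; C ratio undefined")
    return(NaN)
  }
  head_c / tail_c
}

#' Fraction of reads with GG at positions 2-3
#'
#' MspI digestion forces every directional RRBS read to begin CGG or TGG,
#' so the G-G fraction at 1-based positions 2 and 3 should be ~1 (about
#' 95% in real libraries); a low value indicates incomplete digestion or
#' contamination.
#'
#' @param reads data.frame with a `sequence` column, or a character vector.
#' @param alarm_threshold QC warning is attached below this fraction.
#' @return the fraction, with attribute `qc_pass`.
#' @export
gg_start_fraction <- function(reads, alarm_threshold = 0.95) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  seqs <- seqs[nchar(seqs) >= 3L]
  if (length(seqs) == 0L) stop("no reads of length >= 3")
  frac <- mean(substr(seqs, 2L, 3L) == "GG")
  if (frac < alarm_threshold)
    warning(sprintf("GG start fraction %.3f below alarm threshold %.2f",
                    frac, alarm_threshold))
  structure(frac, qc_pass = frac >= alarm_threshold)
}

#' Mean phred score per read position
#'
#' @param reads data.frame with a `quality` column (phred+33).
#' @param min_mean warn when any positional mean falls below this.
#' @return numeric vector of per-position means (over reads covering the
#'   position), with attribute `qc_pass`.
#' @export
phred_summary <- function(reads, min_mean = 30) {
  if (nrow(reads) == 0L) stop("reads must be non-empty")
  lens <- nchar(reads$quality)
  vals <- unlist(phred_ints(reads$quality), use.names = FALSE)
  posi <- sequence(lens)
  tot <- rowsum(vals, posi)
  cov <- tabulate(posi, nbins = max(lens))
  means <- as.numeric(tot) / cov
  if (any(means < min_mean))
    warning("positional mean phred below ", min_mean, " at position(s) ",
            paste(which(means < min_mean), collapse = ","))
  structure(means, qc_pass = all(means >= min_mean))
}

#' Adaptor trimming and read filtering
#'
#' The FASTX-style clean-up stage: the first exact occurrence of the
#' adaptor within a read truncates the read at the match start; reads
#' shorter than `min_length` after trimming are dropped; remaining reads
#' with mean phred below `min_mean_phred` are dropped.
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param adaptor adaptor sequence; `""` disables trimming.
#' @param min_length minimum post-trim read length kept (default 20 bp).
#' @param min_mean_phred mean-quality floor (unset by convention in the
#'   FASTX tools; 20 is common practice).
#' @return list with `reads` (kept, trimmed) and `counters` (`n_input`,
#'   `n_kept`, `n_dropped_short`, `n_dropped_quality`, `n_trimmed`).
#' @export
trim_and_filter <- function(reads, adaptor = "AGATCGGAAGAGC",
                            min_length = 20L, min_mean_phred = 20) {
  if (min_length < 1L) stop("min_length must be >= 1")
  n_input <- nrow(reads)
  seqs <- reads$sequence
  quals <- reads$quality
  n_trimmed <- 0L
  if (nzchar(adaptor)) {
    hit <- regexpr(adaptor, seqs, fixed = TRUE)
    has <- hit > 0L
    n_trimmed <- sum(has)
    keep_len <- ifelse(has, hit - 1L, nchar(seqs))
    seqs <- substr(seqs, 1L, keep_len)
    quals <- substr(quals, 1L, keep_len)
  }
  long_enough <- nchar(seqs) >= min_length
  n_dropped_short <- sum(!long_enough)
  seqs <- seqs[long_enough]
  quals <- quals[long_enough]
  ids <- reads$read_id[long_enough]
  mean_q <- vapply(phred_ints(quals), mean, numeric(1))
  good_q <- mean_q >= min_mean_phred
  n_dropped_quality <- sum(!good_q)
  out <- data.frame(read_id = ids[good_q], sequence = seqs[good_q],
                    quality = quals[good_q], stringsAsFactors = FALSE)
  list(reads = out,
       counters = list(n_input = n_input, n_kept = nrow(out),
                       n_dropped_short = n_dropped_short,
                       n_dropped_quality = n_dropped_quality,
                       n_trimmed = n_trimmed))
}

#' Full pre-alignment QC report
#'
#' Runs trimming/filtering and computes composition, per-position phred
#' means, the C ratio and the GG start fraction on the kept reads.
#'
#' @inheritParams trim_and_filter
#' @param head_range,tail_range windows for [c_ratio()]; defaults adapt to
#'   the observed read length (first and last 10 positions).
#' @return list of class `read_qc_report`.
#' @export
fastq_qc <- function(reads, adaptor = "AGATCGGAAGAGC", min_length = 20L,
                     min_mean_phred = 20, head_range = NULL,
                     tail_range = NULL) {
  tf <- trim_and_filter(reads, adaptor, min_length, min_mean_phred)
  kept <- tf$reads
  if (nrow(kept) == 0L) stop("no reads passed filtering")
  comp <- base_composition(kept)
  npos <- ncol(comp$counts)
  if (is.null(head_range)) head_range <- seq_len(min(10L, npos))
  if (is.null(tail_range)) tail_range <- seq.int(max(1L, npos - 9L), npos)
  cr <- suppressWarnings(c_ratio(comp, head_range, tail_range))
  gg <- suppressWarnings(gg_start_fraction(kept))
  ph <- suppressWarnings(phred_summary(kept))
  structure(list(composition = comp,
                 mean_phred_per_position = as.numeric(ph),
                 c_ratio = as.numeric(cr),
                 gg_start_fraction = as.numeric(gg),
                 gg_qc_pass = attr(gg, "qc_pass"),
                 phred_qc_pass = attr(ph, "qc_pass"),
                 counters = tf$counters,
                 reads = kept),
            class = "read_qc_report")
}

#' Write a QC report as JSON
#'
#' @param report a `read_qc_report` (or any list of scalars/vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(report, path) {
  x <- report
  if (inherits(x, "read_qc_report")) {
    x <- list(n_reads = x$composition$n_reads,
              counters = x$counters,
              c_ratio = x$c_ratio,
              gg_start_fraction = x$gg_start_fraction,
              gg_qc_pass = x$gg_qc_pass,
              phred_qc_pass = x$phred_qc_pass,
              mean_phred_per_position = x$mean_phred_per_position)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
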