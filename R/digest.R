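#' In-silico MspI digestion with end repair
#'
#' Cuts each contig at the supplied MspI cut positions and applies the
#' end-repair fill-in: the 5'-CG overhang left by MspI is filled in at the
#' 3' termini, so the boundary CpG is duplicated into both neighboring
#' fragments. An internal fragment spanning cuts `[p_i, p_j)` therefore has
#' top-strand sequence `genome[p_i:p_j) + "CG"`, which always begins `CGG`
#' and ends `CCG`. Chromosome-terminal pieces (at most one MspI end) are
#' returned with `flanked_both_ends = FALSE` and carry their raw sequence.
#'
#' @param genome a [ref_genome()].
#' @param cuts data.frame from [find_mspi_sites()]; computed if missing.
#' @return data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open top-strand interval), `sequence` (end-repaired top strand)
#'   and `flanked_both_ends`.
#' @examples
#' g <- ref_genome(c(ctg = "ACCGGTACCGGT"))
#' mspi_digest(g)
#' @export
mspi_digest <- function(genome, cuts = find_mspi_sites(genome)) {
  stopifnot(inherits(genome, "ref_genome"))
  res <- lapply(names(genome), function(nm) {
    seq <- genome[[nm]]
    n <- nchar(seq)
    p <- sort(cuts$pos[cuts$contig == nm])
    pieces <- list()
    if (length(p) == 0L) {
      return(data.frame(contig = nm, start = 0L, end = n,
                        sequence = seq, flanked_both_ends = FALSE,
                        stringsAsFactors = FALSE))
    }
    # left terminal piece [0, p1)
    if (p[1] > 0L)
      pieces[[length(pieces) + 1L]] <- data.frame(
        contig = nm, start = 0L, end = p[1],
        sequence = substr(seq, 1L, p[1]), flanked_both_ends = FALSE,
        stringsAsFactors = FALSE)
    if (length(p) >= 2L) {
      s <- p[-length(p)]
      e <- p[-1]
      pieces[[length(pieces) + 1L]] <- data.frame(
        contig = nm, start = s, end = e,
        sequence = paste0(substring(seq, s + 1L, e), "CG"),
        flanked_both_ends = TRUE, stringsAsFactors = FALSE)
    }
    # right terminal piece [p_last, n)
    if (p[length(p)] < n)
      pieces[[length(pieces) + 1L]] <- data.frame(
        contig = nm, start = p[length(p)], end = n,
        sequence = substring(seq, p[length(p)] + 1L, n),
        flanked_both_ends = FALSE, stringsAsFactors = FALSE)
    do.call(rbind, pieces)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gel size selection
#'
#' Keeps fragments whose apparent gel size (insert length plus adaptor
#' overhead) falls in a window. The default window 150--400 bp matches the
#' smear selected during progressive PCR amplification; the default
#' overhead of 65 bp is the two-step adaptor dimer length. Whether a gel
#' window includes adaptors is protocol-dependent, so both are arguments.
#'
#' @param fragments data.frame from [mspi_digest()].
#' @param min_bp,max_bp inclusive window on insert + overhead.
#' @param adaptor_overhead_bp ligated adaptor length added to each insert.
#' @return the filtered fragment data.frame.
#' @export
size_select <- function(fragments, min_bp = 150L, max_bp = 400L,
                        adaptor_overhead_bp = 65L) {
  if (min_bp < 0 || max_bp < 0 || adaptor_overhead_bp < 0)
    stop("size bounds and overhead must be non-negative")
  if (min_bp > max_bp) stop("min_bp must be <= max_bp")
  len <- nchar(fragments$sequence) + adaptor_overhead_bp
  fragments[len >= min_bp & len <= max_bp, , drop = FALSE]
}

#' Write fragment intervals as BED
#'
#' Three-column BED (0-based half-open), plus name and length columns.
#'
#' @param fragments data.frame from [mspi_digest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.frame(fragments$contig, fragments$start, fragments$end,
                    name = sprintf("frag_%d", seq_len(nrow(fragments))),
                    len = nchar(fragments$sequence))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3+ column BED file
#'
#' @param path BED path (0-based half-open intervals).
#' @return data.frame with columns `contig`, `start`, `end` and, when
#'   present, `name`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("contig", "start", "end")
  if (ncol(x) >= 4L) names(x)[4] <- "name"
  x
}
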