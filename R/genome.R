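#' Reference genome container
#'
#' A reference genome is stored as a named character vector of uppercase DNA
#' sequences over `{A,C,G,T,N}`, one element per contig. All coordinates in
#' this package are 0-based, half-open on the forward strand; SAM export
#' converts to 1-based.
#'
#' @param contigs named character vector of DNA sequences. Names must be
#'   unique and non-empty; sequences are case-folded to uppercase.
#' @return an object of class `ref_genome` (a named character vector).
#' @examples
#' g <- ref_genome(c(chr1 = "acCGGT"))
#' nchar(g)
#' @export
ref_genome <- function(contigs) {
  if (length(contigs) == 0L || !is.character(contigs))
    stop("contigs must be a non-empty named character vector")
  nm <- names(contigs)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("contig names must be unique and non-empty")
  contigs <- toupper(contigs)
  if (any(nchar(contigs) < 1L))
    stop("every contig must have length >= 1")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig(s) contain characters outside {A,C,G,T,N}: ",
         paste(nm[bad], collapse = ", "))
  structure(contigs, class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome with", length(x), "contig(s):\n")
  for (nm in names(x))
    cat(sprintf("  %s: %d bp\n", nm, nchar(x[[nm]])))
  invisible(x)
}

#' Read a reference genome from FASTA
#'
#' Multi-contig, wrapped or unwrapped lines; sequences are case-folded to
#' uppercase. Contig names are taken up to the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return a [ref_genome()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(ss))
  ref_genome(stats::setNames(as.character(ss), nms))
}

#' Write a reference genome to FASTA
#'
#' @param genome a [ref_genome()].
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Generate a random reference genome
#'
#' Draws bases i.i.d. with a given GC content. Used to build desk-scale
#' synthetic references for the simulator and the test suite.
#'
#' @param lengths named integer vector of contig lengths.
#' @param gc GC content in `[0,1]`; A/T and C/G are split evenly.
#' @param seed integer seed; all randomness is local to this call.
#' @return a [ref_genome()].
#' @examples
#' random_genome(c(chr1 = 1000), seed = 1)
#' @export
random_genome <- function(lengths, gc = 0.5, seed = 1L) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("lengths must be a named vector")
  stopifnot(gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contigs <- with_seed(seed, vapply(lengths, function(n) {
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }, character(1)))
  ref_genome(contigs)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run code with a locally-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 0-based start positions of all (possibly overlapping) occurrences of a
# fixed pattern on the forward strand of one sequence.
match_positions <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Find MspI recognition sites
#'
#' MspI recognizes `CCGG` and cleaves between the two Cs, leaving 5'-CG
#' overhangs. The cut position reported is the 0-based index of the first
#' base of `CGG` within each forward-strand `CCGG` occurrence (the site is
#' palindromic, so a forward scan suffices). `N` bases never form sites.
#'
#' @param genome a [ref_genome()].
#' @return data.frame with columns `contig`, `pos` (0-based cut position),
#'   sorted by contig then position; zero rows when no site exists.
#' @examples
#' find_mspi_sites(ref_genome(c(ctg = "TTCCGGAA")))
#' @export
find_mspi_sites <- function(genome) {
  stopifnot(inherits(genome, "ref_genome"))
  res <- lapply(names(genome), function(nm) {
    p <- match_positions(genome[[nm]], "CCGG")
    if (length(p) == 0L) return(NULL)
    data.frame(contig = nm, pos = p + 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(contig = character(0), pos = integer(0))
  out
}

#' Find CpG sites
#'
#' Every forward-strand `CG` dinucleotide, reported once at the 0-based
#' position of the C. Calls from the reverse-strand G of a CpG are
#' attributed to this same forward position throughout the package.
#'
#' @param genome a [ref_genome()].
#' @return data.frame with columns `contig`, `pos`, sorted.
#' @export
find_cpg_sites <- function(genome) {
  stopifnot(inherits(genome, "ref_genome"))
  res <- lapply(names(genome), function(nm) {
    p <- match_positions(genome[[nm]], "CG")
    if (length(p) == 0L) return(NULL)
    data.frame(contig = nm, pos = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(contig = character(0), pos = integer(0))
  out
}

#' Classify the context of a genomic cytosine
#'
#' Cytosine context is `CpG` when the next base on the cytosine's strand is
#' G, `CHG` when the next base is H (any non-G) and the one after is G, and
#' `CHH` otherwise, mirroring the convention used when pooling non-CpG calls
#' to estimate bisulfite conversion. Reverse-strand classification uses the
#' reverse complement. Contexts involving `N` are returned as `NA` and are
#' excluded from all tallies.
#'
#' @param genome a [ref_genome()].
#' @param contig contig name.
#' @param pos 0-based position of the cytosine on the forward strand (for
#'   `strand = "-"` the forward base must be G, i.e. a reverse-strand C).
#' @param strand `"+"` or `"-"`.
#' @return one of `"CpG"`, `"CHG"`, `"CHH"` or `NA` (N in context).
#' @examples
#' g <- ref_genome(c(c1 = "CAGTACG"))
#' classify_context(g, "c1", 0, "+")  # CAG -> CHG
#' @export
classify_context <- function(genome, contig, pos, strand = "+") {
  stopifnot(inherits(genome, "ref_genome"), length(pos) == 1L)
  seq <- genome[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  n <- nchar(seq)
  base <- substr(seq, pos + 1L, pos + 1L)
  if (strand == "+") {
    if (base != "C") stop("base at position is not a cytosine on '+': ", base)
    if (pos + 2L >= n) stop("fewer than 2 downstream bases at contig boundary")
    b1 <- substr(seq, pos + 2L, pos + 2L)
    b2 <- substr(seq, pos + 3L, pos + 3L)
  } else if (strand == "-") {
    if (base != "G") stop("base at position is not a cytosine on '-': ", base)
    if (pos - 2L < 0L) stop("fewer than 2 downstream bases at contig boundary")
    # downstream on the reverse strand reads leftwards; complement to compare
    b1 <- chartr("ACGTN", "TGCAN", substr(seq, pos, pos))
    b2 <- chartr("ACGTN", "TGCAN", substr(seq, pos - 1L, pos - 1L))
  } else stop("strand must be '+' or '-'")
  if (b1 == "N" || b2 == "N") return(NA_character_)
  if (b1 == "G") "CpG" else if (b2 == "G") "CHG" else "CHH"
}

# Vectorized context classification used by the caller/simulator.
# `pos` are 0-based positions known to carry a C on `strand`; returns
# NA for boundary positions and N contexts (callers skip those).
context_vec <- function(seq, pos, strand) {
  n <- nchar(seq)
  out <- rep(NA_character_, length(pos))
  if (strand == "+") {
    ok <- pos + 2L < n
    b1 <- substring(seq, pos + 2L, pos + 2L)
    b2 <- substring(seq, pos + 3L, pos + 3L)
  } else {
    ok <- pos - 2L >= 0L
    b1 <- chartr("ACGTN", "TGCAN", substring(seq, pos, pos))
    b2 <- chartr("ACGTN", "TGCAN", substring(seq, pos - 1L, pos - 1L))
  }
  ok <- ok & b1 != "N" & b2 != "N"
  out[ok & b1 == "G"] <- "CpG"
  out[ok & b1 != "G" & b2 == "G"] <- "CHG"
  out[ok & b1 != "G" & b2 != "G"] <- "CHH"
  out
}
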